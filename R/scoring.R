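# Probe scoring: robust array standardisation, windowed trimmed-mean
# enrichment score, and empirical FDR calibration from an input-swap null.

#' Robustly standardise arrays
#'
#' Median-centres every array (column) and scales it to unit
#' median-absolute-deviation (MAD, Gaussian-consistent constant), i.e. a
#' robust z-transform on the log2 scale. Idempotent and invariant to
#' affine transforms of an array.
#'
#' @param intensities a `medip_intensities` object or a numeric matrix
#'   (probes x arrays).
#' @return same shape as the input with standardised values.
#' @export
standardize_arrays <- function(intensities) {
  m <- if (inherits(intensities, "medip_intensities")) intensities$log2
       else intensities
  med <- apply(m, 2, stats::median)
  s <- apply(m, 2, stats::mad)
  if (any(s == 0)) stopf("constant array cannot be standardised")
  out <- sweep(sweep(m, 2, med, "-"), 2, s, "/")
  if (inherits(intensities, "medip_intensities")) {
    intensities$log2 <- out
    intensities$standardized <- TRUE
    intensities
  } else out
}

# Trimmed-mean window score for one window.
# values: standardised MeDIP-minus-input differences; probe: probe index of
# each value. Score = trimmed mean x sqrt(effective count) with
# effective count = n_probes_surviving * r_m*r_i/(r_m+r_i) — the harmonic
# replicate correction that gives the score unit variance under the null
# for any replicate design (so observed and input-swap null tracks share
# the same scale).
window_score <- function(values, probe, trim_frac, r_m, r_i) {
  n <- length(values)
  k <- floor(trim_frac * n)
  if (k > 0L) {
    o <- order(values)
    keep <- o[(k + 1L):(n - k)]
    tm <- mean(values[keep])
    n_probes <- length(unique(probe[keep]))
  } else {
    tm <- mean(values)
    n_probes <- length(unique(probe))
  }
  n_eff <- n_probes * (r_m * r_i) / (r_m + r_i)
  tm * sqrt(n_eff)
}

score_one_sample <- function(values, probe_of_value, centers, window_bp,
                             trim_frac, min_probes, r_m, r_i) {
  # values arranged probe-major: for probe j, its r_m differences are at
  # rows (j-1)*r_m + 1..r_m. centers must be sorted ascending.
  n_probes <- length(centers)
  half <- window_bp / 2
  lo <- findInterval(centers - half - 1e-9, centers) + 1L
  hi <- findInterval(centers + half + 1e-9, centers)
  vm <- matrix(values, nrow = r_m)  # r_m x n_probes
  psum <- colSums(vm)
  cs <- c(0, cumsum(psum))
  np_win <- hi - lo + 1L
  nval <- np_win * r_m
  k <- floor(trim_frac * nval)
  score <- rep(NA_real_, n_probes)
  fast <- which(k == 0L & nval >= min_probes)
  if (length(fast) > 0L) {
    tm <- (cs[hi[fast] + 1L] - cs[lo[fast]]) / nval[fast]
    score[fast] <- tm * sqrt(np_win[fast] * (r_m * r_i) / (r_m + r_i))
  }
  slow <- which(k > 0L & nval >= min_probes)
  for (i in slow) {
    idx <- lo[i]:hi[i]
    vals <- as.vector(vm[, idx, drop = FALSE])
    score[i] <- window_score(vals, rep(idx, each = r_m), trim_frac, r_m, r_i)
  }
  score
}

#' Windowed probe score track
#'
#' For every probe, pools the standardised MeDIP-minus-mean-input
#' differences of all probes whose centers lie within half the window of
#' its own center (replicate arrays contribute separate values), and
#' scores the window as trimmed mean x sqrt(effective count). Windows with
#' fewer than `min_probes` values give a missing score.
#'
#' @param intensities a `medip_intensities` object (standardised with
#'   [standardize_arrays()]; raw input is standardised on the fly).
#' @param samples samples to score (default: all in the metadata).
#' @param window_bp full window width in bp.
#' @param trim_frac fraction trimmed from each tail of the pooled window
#'   values (0 <= trim_frac < 0.5).
#' @param min_probes minimum number of pooled values required for a score.
#' @param null_swap if `TRUE`, build the label-swapped null track instead:
#'   within each sample the first input replicate plays the MeDIP role and
#'   the remaining input replicate(s) the input role; MeDIP arrays are
#'   ignored. Requires >= 2 input replicates.
#' @return object of class `score_track`: list with `probes` (probe table)
#'   and `scores` (probes x samples matrix).
#' @export
score_probes <- function(intensities, samples = NULL, window_bp = 800,
                         trim_frac = 0.1, min_probes = 3L,
                         null_swap = FALSE) {
  if (window_bp <= 0) stopf("window_bp must be positive")
  if (trim_frac < 0 || trim_frac >= 0.5) stopf("trim_frac must be in [0, 0.5)")
  if (!isTRUE(intensities$standardized))
    intensities <- standardize_arrays(intensities)
  meta <- intensities$arrays
  m <- intensities$log2
  if (is.null(samples)) samples <- unique(meta$sample)
  pr <- intensities$probes
  o <- order(pr$chrom, pr$center)
  pr <- pr[o, , drop = FALSE]
  m <- m[o, , drop = FALSE]

  scores <- matrix(NA_real_, nrow(pr), length(samples),
                   dimnames = list(pr$probe_id, samples))
  for (s in samples) {
    med_ids <- meta$array_id[meta$sample == s & meta$channel == "MeDIP"]
    inp_ids <- meta$array_id[meta$sample == s & meta$channel == "input"]
    if (null_swap) {
      if (length(inp_ids) < 2L)
        stopf("null track needs >= 2 input replicates in sample %s", s)
      med_ids <- inp_ids[1L]
      inp_ids <- inp_ids[-1L]
    }
    if (length(med_ids) < 1L || length(inp_ids) < 1L)
      stopf("sample %s needs at least one MeDIP and one input array", s)
    ibar <- rowMeans(m[, inp_ids, drop = FALSE])
    d <- m[, med_ids, drop = FALSE] - ibar  # probes x r_m
    for (ch in unique(pr$chrom)) {
      ci <- which(pr$chrom == ch)
      vals <- as.vector(t(d[ci, , drop = FALSE]))  # probe-major
      scores[ci, s] <- score_one_sample(
        vals, NULL, pr$center[ci], window_bp, trim_frac, min_probes,
        r_m = length(med_ids), r_i = length(inp_ids))
    }
  }
  structure(list(probes = pr, scores = scores,
                 params = list(window_bp = window_bp, trim_frac = trim_frac,
                               min_probes = min_probes,
                               null_swap = null_swap)),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score_track: %d probes x %d samples (window %g bp, trim %g)%s\n",
              nrow(x$scores), ncol(x$scores), x$params$window_bp,
              x$params$trim_frac,
              if (isTRUE(x$params$null_swap)) " [null swap]" else ""))
  invisible(x)
}

#' Empirical FDR curve from observed and null score tracks
#'
#' `FDR%(s) = 100 * min(1, null exceedance rate at s / observed exceedance
#' rate at s)`, where the null track is scored from the input-replicate
#' label swap. With equal numbers of scored probes in both tracks this is
#' the plain count ratio. The curve is regularised to be monotone
#' non-increasing (cumulative minimum from the highest threshold down).
#' Thresholds with no observed exceedances give a missing FDR.
#'
#' @param observed,null `score_track` objects (or numeric score vectors).
#' @param thresholds numeric thresholds at which to evaluate the curve.
#' @return data.frame with `threshold`, `n_observed`, `n_null`, `fdr_pct`.
#' @export
estimate_fdr <- function(observed, null,
                         thresholds = seq(0.5, 5, by = 0.25)) {
  obs <- if (inherits(observed, "score_track")) as.vector(observed$scores)
         else as.numeric(observed)
  nul <- if (inherits(null, "score_track")) as.vector(null$scores)
         else as.numeric(null)
  obs <- obs[!is.na(obs)]; nul <- nul[!is.na(nul)]
  if (length(obs) == 0L || length(nul) == 0L)
    stopf("both score tracks must be non-empty")
  thresholds <- sort(thresholds)
  n_obs <- vapply(thresholds, function(s) sum(obs >= s), 0)
  n_nul <- vapply(thresholds, function(s) sum(nul >= s), 0)
  fdr <- ifelse(n_obs > 0,
                100 * pmin(1, (n_nul / length(nul)) / (n_obs / length(obs))),
                NA_real_)
  # monotone non-increasing in threshold: no threshold may report a larger
  # FDR than any lower threshold
  ok <- !is.na(fdr)
  fdr[ok] <- cummin(fdr[ok])
  data.frame(threshold = thresholds, n_observed = n_obs, n_null = n_nul,
             fdr_pct = fdr)
}

#' Write a per-sample score track as bedGraph
#'
#' One `chrom start end score` line per scored probe (missing scores are
#' omitted), 0-based half-open.
#'
#' @param track a `score_track`.
#' @param sample sample column to export.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_bedgraph <- function(track, sample, path) {
  sc <- track$scores[, sample]
  keep <- !is.na(sc)
  pr <- track$probes[keep, ]
  writeLines(sprintf("%s\t%d\t%d\t%.6g", pr$chrom, as.integer(pr$start),
                     as.integer(pr$end), sc[keep]), path)
  invisible(path)
}
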