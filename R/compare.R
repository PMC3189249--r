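# Cross-sample methylome comparison: TSS-distance methylation frequency
# profiles, CpG-island / promoter-zone summary tables, common-vs-variable
# categorisation of CMRs, and T-DMR extraction.

#' Methylation frequency profile around the TSS
#'
#' Probes are assigned a strand-aware offset to their gene's TSS, binned,
#' and the per-bin frequency is (number of probes scoring above
#' `call_threshold`) / (total probes in the bin). A centred moving average
#' over `smooth_bp` produces the smoothed curve. Empty bins are omitted.
#'
#' @param track a `score_track`.
#' @param genes gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param sample sample column of the track to profile.
#' @param bin_bp bin width in bp.
#' @param smooth_bp moving-average window (rounded to an odd number of
#'   bins, minimum 1).
#' @param call_threshold probe-level methylation threshold.
#' @param span offsets (bp) retained, default the probe layout span.
#' @return data.frame with `position` (bin center offset), `n_probes`,
#'   `n_methylated`, `frequency`, `smoothed`.
#' @export
tss_profile <- function(track, genes, sample, bin_bp = 100,
                        smooth_bp = 200, call_threshold = 2.5,
                        span = c(-6000, 2500)) {
  pr <- track$probes
  sc <- track$scores[, sample]
  if (!"gene_id" %in% names(pr) || !all(pr$gene_id %in% genes$gene_id)) {
    asg <- assign_region_to_tss(pr, genes)
    offset <- asg$tss_offset
  } else {
    g <- genes[match(pr$gene_id, genes$gene_id), ]
    offset <- ifelse(g$strand == "-", g$tss - pr$center, pr$center - g$tss)
  }
  keep <- !is.na(sc) & offset >= span[1] & offset <= span[2]
  offset <- offset[keep]; sc <- sc[keep]
  bin <- floor(offset / bin_bp)
  n_tot <- tapply(sc, bin, length)
  n_met <- tapply(sc > call_threshold, bin, sum)
  pos <- (as.numeric(names(n_tot)) + 0.5) * bin_bp
  out <- data.frame(position = pos, n_probes = as.integer(n_tot),
                    n_methylated = as.integer(n_met),
                    frequency = as.numeric(n_met / n_tot))
  out <- out[order(out$position), ]
  k <- max(1L, 2L * floor(smooth_bp / (2 * bin_bp)) + 1L)
  out$smoothed <- stats::filter(out$frequency, rep(1 / k, k), sides = 2)
  out$smoothed <- as.numeric(out$smoothed)
  # shrink the moving-average window at the profile edges
  na_idx <- which(is.na(out$smoothed))
  for (i in na_idx) {
    w <- max(1L, i - k %/% 2):min(nrow(out), i + k %/% 2)
    out$smoothed[i] <- mean(out$frequency[w])
  }
  rownames(out) <- NULL
  out
}

#' CpG-island methylation and promoter-zone tables
#'
#' Per sample and score threshold, counts CpG islands overlapped by a CMR
#' whose score in that sample exceeds the threshold, with the frequency as
#' a percentage of all islands. Also tabulates, per sample, the promoter
#' zone (core / tss_up / tss_down, via [assign_region_to_tss()]) of the
#' CMRs methylated in that sample.
#'
#' @param cmrs a `cmr_set`.
#' @param cpg_islands interval data.frame of CpG islands.
#' @param genes gene table for the zone assignment.
#' @param thresholds score thresholds for the island table.
#' @return list with `islands` (sample x threshold counts and
#'   frequencies) and `zones` (sample x zone counts) data.frames.
#' @export
methylation_tables <- function(cmrs, cpg_islands, genes,
                               thresholds = c(2.5, 3.0, 4.0)) {
  if (nrow(cpg_islands) == 0L) stopf("island set is empty")
  samples <- cmr_samples(cmrs)
  n_isl <- nrow(cpg_islands)
  sc <- cmr_scores(cmrs)

  ov <- if (nrow(cmrs) > 0L)
    GenomicRanges::findOverlaps(as_granges(cmrs), as_granges(cpg_islands))
  else NULL
  isl_tab <- expand.grid(sample = samples, threshold = thresholds,
                         stringsAsFactors = FALSE)
  isl_tab$n_islands <- 0L
  if (!is.null(ov) && length(ov) > 0L) {
    q <- S4Vectors::queryHits(ov); subj <- S4Vectors::subjectHits(ov)
    for (r in seq_len(nrow(isl_tab))) {
      hit <- !is.na(sc[q, isl_tab$sample[r]]) &
        sc[q, isl_tab$sample[r]] > isl_tab$threshold[r]
      isl_tab$n_islands[r] <- length(unique(subj[hit]))
    }
  }
  isl_tab$frequency_pct <- 100 * isl_tab$n_islands / n_isl

  zone_tab <- data.frame(sample = samples, total = 0L, tss_up = 0L,
                         core = 0L, tss_down = 0L)
  if (nrow(cmrs) > 0L) {
    zo <- assign_region_to_tss(as.data.frame(cmrs)[, c("chrom", "start", "end")],
                               genes)$zone
    st <- cmr_states(cmrs)
    for (r in seq_along(samples)) {
      met <- st[, samples[r]] == "methylated"
      zone_tab$total[r] <- sum(met)
      zone_tab$tss_up[r] <- sum(met & zo == "tss_up")
      zone_tab$core[r] <- sum(met & zo == "core")
      zone_tab$tss_down[r] <- sum(met & zo == "tss_down")
    }
  }
  list(islands = isl_tab, zones = zone_tab)
}

# tri-state helpers: TRUE / FALSE / NA (indeterminate)
tri_met <- function(states) ifelse(states == "methylated", TRUE,
                                   ifelse(states == "hypomethylated", FALSE,
                                          NA))

#' Categorise CMRs by cross-sample commonality
#'
#' Walks the precedence order `all_positive` (methylated in every sample
#' including sperm) > `sperm_any_others_positive` (methylated in every
#' non-sperm sample, sperm unconstrained) > `somatic_common` (methylated
#' in every somatic sample — germ layers and adult tissues; ES and sperm
#' unconstrained) > `early_diff_only` (methylated in all three germ
#' layers and hypomethylated in every adult tissue), and returns the first
#' category whose conditions hold definitively. Regions matching none are
#' `variable`; regions for which no category holds but at least one was
#' blocked only by indeterminate states in its decisive samples are
#' `other`.
#'
#' @param cmrs a `cmr_set`.
#' @param roles sample roles (list with `es`, `germ_layers`, `adult`,
#'   `sperm`); see [default_sample_roles()].
#' @return list with `category` (character per CMR, in the input order)
#'   and `counts` (category summary table).
#' @export
categorize_commonality <- function(cmrs, roles = default_sample_roles(cmr_samples(cmrs))) {
  for (need in c("germ_layers", "adult", "sperm"))
    if (is.null(roles[[need]]) || length(roles[[need]]) == 0L)
      stopf("sample role '%s' is missing", need)
  samples <- cmr_samples(cmrs)
  somatic <- c(roles$germ_layers, roles$adult)
  non_sperm <- setdiff(samples, roles$sperm)
  st <- cmr_states(cmrs)
  m <- tri_met(st)

  all_true <- function(x) !anyNA(x) && all(x)          # definitive yes
  any_false <- function(x) any(x %in% FALSE)           # definitive no
  categorise_one <- function(mi) {
    checks <- list(
      all_positive = mi[samples],
      sperm_any_others_positive = mi[non_sperm],
      somatic_common = mi[somatic],
      early_diff_only = c(mi[roles$germ_layers], !mi[roles$adult])
    )
    blocked <- FALSE
    for (nm in names(checks)) {
      x <- checks[[nm]]
      if (all_true(x)) return(nm)
      if (!any_false(x)) blocked <- TRUE  # only indeterminates in the way
    }
    if (blocked) "other" else "variable"
  }
  category <- if (nrow(cmrs) > 0L)
    vapply(seq_len(nrow(cmrs)), function(i) categorise_one(m[i, ]), "")
  else character(0)
  lv <- c("all_positive", "sperm_any_others_positive", "somatic_common",
          "early_diff_only", "variable", "other")
  counts <- as.data.frame(table(factor(category, levels = lv)),
                          stringsAsFactors = FALSE)
  names(counts) <- c("category", "n")
  list(category = category, counts = counts)
}

#' Extract tissue-specific differentially methylated regions (T-DMRs)
#'
#' A CMR is a T-DMR when it is methylated (score above the methylated
#' threshold) in at least one sample and hypomethylated in at least one
#' other; indeterminate samples contribute to neither side. A pairwise
#' contrast matrix counts, for every ordered sample pair (a, b), the
#' T-DMRs methylated in a and hypomethylated in b.
#'
#' @param cmrs a `cmr_set`.
#' @return list with `tdmrs` (the subset `cmr_set`) and `contrasts`
#'   (samples x samples integer matrix).
#' @export
extract_tdmrs <- function(cmrs) {
  samples <- cmr_samples(cmrs)
  if (length(samples) < 2L) stopf("need >= 2 samples")
  st <- cmr_states(cmrs)
  is_td <- apply(st, 1, function(x)
    any(x == "methylated") && any(x == "hypomethylated"))
  if (nrow(cmrs) == 0L) is_td <- logical(0)
  td <- cmrs[is_td, , drop = FALSE]
  contr <- matrix(0L, length(samples), length(samples),
                  dimnames = list(methylated_in = samples,
                                  hypomethylated_in = samples))
  if (nrow(td) > 0L) {
    std <- cmr_states(td)
    for (a in samples) for (b in samples) {
      if (a == b) next
      contr[a, b] <- sum(std[, a] == "methylated" &
                           std[, b] == "hypomethylated")
    }
  }
  list(tdmrs = td, contrasts = contr)
}
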