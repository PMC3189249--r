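# Candidate methylated region (CMR) calling: per-sample probe runs above
# the calling threshold, cross-sample merging, the CpG-density and
# high-confidence gates, and tri-state methylation calls.

#' Tri-state methylation call from a region score
#'
#' Scores above 2.5 are `methylated`, below 1.5 `hypomethylated`, between
#' the two (boundaries included) `indeterminate`. Missing scores are
#' `indeterminate`.
#'
#' @param region_score numeric vector of region scores.
#' @param methylated_above,hypomethylated_below thresholds (strict
#'   inequalities).
#' @return character vector of states.
#' @export
call_state <- function(region_score, methylated_above = 2.5,
                       hypomethylated_below = 1.5) {
  out <- rep("indeterminate", length(region_score))
  out[!is.na(region_score) & region_score > methylated_above] <- "methylated"
  out[!is.na(region_score) & region_score < hypomethylated_below] <-
    "hypomethylated"
  out
}

#' Call candidate methylated regions
#'
#' Per sample, maximal runs of probes scoring above `call_threshold`,
#' with consecutive member probes separated by at most `max_gap_bp`
#' (gap measured between probe intervals), become candidate intervals.
#' Candidate intervals from all samples are then merged wherever they
#' overlap, yielding one region set shared by all samples.
#'
#' @param track a `score_track`.
#' @param call_threshold probe score above which a probe is a candidate.
#' @param max_gap_bp largest inter-probe gap bridged within a run.
#' @return data.frame of merged regions (`chrom`, `start`, `end`).
#' @export
call_candidate_regions <- function(track, call_threshold = 2.5,
                                   max_gap_bp = 400) {
  pr <- track$probes
  pieces <- list()
  for (s in colnames(track$scores)) {
    sc <- track$scores[, s]
    hit <- which(!is.na(sc) & sc > call_threshold)
    if (length(hit) == 0L) next
    new_run <- c(TRUE,
                 pr$chrom[hit[-1]] != pr$chrom[hit[-length(hit)]] |
                   pr$start[hit[-1]] - pr$end[hit[-length(hit)]] > max_gap_bp)
    run <- cumsum(new_run)
    pieces[[s]] <- data.frame(
      chrom = tapply(pr$chrom[hit], run, `[`, 1L),
      start = as.integer(tapply(pr$start[hit], run, min)),
      end = as.integer(tapply(pr$end[hit], run, max))
    )
  }
  if (length(pieces) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  all <- do.call(rbind, pieces)
  merged <- GenomicRanges::reduce(as_granges(all))
  data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged) - 1L,
             end = GenomicRanges::end(merged))
}

region_probe_index <- function(regions, probes) {
  # probes whose center falls inside each region (half-open)
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(probes$chrom,
                           IRanges::IRanges(probes$center + 1L,
                                            probes$center + 1L)),
    as_granges(regions))
  split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
}

#' Filter candidate regions and build the CMR table
#'
#' A candidate region is kept when its CpG density (mean of the member
#' probes' 500-bp window densities) exceeds `min_cpg_density` percent and
#' its score exceeds `hc_threshold` in at least one sample. The region
#' score per sample is the maximum member-probe score; a tri-state call
#' ([call_state()]) is added per sample.
#'
#' @param regions data.frame from [call_candidate_regions()].
#' @param track the `score_track` the regions were called from.
#' @param min_cpg_density CpG density gate in percent (strict).
#' @param hc_threshold high-confidence score gate (strict, >= 1 sample).
#' @return data.frame of class `cmr_set`: `region_id`, `chrom`, `start`,
#'   `end`, `n_probes`, `cpg_density`, then `score_<sample>` and
#'   `state_<sample>` columns.
#' @export
filter_cmrs <- function(regions, track, min_cpg_density = 5.0,
                        hc_threshold = 3.0) {
  samples <- colnames(track$scores)
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(), cpg_density = numeric())
  if (nrow(regions) == 0L) {
    for (s in samples) empty[[paste0("score_", s)]] <- numeric(0)
    for (s in samples) empty[[paste0("state_", s)]] <- character(0)
    return(structure(empty, class = c("cmr_set", "data.frame")))
  }
  idx <- region_probe_index(regions, track$probes)
  out <- regions
  out$n_probes <- 0L
  out$cpg_density <- NA_real_
  smat <- matrix(NA_real_, nrow(regions), length(samples),
                 dimnames = list(NULL, samples))
  for (k in seq_len(nrow(regions))) {
    pi <- idx[[as.character(k)]]
    if (is.null(pi)) next
    out$n_probes[k] <- length(pi)
    out$cpg_density[k] <- mean(track$probes$cpg_density[pi])
    smat[k, ] <- suppressWarnings(
      apply(track$scores[pi, , drop = FALSE], 2, max, na.rm = TRUE))
  }
  smat[!is.finite(smat)] <- NA_real_
  keep <- !is.na(out$cpg_density) & out$cpg_density > min_cpg_density &
    apply(smat, 1, function(x) any(!is.na(x) & x > hc_threshold))
  out <- out[keep, , drop = FALSE]
  smat <- smat[keep, , drop = FALSE]
  if (nrow(out) > 0L)
    out$region_id <- sprintf("cmr%05d", seq_len(nrow(out)))
  else out$region_id <- character(0)
  for (s in samples) out[[paste0("score_", s)]] <- smat[, s]
  for (s in samples) out[[paste0("state_", s)]] <- call_state(smat[, s])
  out <- out[, c("region_id", "chrom", "start", "end", "n_probes",
                 "cpg_density", paste0("score_", samples),
                 paste0("state_", samples))]
  rownames(out) <- NULL
  structure(out, class = c("cmr_set", "data.frame"))
}

#' Score, call and filter in one step
#'
#' Convenience wrapper: [call_candidate_regions()] then [filter_cmrs()].
#'
#' @inheritParams call_candidate_regions
#' @inheritParams filter_cmrs
#' @return a `cmr_set` data.frame.
#' @export
call_cmrs <- function(track, call_threshold = 2.5, max_gap_bp = 400,
                      min_cpg_density = 5.0, hc_threshold = 3.0) {
  regions <- call_candidate_regions(track, call_threshold, max_gap_bp)
  filter_cmrs(regions, track, min_cpg_density, hc_threshold)
}

cmr_samples <- function(cmrs) {
  sub("^score_", "", grep("^score_", names(cmrs), value = TRUE))
}

cmr_states <- function(cmrs) {
  samples <- cmr_samples(cmrs)
  st <- as.matrix(as.data.frame(cmrs)[, paste0("state_", samples),
                                      drop = FALSE])
  colnames(st) <- samples
  st
}

cmr_scores <- function(cmrs) {
  samples <- cmr_samples(cmrs)
  sc <- as.matrix(as.data.frame(cmrs)[, paste0("score_", samples),
                                      drop = FALSE])
  colnames(sc) <- samples
  sc
}
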