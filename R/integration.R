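# Integration of methylation calls with histone states and expression:
# four-state promoter classification, conditional methylation percentages,
# state-transition tables and group expression comparisons.

#' Assign the four-state histone classification per gene
#'
#' A gene's promoter state is determined solely by peak overlap with the
#' TSS window (default +/- 2 kb, closed; an overlap needs >= 1 bp
#' intersection): K4-only overlap gives `K4`, K27-only `K27`, both
#' `bivalent`, neither `none`.
#'
#' @param k4_peaks,k27_peaks interval data.frames (0-based half-open).
#' @param genes gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param window half-width of the TSS window in bp.
#' @return named character vector of states per gene.
#' @export
assign_histone_state <- function(k4_peaks, k27_peaks, genes,
                                 window = 2000L) {
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, genes$tss - window),
                    end = genes$tss + window + 1L)
  overlaps <- function(peaks) {
    hit <- rep(FALSE, nrow(genes))
    if (nrow(peaks) > 0L) {
      ov <- GenomicRanges::findOverlaps(as_granges(win), as_granges(peaks))
      hit[unique(S4Vectors::queryHits(ov))] <- TRUE
    }
    hit
  }
  k4 <- overlaps(k4_peaks)
  k27 <- overlaps(k27_peaks)
  st <- ifelse(k4 & k27, "bivalent",
               ifelse(k4, "K4", ifelse(k27, "K27", "none")))
  stats::setNames(st, genes$gene_id)
}

#' Gene-level methylation calls from CMRs
#'
#' A gene is flagged methylated in a sample when any CMR with state
#' `methylated` in that sample has its midpoint inside the gene's core
#' promoter window (strand-aware, default -1.5 kb..+0.5 kb of the TSS).
#'
#' @param cmrs a `cmr_set`.
#' @param genes gene table.
#' @param core_window bp interval relative to the TSS.
#' @return genes x samples logical matrix.
#' @export
gene_methyl_calls <- function(cmrs, genes, core_window = c(-1500, 500)) {
  samples <- cmr_samples(cmrs)
  out <- matrix(FALSE, nrow(genes), length(samples),
                dimnames = list(genes$gene_id, samples))
  if (nrow(cmrs) == 0L) return(out)
  asg <- assign_region_to_tss(as.data.frame(cmrs)[, c("chrom", "start", "end")],
                              genes, core_zone = core_window)
  st <- cmr_states(cmrs)
  in_core <- asg$tss_offset >= core_window[1] & asg$tss_offset <= core_window[2]
  for (k in which(in_core)) {
    met <- samples[st[k, ] == "methylated"]
    if (length(met) > 0L) out[asg$gene_id[k], met] <- TRUE
  }
  out
}

#' Percentage of methylated genes per histone state
#'
#' @param states named character vector (per gene) of histone states.
#' @param methylated named logical vector (per gene) of methylation calls,
#'   same gene universe.
#' @return data.frame `state`, `n_genes`, `n_methylated`, `pct_methylated`
#'   (0 when the state class is empty).
#' @export
methylation_by_state <- function(states, methylated) {
  if (!identical(sort(names(states)), sort(names(methylated))))
    stopf("states and methylation calls must share the gene universe")
  methylated <- methylated[names(states)]
  lv <- c("K4", "K27", "bivalent", "none")
  st <- factor(states, levels = lv)
  n <- as.integer(table(st))
  nm <- as.integer(tapply(methylated, st, sum, default = 0L))
  data.frame(state = lv, n_genes = n, n_methylated = nm,
             pct_methylated = ifelse(n > 0, 100 * nm / n, 0))
}

#' Histone state transition table between two samples
#'
#' Counts genes per ordered state pair (16 rows) together with the number
#' methylated in the destination sample. Row totals sum to the gene
#' universe size, and the marginals reproduce the per-sample state counts.
#'
#' @param states_a,states_b named character state vectors (same genes).
#' @param methylated_b named logical methylation calls in the destination
#'   sample.
#' @return data.frame `from`, `to`, `total`, `methylated`.
#' @export
transition_table <- function(states_a, states_b, methylated_b) {
  genes <- names(states_a)
  if (!identical(sort(genes), sort(names(states_b))))
    stopf("state maps must share the gene universe")
  states_b <- states_b[genes]
  methylated_b <- methylated_b[genes]
  lv <- c("K4", "K27", "bivalent", "none")
  out <- expand.grid(to = lv, from = lv, stringsAsFactors = FALSE)[, c("from", "to")]
  out$total <- 0L
  out$methylated <- 0L
  for (r in seq_len(nrow(out))) {
    sel <- states_a == out$from[r] & states_b == out$to[r]
    out$total[r] <- sum(sel)
    out$methylated[r] <- sum(sel & methylated_b)
  }
  out
}

#' Compare expression between two gene groups
#'
#' Welch two-sample t-test on log2(signal + 1), with the descriptive
#' statistics of the corresponding box plot (median, quartiles, 10th/90th
#' percentiles) per group.
#'
#' @param expression genes x samples matrix.
#' @param group_a,group_b character vectors of gene ids (>= 2 each).
#' @param sample column to compare.
#' @return data.frame of class `expression_comparison` with one row per
#'   group plus attributes `t`, `p`.
#' @export
compare_expression <- function(expression, group_a, group_b, sample) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("both groups need >= 2 genes")
  xa <- log2(expression[group_a, sample] + 1)
  xb <- log2(expression[group_b, sample] + 1)
  tt <- stats::t.test(xa, xb)
  desc <- function(x, label) {
    q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    data.frame(group = label, n = length(x), p10 = q[1], q1 = q[2],
               median = q[3], q3 = q[4], p90 = q[5], mean = mean(x))
  }
  out <- rbind(desc(xa, "a"), desc(xb, "b"))
  attr(out, "t") <- unname(tt$statistic)
  attr(out, "p") <- tt$p.value
  class(out) <- c("expression_comparison", "data.frame")
  out
}
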