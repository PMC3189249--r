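# Testis-specificity ranking and gene-set enrichment with a
# gene-permutation null (weighted Kolmogorov-Smirnov running sum).

#' Rank genes by testis-specific expression
#'
#' Score = testis signal / max(maximum somatic signal, floor). The floor
#' guards against zero somatic expression on the mean-100 normalised
#' scale. Genes are returned in descending score order, ties broken by
#' gene id.
#'
#' @param expression genes x samples matrix (rownames = gene ids).
#' @param somatic_columns somatic sample columns entering the maximum.
#' @param testis_column testis column name.
#' @param floor lower bound for the somatic maximum (> 0).
#' @return data.frame `gene_id`, `score`, descending.
#' @export
testis_score <- function(expression, somatic_columns, testis_column,
                         floor = 1.0) {
  if (!testis_column %in% colnames(expression))
    stopf("testis column '%s' not found", testis_column)
  miss <- setdiff(somatic_columns, colnames(expression))
  if (length(miss) > 0L)
    stopf("somatic column(s) missing: %s", paste(miss, collapse = ", "))
  if (floor <= 0) stopf("floor must be positive")
  den <- pmax(apply(expression[, somatic_columns, drop = FALSE], 1, max),
              floor)
  sc <- expression[, testis_column] / den
  ids <- rownames(expression)
  o <- order(-sc, ids)
  data.frame(gene_id = ids[o], score = as.numeric(sc[o]))
}

# ES from hit positions (already sorted ascending) over a ranked list of
# length n with weights w (all genes, list order). Classic weighted KS:
# hit steps proportional to |score|^p (normalised over the set), miss
# steps -1/(n - n_hits). Returns the signed extremum.
running_extremum <- function(hit_pos, w_hits, n) {
  nh <- length(hit_pos)
  p_hit <- cumsum(w_hits) / sum(w_hits)
  p_miss <- (hit_pos - seq_len(nh)) / (n - nh)
  # extrema can only occur immediately at (after) a hit or just before the
  # next hit; evaluate both bracketing values per hit
  top <- p_hit - p_miss
  bottom <- c(0, p_hit[-nh]) - p_miss
  i <- which.max(pmax(abs(top), abs(bottom)))
  if (abs(top[i]) >= abs(bottom[i])) top[i] else bottom[i]
}

#' Weighted KS enrichment score with full running sum
#'
#' Walks the ranked list; genes in the set increment the running sum by
#' `|score|^weight_exponent` (normalised over the set), others decrement
#' it by 1/(N - N_hits). The enrichment score (ES) is the extremum of the
#' running sum by absolute value. The running sum returns to zero at the
#' end of the list.
#'
#' @param ranked data.frame from [testis_score()] (or any `gene_id`,
#'   `score` ranking, descending).
#' @param gene_set character vector, non-empty proper subset of the
#'   ranked genes.
#' @param weight_exponent weighting exponent p (0 = classic KS, 1 =
#'   weighted GSEA default).
#' @return list with `es` and `running` (data.frame `gene_id`,
#'   `running_sum`).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  n <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stopf("gene set has no genes in the ranked list")
  if (nh == n) stopf("gene set equals the full ranked list")
  w <- abs(ranked$score)^weight_exponent
  w_hit <- w * hit
  inc <- ifelse(hit, w_hit / sum(w_hit), -1 / (n - nh))
  rs <- cumsum(inc)
  es <- rs[which.max(abs(rs))]
  list(es = es,
       running = data.frame(gene_id = ranked$gene_id, running_sum = rs))
}

#' Permutation test for gene-set enrichment
#'
#' Null ES values come from random gene-label permutations (uniformly
#' resampled hit positions). For a positive observed ES the p-value is
#' `(1 + #{null ES >= ES}) / (1 + n)` (mirrored for negative ES), and
#' `NES = ES / mean(|null ES| of the same sign)`.
#'
#' @inheritParams enrichment_score
#' @param n number of permutations (>= 100).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list of class `enrichment_result`: `es`, `nes`, `p`,
#'   `n_permutations`, `set_size`, `seed`.
#' @export
permutation_test <- function(ranked, gene_set, n = 1000L, seed = 1L,
                             weight_exponent = 1) {
  if (n < 100L) stopf("need >= 100 permutations")
  obs <- enrichment_score(ranked, gene_set, weight_exponent)$es
  nh <- sum(ranked$gene_id %in% gene_set)
  ng <- nrow(ranked)
  w <- abs(ranked$score)^weight_exponent
  set.seed(seed)
  null_es <- vapply(seq_len(n), function(i) {
    pos <- sort.int(sample.int(ng, nh))
    running_extremum(pos, w[pos], ng)
  }, 0)
  if (all(null_es == 0)) stopf("degenerate null: all permutation ES are zero")
  same_sign <- if (obs >= 0) null_es[null_es > 0] else -null_es[null_es < 0]
  if (length(same_sign) == 0L) same_sign <- abs(null_es)
  nes <- obs / mean(abs(same_sign))
  p <- if (obs >= 0) (1 + sum(null_es >= obs)) / (1 + n)
       else (1 + sum(null_es <= obs)) / (1 + n)
  structure(list(es = obs, nes = nes, p = p, n_permutations = n,
                 set_size = nh, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (%d genes, %d permutations)\n",
              x$es, x$nes, x$p, x$set_size, x$n_permutations))
  invisible(x)
}
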