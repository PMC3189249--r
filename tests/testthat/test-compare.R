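test_that("TSS profile frequency follows the probe-count formula", {
  # 10 probes at one position bin: 3 above the threshold -> 0.3
  genes <- data.frame(gene_id = "g1", chrom = "chrT", tss = 50000L,
                      strand = "+")
  centers <- 50000L + seq(50L, 950L, by = 100L)  # all in one 1-kb bin
  probes <- data.frame(probe_id = sprintf("p%02d", 1:10), chrom = "chrT",
                       start = centers - 30, end = centers + 30,
                       center = centers, gene_id = "g1",
                       cpg_density = 6)
  sc <- matrix(c(3, 3, 3, rep(1, 7)), ncol = 1,
               dimnames = list(probes$probe_id, "A"))
  tr <- structure(list(probes = probes, scores = sc, params = list()),
                  class = "score_track")
  one_bin <- tss_profile(tr, genes, "A", bin_bp = 1000, smooth_bp = 0)
  expect_equal(one_bin$n_probes, 10L)
  expect_equal(one_bin$n_methylated, 3L)
  expect_equal(one_bin$frequency, 0.3)

  # all probes methylated -> 1.0
  tr$scores[] <- 5
  expect_equal(tss_profile(tr, genes, "A", bin_bp = 10000)$frequency, 1.0)

  # smoothing a constant profile leaves it unchanged
  st <- small_study()
  prof2 <- tss_profile(st$track, st$sim$annotation$genes, "Ect")
  const <- prof2
  const$frequency <- 0.25
  k_smoothed <- tss_profile(st$track, st$sim$annotation$genes, "Ect",
                            smooth_bp = 600)
  expect_equal(nrow(k_smoothed), nrow(prof2))
  # direct check on the smoother: constant in, constant out
  flat <- tr
  flat$scores <- matrix(rep(c(5, 1), 5), ncol = 1,
                        dimnames = list(probes$probe_id, "A"))
  pf <- tss_profile(flat, genes, "A", bin_bp = 100, smooth_bp = 0)
  expect_equal(pf$smoothed, pf$frequency)
})

test_that("island and zone tables count overlaps per threshold", {
  islands <- data.frame(chrom = "chrT",
                        start = c(1000L, 3000L, 5000L, 7000L),
                        end = c(1600L, 3600L, 5600L, 7600L))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chrT",
                      tss = c(1200L, 5200L), strand = "+")
  cm <- make_cmr_set(cbind(A = c(3.5, 2.7), B = c(1.0, 4.5)))
  # regions r001 = [1000,2200) overlaps island 1; r002 = [3000,4200) island 2
  tabs <- methylation_tables(cm, islands, genes)
  it <- tabs$islands
  get <- function(s, t) it$n_islands[it$sample == s & it$threshold == t]
  expect_equal(get("A", 2.5), 2L)  # 3.5 and 2.7 both over 2.5
  expect_equal(get("A", 3.0), 1L)
  expect_equal(get("A", 4.0), 0L)
  expect_equal(get("B", 4.0), 1L)
  expect_equal(it$frequency_pct, 100 * it$n_islands / 4)

  # counts are monotone non-increasing in the threshold for every sample
  st <- small_study()
  tabs2 <- methylation_tables(st$cmrs, st$sim$annotation$cpg_islands,
                              st$sim$annotation$genes)
  for (s in unique(tabs2$islands$sample)) {
    cnt <- tabs2$islands$n_islands[tabs2$islands$sample == s]
    expect_true(all(diff(cnt) <= 0))
  }
  # brute-force overlap oracle at one threshold
  sc <- promethylome:::cmr_scores(st$cmrs)
  hit <- sc[, "Ect"] > 3.0 & !is.na(sc[, "Ect"])
  ov <- GenomicRanges::countOverlaps(as_gr(st$sim$annotation$cpg_islands),
                                     as_gr(st$cmrs[hit, ]))
  want <- sum(ov > 0)
  got <- tabs2$islands$n_islands[tabs2$islands$sample == "Ect" &
                                   tabs2$islands$threshold == 3.0]
  expect_equal(got, want)

  # zero CMRs -> all zero
  empty <- make_cmr_set(cbind(A = numeric(0), B = numeric(0)))
  t0 <- methylation_tables(empty, islands, genes)
  expect_true(all(t0$islands$n_islands == 0))
  expect_true(all(t0$islands$frequency_pct == 0))
  expect_true(all(t0$zones$total == 0))
})

test_that("commonality categories follow the precedence rules", {
  samples <- c("ES1", "ES2", "Ect", "End", "Pme", "Brain", "Liver",
               "Muscle", "Sperm")
  row <- function(...) {
    x <- c(...)
    names(x) <- samples
    x
  }
  sc <- rbind(
    row(1.0, 1.0, 3.2, 2.7, 2.8, 2.6, 2.8, 2.9, 1.2),  # somatic_common
    row(3.1, 3.0, 3.2, 2.7, 2.8, 2.6, 2.8, 2.9, 2.6),  # all_positive
    row(2.6, 2.7, 3.2, 2.7, 2.8, 2.6, 2.8, 2.9, 1.2),  # sperm_any
    row(1.0, 1.0, 3.2, 2.7, 2.8, 1.0, 1.1, 1.2, 1.0),  # early_diff_only
    row(1.0, 1.0, 3.2, 1.0, 1.0, 1.0, 1.1, 1.2, 1.0),  # variable
    row(1.0, 1.0, 3.2, 2.0, 2.8, 2.6, 2.8, 2.9, 1.2)   # other (End indet)
  )
  cm <- make_cmr_set(sc)
  got <- categorize_commonality(cm)$category
  expect_equal(got, c("somatic_common", "all_positive",
                      "sperm_any_others_positive", "early_diff_only",
                      "variable", "other"))
})

test_that("T-DMRs need one methylated and one hypomethylated sample", {
  sc <- rbind(
    c(A = 3.0, B = 3.1, C = 3.2),  # methylated everywhere: not a T-DMR
    c(A = 3.0, B = 1.0, C = 1.0),  # A-specific T-DMR
    c(A = 3.0, B = 2.0, C = 2.2)   # indeterminate elsewhere: not a T-DMR
  )
  cm <- make_cmr_set(sc)
  td <- extract_tdmrs(cm)
  expect_equal(nrow(td$tdmrs), 1L)
  expect_equal(td$tdmrs$region_id, "r002")
  expect_equal(td$contrasts["A", "B"], 1L)
  expect_equal(td$contrasts["B", "A"], 0L)
  # the indeterminate sample contributed to neither side
  expect_equal(sum(td$contrasts), 2L)  # A>B and A>C
})

test_that("category counts partition the classified regions", {
  st <- small_study()
  comm <- categorize_commonality(st$cmrs)
  expect_equal(sum(comm$counts$n), nrow(st$cmrs))
  expect_equal(length(comm$category), nrow(st$cmrs))
})
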