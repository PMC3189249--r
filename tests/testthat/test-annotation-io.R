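test_that("interval sets round-trip through BED, GFF and TSV", {
  set.seed(1)
  iv <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                   start = sample.int(1e5, 20),
                   name = sprintf("iv%02d", 1:20))
  iv$end <- iv$start + sample.int(5000, 20)
  iv <- iv[, c("chrom", "start", "end", "name")]
  iv <- iv[order(iv$chrom, iv$start, iv$end), ]
  rownames(iv) <- NULL
  for (fmt in c("BED", "GFF", "TSV")) {
    f <- withr::local_tempfile()
    write_intervals(iv, f, fmt)
    back <- read_intervals(f, fmt)
    expect_equal(back[, c("chrom", "start", "end", "name")], iv,
                 info = fmt)
  }
})

test_that("BED is parsed 0-based half-open and GFF emitted 1-based closed", {
  f <- withr::local_tempfile(lines = "chr1\t100\t200\tx")
  iv <- read_intervals(f, "BED")
  expect_equal(iv$start, 100L)  # first covered base is position 100
  expect_equal(iv$end, 200L)    # position 200 itself not covered

  g <- withr::local_tempfile()
  write_intervals(iv, g, "GFF")
  line <- grep("^chr1", readLines(g), value = TRUE)
  fields <- strsplit(line, "\t")[[1]]
  expect_equal(as.integer(fields[4:5]), c(101L, 200L))

  skip_if_not_installed("rtracklayer")
  # independent coordinate-convention oracle
  bed_gr <- rtracklayer::import(f, format = "bed")
  expect_equal(GenomicRanges::start(bed_gr), iv$start + 1L)
  expect_equal(GenomicRanges::end(bed_gr), iv$end)
})

test_that("malformed input is rejected with its line number", {
  f <- withr::local_tempfile(lines = c("chr1\t1\t10", "chr1\toops"))
  expect_error(read_intervals(f, "BED"), "line 2")
  f2 <- withr::local_tempfile(lines = c("chr1\t5\t2\tbad"))
  expect_error(read_intervals(f2, "BED"), "start >= end")
})

test_that("unsorted input is accepted and returned sorted", {
  f <- withr::local_tempfile(lines = c("chr2\t50\t60", "chr1\t500\t600",
                                       "chr1\t10\t20"))
  iv <- read_intervals(f, "BED")
  expect_equal(iv$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(iv$start, c(10L, 500L, 50L))
})

test_that("probe CpG content matches the definition and a string-scan oracle", {
  # 20 CpGs in a 500 bp window is 4 percent
  s <- paste0(strrep("AT", 115), strrep("CGAATTATTA", 20), strrep("TA", 35))
  expect_equal(nchar(s), 500)
  expect_equal(probe_cpg_content(250, s), 4.0)
  expect_equal(probe_cpg_content(250, strrep("AT", 250)), 0.0)
  expect_equal(probe_cpg_content(3, "CGCGCG"), 100 * 3 / 6)

  skip_if_not_installed("Biostrings")
  set.seed(7)
  for (i in 1:50) {
    seqs <- paste(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = "")
    center <- sample(0:700, 1)
    got <- probe_cpg_content(center, seqs)
    win <- substr(seqs, max(0, center - 250) + 1, min(700, center + 250))
    exp_cnt <- Biostrings::countPattern("CG", Biostrings::DNAString(win))
    expect_equal(got, 100 * exp_cnt / nchar(win))
  }
})

test_that("promoter CpG classification follows the windowed o/e and GC rule", {
  # maximal density: pure CG repeats
  expect_equal(classify_promoter_cpg(700, "+", strrep("CG", 1000)), "HCP")
  # zero CpG anywhere
  expect_equal(classify_promoter_cpg(700, "+", strrep("AT", 1000)), "LCP")

  # derived oracle: single 500-bp window, independent o/e and GC computation
  skip_if_not_installed("Biostrings")
  set.seed(11)
  for (i in 1:30) {
    n_cpg <- sample(0:40, 1)
    gc_bg <- stats::runif(1, 0.35, 0.6)
    bases <- sample(c("A", "C", "G", "T"), 500, TRUE,
                    prob = c((1 - gc_bg) / 2, gc_bg / 2, gc_bg / 2,
                             (1 - gc_bg) / 2))
    acc <- which(bases[-500] == "C" & bases[-1] == "G")
    bases[acc + 1] <- "A"
    if (n_cpg > 0) {
      pos <- seq(3, 497, length.out = max(n_cpg, 2))[seq_len(n_cpg)]
      bases[round(pos)] <- "C"; bases[round(pos) + 1] <- "G"
    }
    s <- paste(bases, collapse = "")
    d <- Biostrings::DNAString(s)
    cnt <- Biostrings::countPattern("CG", d)
    fr <- Biostrings::letterFrequency(d, c("C", "G"))
    oe <- if (prod(fr) > 0) cnt * 500 / prod(fr) else 0
    gc <- sum(fr) / 500
    want <- if (oe >= 0.75 && gc >= 0.55) "HCP"
            else if (oe < 0.48) "LCP" else "ICP"
    # region equal to a single window: rule applies verbatim
    got <- classify_promoter_cpg(250, "+", s, region = c(-250, 250))
    expect_equal(got, want, info = sprintf("oe=%.3f gc=%.3f", oe, gc))
  }
})

test_that("regions are assigned to nearest TSS with strand-aware zones", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(10000L, 30000L), strand = c("+", "-"))
  reg <- function(mid) data.frame(chrom = "chr1", start = mid - 50,
                                  end = mid + 50)
  # midpoint at the TSS
  expect_equal(assign_region_to_tss(reg(10000), genes)$zone, "core")
  # one bp past the upstream core limit
  r <- assign_region_to_tss(reg(10000 - 1001), genes)
  expect_equal(r$zone, "tss_up")
  expect_equal(r$tss_offset, -1001)
  # minus-strand gene: genomically downstream of the TSS is upstream
  r <- assign_region_to_tss(reg(30000 + 1001), genes)
  expect_equal(r$gene_id, "gB")
  expect_equal(r$zone, "tss_up")
  # equidistant tie goes to the lower gene id
  r <- assign_region_to_tss(reg(20000), genes)
  expect_equal(r$gene_id, "gA")

  # zones partition any region set
  set.seed(3)
  mids <- sample.int(40000, 200)
  rr <- data.frame(chrom = "chr1", start = mids - 10, end = mids + 10)
  z <- assign_region_to_tss(rr, genes)$zone
  expect_equal(sum(z == "core") + sum(z == "tss_up") + sum(z == "tss_down"),
               200L)
})
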