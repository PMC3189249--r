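test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(n_genes = 60, seed = 1)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))
  t1 <- generate_truth(a1, cfg)
  t2 <- generate_truth(a2, cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_arrays(t1, a1, cfg)$log2,
                   simulate_arrays(t2, a2, cfg)$log2)
})

test_that("planted class counts and ICR records follow the configuration", {
  cfg <- sim_config(n_genes = 500, seed = 3)
  ann <- generate_annotation(cfg)
  tab <- table(ann$genes$class)
  expect_equal(unname(tab["common_germline"]), floor(0.04 * 500))
  expect_equal(unname(tab["imprinted"]), floor(0.008 * 500))
  expect_equal(unname(tab["tdmr"]), floor(0.02 * 500))
  expect_equal(nrow(ann$icrs), floor(0.008 * 500))

  cfg0 <- sim_config(n_genes = 200, seed = 3, frac_imprinted = 0)
  expect_equal(nrow(generate_annotation(cfg0)$icrs), 0L)

  expect_error(sim_config(n_genes = 100, frac_common_germline = 0.8,
                          frac_tdmr = 0.5), "sum")
})

test_that("realised CpG-high promoter fraction matches the configured fraction", {
  st <- small_study()
  ann <- st$sim$annotation
  # a promoter is CpG-high when some probe window reaches 25 CpG / 500 bp
  cnt <- tapply(ann$probes$cpg_count_500bp, ann$probes$gene_id, max)
  frac <- mean(cnt[ann$genes$gene_id] >= 25)
  expect_lt(abs(frac - st$cfg$frac_cpg_high), 0.02)
  # and the generating labels agree with the sequence-derived call
  expect_equal(as.vector(cnt[ann$genes$gene_id] >= 25),
               ann$genes$cpg_class == "high")
})

test_that("planted truth respects the class-level invariants", {
  st <- small_study()
  truth <- st$sim$truth
  roles <- default_sample_roles(st$cfg$samples)
  lev <- truth$levels
  cls <- truth$regions$class

  imp <- lev[cls == "imprinted", , drop = FALSE]
  expect_true(all(abs(imp - 0.5) < 1e-12))  # including sperm

  germ <- lev[cls == "common_germline", , drop = FALSE]
  expect_true(all(germ[, roles$somatic] >= 0.8))
  expect_true(all(germ[, roles$sperm] <= 0.1))
  expect_true(all(germ[, roles$es] <= 0.1))

  unm <- lev[cls == "unmethylated", , drop = FALSE]
  expect_true(all(unm <= 0.05))

  td <- truth$regions$class == "tdmr"
  layer_hits <- rowSums(lev[td, roles$germ_layers, drop = FALSE] > 0.5)
  expect_true(all(layer_hits == 1))  # exactly one germ layer
})

test_that("without T-DMRs all somatic samples share identical truth", {
  cfg <- sim_config(n_genes = 150, seed = 8, frac_tdmr = 0)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  roles <- default_sample_roles(cfg$samples)
  som <- truth$levels[, roles$somatic]
  expect_true(all(som == som[, 1]))
})

test_that("array log-ratios follow the closed-form enrichment model", {
  # no methylation anywhere -> zero expected MeDIP/input log-ratio
  cfg0 <- sim_config(n_genes = 80, seed = 4, frac_common_germline = 0,
                     frac_imprinted = 0, frac_tdmr = 0, frac_cluster = 0,
                     flank_meth_prob = 0)
  ann0 <- generate_annotation(cfg0)
  tr0 <- generate_truth(ann0, cfg0)
  ints0 <- simulate_arrays(tr0, ann0, cfg0)
  med <- ints0$arrays$channel == "MeDIP"
  lr <- rowMeans(ints0$log2[, med]) - rowMeans(ints0$log2[, !med])
  # truth levels are small but nonzero (<= 0.04); allow that offset
  expect_lt(abs(mean(lr)), 3 * stats::sd(lr) / sqrt(length(lr)) + 0.1)

  # saturating response is monotone in CpG count
  sat <- function(c) c / (c + cfg0$cpg_half)
  cc <- 1:60
  expect_true(all(diff(sat(cc)) > 0))
  expect_true(all(sat(2 * cc) > sat(cc)))

  # Monte-Carlo mean vs closed form at fixed methylation and CpG count
  st <- small_study()
  cfg <- st$cfg
  pm <- promethylome:::probe_methylation(st$sim$truth, st$sim$annotation)
  pr <- st$sim$annotation$probes
  sel <- which(pm[, "Ect"] >= 0.82 & pr$cpg_count_500bp >= 30)
  ints <- st$sim$intensities
  med_e <- ints$arrays$array_id[ints$arrays$sample == "Ect" &
                                  ints$arrays$channel == "MeDIP"]
  inp_e <- ints$arrays$array_id[ints$arrays$sample == "Ect" &
                                  ints$arrays$channel == "input"]
  lr <- rowMeans(ints$log2[sel, med_e]) - rowMeans(ints$log2[sel, inp_e])
  expected <- cfg$enrichment_slope * pm[sel, "Ect"] *
    pr$cpg_count_500bp[sel] / (pr$cpg_count_500bp[sel] + cfg$cpg_half)
  resid <- lr - expected
  expect_lt(abs(mean(resid)), 3 * stats::sd(resid) / sqrt(length(resid)))

  cfg_bad <- cfg0
  cfg_bad$noise_sd <- -1
  expect_error(simulate_arrays(tr0, ann0, cfg_bad), "noise_sd")
})

test_that("null log-ratio distribution matches its closed form (KS)", {
  cfg <- sim_config(n_genes = 400, seed = 6, frac_common_germline = 0,
                    frac_imprinted = 0, frac_tdmr = 0, frac_cluster = 0,
                    flank_meth_prob = 0)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  truth$levels[] <- 0  # exact null
  ints <- simulate_arrays(truth, ann, cfg)
  d <- ints$log2[, "Ect.MeDIP.1"] - ints$log2[, "Ect.input.1"]
  d <- d[seq_len(10000)]
  # probe effects cancel in the difference; residual is N(0, sqrt(2) sd)
  p <- stats::ks.test(d, "pnorm", 0, sqrt(2) * cfg$noise_sd)$p.value
  expect_gt(p, 0.01)
})

test_that("expression is mean-100 normalised and responds to core methylation", {
  st <- small_study()
  expr <- st$sim$expression
  expect_true(all(abs(colMeans(expr) - 100) < 1e-6))

  g <- st$sim$annotation$genes
  meth_ect <- g$gene_id[g$class %in% c("common_germline", "imprinted")]
  unmeth <- g$gene_id[g$class == "unmethylated"]
  expect_lt(stats::median(expr[meth_ect, "Ect"]),
            stats::median(expr[unmeth, "Ect"]))

  # germline genes are testis-specific on the ranking score
  roles <- default_sample_roles(st$cfg$samples)
  rk <- testis_score(expr, roles$somatic, st$cfg$testis_sample)
  sc <- stats::setNames(rk$score, rk$gene_id)
  germ <- g$gene_id[g$class == "common_germline"]
  expect_gte(mean(sc[germ] > 1), 0.9)
})

test_that("histone states come with consistent peaks and conditionals", {
  st <- small_study()
  hist <- st$sim$histone
  g <- st$sim$annotation$genes

  for (s in hist$samples) {
    st_s <- hist$states[, s]
    k4 <- hist$peaks[[s]]$K4
    k27 <- hist$peaks[[s]]$K27
    # bivalent genes have both peaks inside TSS +/- 2 kb, none genes neither
    biv <- names(st_s)[st_s == "bivalent"]
    expect_true(all(biv %in% k4$name) && all(biv %in% k27$name))
    non <- names(st_s)[st_s == "none"]
    expect_false(any(non %in% c(k4$name, k27$name)))
    # peaks overlap the window
    tssw <- data.frame(chrom = g$chrom, start = g$tss - 2000,
                       end = g$tss + 2001)
    ov <- GenomicRanges::countOverlaps(as_gr(k4), as_gr(tssw))
    expect_true(all(ov > 0))
    # round trip through the state-assignment operation
    back <- assign_histone_state(k4, k27, g)
    expect_equal(unname(back), unname(st_s[g$gene_id]))
  }

  # realised P(methylated | K4) within the binomial 95% CI of the target
  core <- grepl("_core$", st$sim$truth$regions$region_id)
  lev <- st$sim$truth$levels[core, ]
  rownames(lev) <- st$sim$truth$regions$gene_id[core]
  m <- lev[g$gene_id, "Ect"] >= 0.5
  k4_genes <- hist$states[, "Ect"] == "K4"
  n_k4 <- sum(k4_genes)
  phat <- mean(m[k4_genes])
  target <- st$cfg$p_meth_given_state[["K4"]]
  ci <- target + c(-1, 1) * 1.96 * sqrt(target * (1 - target) / n_k4)
  expect_gte(phat, ci[1])
  expect_lte(phat, ci[2])
})
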