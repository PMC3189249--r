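#' Simulation configuration for a synthetic promoter-methylome study
#'
#' Builds the parameter object consumed by [generate_annotation()],
#' [generate_truth()], [simulate_arrays()], [simulate_expression()] and
#' [simulate_histone()]. Defaults emulate a MeDIP promoter tiling-array
#' study: each promoter is covered by 25 probes spanning 6 kb upstream to
#' 2.5 kb downstream of the TSS, MeDIP enrichment grows with local CpG
#' density up to saturation, CpG-rich promoter cores are hypomethylated,
#' and the planted region classes (commonly methylated germline promoters,
#' imprinting centers, germ-layer T-DMRs, mosaic gene clusters, CpG-poor
#' constitutively methylated flanks) carry the cross-sample structure the
#' downstream analysis looks for.
#'
#' @param n_genes number of simulated promoters.
#' @param n_probes_per_promoter probes tiled across each promoter (>= 3).
#' @param promoter_span two integers, probe span relative to the TSS in bp.
#' @param samples ordered sample labels with methylation arrays. The default
#'   set is two ES lines, the three ES-derived germ layers (ectoderm,
#'   endoderm, paraxial mesoderm), three adult somatic tissues and sperm.
#' @param testis_sample label of the expression-only testis column (no
#'   methylation arrays are simulated for it).
#' @param frac_common_germline fraction of genes planted as commonly
#'   methylated germline promoters (methylated in every somatic sample,
#'   unmethylated in ES and sperm, expressed only in testis).
#' @param frac_imprinted fraction planted as imprinting centers
#'   (allelic level 0.5 in every sample including sperm).
#' @param frac_tdmr fraction planted as germ-layer T-DMRs (methylated in
#'   exactly one germ layer).
#' @param frac_tdmr_maintained fraction of T-DMRs whose methylation is
#'   maintained in the matched adult tissue; the rest are early-only.
#' @param frac_cluster fraction planted as cluster genes with mosaic
#'   (intermediate, variable) somatic methylation, laid out as runs of
#'   adjacent genes.
#' @param flank_meth_prob per-side probability that a non-planted gene
#'   carries a CpG-poor constitutively methylated promoter flank. These
#'   flanks produce the V-shaped methylation frequency profile around the
#'   TSS and are below the CpG-density gate.
#' @param frac_cpg_high,frac_cpg_low fractions of promoters with high
#'   (>= 5% CpG/500 bp core island) and low (< 4%) CpG density; the
#'   remainder is intermediate. Planted methylated classes are always
#'   CpG-high so that they survive the density gate.
#' @param enrichment_slope expected MeDIP log2-ratio per unit methylation at
#'   CpG saturation.
#' @param cpg_half CpG count per 500 bp at which enrichment reaches half its
#'   saturating value.
#' @param noise_sd array noise standard deviation on the log2 scale.
#' @param probe_effect_sd standard deviation of per-probe affinity effects
#'   (shared across arrays, cancelled by the MeDIP - input contrast).
#' @param replicates number of MeDIP and of input arrays per sample (>= 1).
#' @param expr_base_log2,expr_sd_log2 mean/sd of baseline log2 expression.
#' @param expr_suppression log2 drop in expression when the core promoter is
#'   methylated in a sample.
#' @param p_meth_given_state named numeric: target probability that a gene
#'   is core-promoter methylated given each histone state. H3K4me3 must be
#'   the minimum (the marks are mutually exclusive with DNA methylation).
#' @param histone_samples samples for which histone maps are simulated
#'   (ES-like, differentiated-like, adult-like).
#' @param seed integer master seed; every simulated quantity is a
#'   deterministic function of it.
#' @return a list of class `sim_config` with validated fields.
#' @export
sim_config <- function(n_genes = 5000L,
                       n_probes_per_promoter = 25L,
                       promoter_span = c(-6000L, 2500L),
                       samples = c("ES1", "ES2", "Ect", "End", "Pme",
                                   "Brain", "Liver", "Muscle", "Sperm"),
                       testis_sample = "Testis",
                       frac_common_germline = 0.04,
                       frac_imprinted = 0.008,
                       frac_tdmr = 0.02,
                       frac_tdmr_maintained = 0.1,
                       frac_cluster = 0.015,
                       flank_meth_prob = 0.7,
                       frac_cpg_high = 0.5,
                       frac_cpg_low = 0.2,
                       enrichment_slope = 4.0,
                       cpg_half = 5,
                       noise_sd = 0.35,
                       probe_effect_sd = 0.15,
                       replicates = 2L,
                       expr_base_log2 = 7,
                       expr_sd_log2 = 1.5,
                       expr_suppression = 3,
                       p_meth_given_state = c(K4 = 0.02, K27 = 0.25,
                                              bivalent = 0.15, none = 0.35),
                       histone_samples = c("ES1", "Ect", "Brain"),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_probes_per_promoter = as.integer(n_probes_per_promoter),
    promoter_span = as.integer(promoter_span),
    samples = as.character(samples),
    testis_sample = as.character(testis_sample),
    frac_common_germline = frac_common_germline,
    frac_imprinted = frac_imprinted,
    frac_tdmr = frac_tdmr,
    frac_tdmr_maintained = frac_tdmr_maintained,
    frac_cluster = frac_cluster,
    flank_meth_prob = flank_meth_prob,
    frac_cpg_high = frac_cpg_high,
    frac_cpg_low = frac_cpg_low,
    enrichment_slope = enrichment_slope,
    cpg_half = cpg_half,
    noise_sd = noise_sd,
    probe_effect_sd = probe_effect_sd,
    replicates = as.integer(replicates),
    expr_base_log2 = expr_base_log2,
    expr_sd_log2 = expr_sd_log2,
    expr_suppression = expr_suppression,
    p_meth_given_state = p_meth_given_state,
    histone_samples = as.character(histone_samples),
    seed = as.integer(seed),
    # fixed layout constants (documented in the methods vignette)
    probe_len = 60L,
    gene_spacing = 10000L,
    core_region = c(-800L, 400L),
    island_span = c(-1200L, 700L),
    island_cpg_per_500 = c(high = 34, intermediate = 22, low = 5),
    background_cpg_per_500 = 5,
    island_gc = 0.52,
    background_gc = 0.42
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_genes) || cfg$n_genes < 1)
    stopf("n_genes must be a positive integer")
  if (cfg$n_probes_per_promoter < 3L)
    stopf("n_probes_per_promoter must be >= 3")
  if (cfg$replicates < 1L) stopf("replicates must be >= 1")
  if (length(cfg$promoter_span) != 2L ||
      cfg$promoter_span[1] >= cfg$promoter_span[2])
    stopf("promoter_span must be an increasing bp interval")
  fracs <- c(cfg$frac_common_germline, cfg$frac_imprinted, cfg$frac_tdmr,
             cfg$frac_cluster)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1)
    stopf("planted-class fractions must lie in [0,1] and sum to <= 1")
  if (cfg$frac_cpg_high + cfg$frac_cpg_low > 1)
    stopf("frac_cpg_high + frac_cpg_low must be <= 1")
  if (cfg$frac_cpg_high < sum(fracs))
    stopf("frac_cpg_high must cover all planted methylated classes")
  if (cfg$noise_sd < 0) stopf("noise_sd must be non-negative")
  if (anyDuplicated(cfg$samples)) stopf("duplicate sample labels")
  if (cfg$testis_sample %in% cfg$samples)
    stopf("testis_sample is expression-only and must not appear in samples")
  states <- c("K4", "K27", "bivalent", "none")
  if (!all(states %in% names(cfg$p_meth_given_state)))
    stopf("p_meth_given_state needs entries K4, K27, bivalent, none")
  if (!all(cfg$histone_samples %in% cfg$samples))
    stopf("histone_samples must be a subset of samples")
  invisible(cfg)
}

#' Default sample-role assignment for the simulated study design
#'
#' @param samples character vector of sample labels.
#' @return list with elements `es`, `germ_layers`, `adult`, `sperm`, and
#'   `somatic` (= germ layers plus adult tissues).
#' @export
default_sample_roles <- function(samples = sim_config(n_genes = 10)$samples) {
  roles <- list(
    es = intersect(c("ES1", "ES2"), samples),
    germ_layers = intersect(c("Ect", "End", "Pme"), samples),
    adult = intersect(c("Brain", "Liver", "Muscle"), samples),
    sperm = intersect("Sperm", samples)
  )
  roles$somatic <- c(roles$germ_layers, roles$adult)
  roles
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic MeDIP-chip study configuration\n")
  cat(sprintf("  %d genes x %d probes (%d..%d bp of TSS), %d+%d arrays/sample\n",
              x$n_genes, x$n_probes_per_promoter, x$promoter_span[1],
              x$promoter_span[2], x$replicates, x$replicates))
  cat(sprintf("  samples: %s (+ %s, expression only)\n",
              paste(x$samples, collapse = ", "), x$testis_sample))
  cat(sprintf("  planted fractions: germline %.3f, imprinted %.3f, T-DMR %.3f, cluster %.3f\n",
              x$frac_common_germline, x$frac_imprinted, x$frac_tdmr,
              x$frac_cluster))
  invisible(x)
}
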