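# End-to-end pipeline: simulate -> score -> call -> compare -> GSEA ->
# integrate, with all stage outputs written as plain-text tables and a
# manifest recording parameters, seeds and a parameter hash.

#' Pipeline configuration
#'
#' Collects every stage parameter with the study's defaults: probe calling
#' threshold 2.5, high-confidence threshold 3.0, hypomethylation threshold
#' 1.5, CpG-density gate 5%, core promoter -1.5 kb..+0.5 kb (zone tables
#' -1 kb..+0.5 kb), histone TSS window +/- 2 kb, 1000 gene permutations,
#' expression normalised to array mean 100.
#'
#' @param sim a [sim_config()] for the synthetic study.
#' @param window_bp,trim_frac,min_probes probe-score parameters.
#' @param call_threshold,hc_threshold,hypo_threshold,min_cpg_density CMR
#'   thresholds.
#' @param max_gap_bp largest bridged inter-probe gap.
#' @param core_zone,core_window zone-table and gene-call windows (bp).
#' @param histone_window TSS window half-width for histone states (bp).
#' @param n_perm GSEA permutations.
#' @param gsea_seed seed for the permutation null.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            window_bp = 800, trim_frac = 0.1,
                            min_probes = 3L,
                            call_threshold = 2.5, hc_threshold = 3.0,
                            hypo_threshold = 1.5, min_cpg_density = 5.0,
                            max_gap_bp = 400,
                            core_zone = c(-1000, 500),
                            core_window = c(-1500, 500),
                            histone_window = 2000L,
                            n_perm = 1000L,
                            gsea_seed = sim$seed + 7L) {
  if (!(hypo_threshold < call_threshold && call_threshold < hc_threshold))
    stopf("thresholds must satisfy hypo < methylated < high-confidence")
  structure(list(sim = sim, window_bp = window_bp, trim_frac = trim_frac,
                 min_probes = min_probes, call_threshold = call_threshold,
                 hc_threshold = hc_threshold, hypo_threshold = hypo_threshold,
                 min_cpg_density = min_cpg_density, max_gap_bp = max_gap_bp,
                 core_zone = core_zone, core_window = core_window,
                 histone_window = histone_window, n_perm = n_perm,
                 gsea_seed = gsea_seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # parameter hash: serialise deterministically to YAML, then md5
  flat <- unclass(config)
  flat$sim <- unclass(flat$sim)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(flat, precision = 12), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates the study, scores probes, calibrates the empirical FDR,
#' calls and filters CMRs, builds the TSS profile and summary tables,
#' categorises commonality, extracts T-DMRs, runs the testis-specificity
#' GSEA on the commonly methylated core-promoter gene set, and integrates
#' histone states. All tables are written to `out_dir` together with a
#' manifest; reruns with the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return list with every stage result (`annotation`, `truth`, `track`,
#'   `null_track`, `fdr`, `cmrs`, `profile`, `tables`, `commonality`,
#'   `tdmrs`, `expression`, `ranked`, `gsea`, `histone`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  cfg <- config
  sim <- stage("simulate", simulate_methylome_study(cfg$sim))
  roles <- default_sample_roles(cfg$sim$samples)

  std <- stage("standardize", standardize_arrays(sim$intensities))
  track <- stage("score", score_probes(std, window_bp = cfg$window_bp,
                                       trim_frac = cfg$trim_frac,
                                       min_probes = cfg$min_probes))
  null_track <- stage("score", score_probes(std, window_bp = cfg$window_bp,
                                            trim_frac = cfg$trim_frac,
                                            min_probes = cfg$min_probes,
                                            null_swap = TRUE))
  fdr <- stage("fdr", estimate_fdr(track, null_track,
                                   thresholds = c(cfg$hypo_threshold,
                                                  cfg$call_threshold,
                                                  cfg$hc_threshold, 4.0)))
  cmrs <- stage("call", call_cmrs(track, cfg$call_threshold, cfg$max_gap_bp,
                                  cfg$min_cpg_density, cfg$hc_threshold))
  genes <- sim$annotation$genes
  profile_sample <- roles$germ_layers[1]
  profile <- stage("profile", tss_profile(track, genes, profile_sample,
                                          span = cfg$sim$promoter_span))
  tables <- stage("tables", methylation_tables(cmrs, sim$annotation$cpg_islands,
                                               genes))
  commonality <- stage("commonality", categorize_commonality(cmrs, roles))
  tdmrs <- stage("tdmr", extract_tdmrs(cmrs))

  ranked <- stage("gsea", testis_score(sim$expression, roles$somatic,
                                       cfg$sim$testis_sample))
  calls <- stage("integrate", gene_methyl_calls(cmrs, genes, cfg$core_window))
  common_set <- stage("gsea", {
    idx <- commonality$category %in% c("somatic_common", "all_positive")
    asg <- if (any(idx))
      assign_region_to_tss(as.data.frame(cmrs)[idx, c("chrom", "start", "end")],
                           genes, core_zone = cfg$core_window)
    else NULL
    unique(asg$gene_id[asg$tss_offset >= cfg$core_window[1] &
                         asg$tss_offset <= cfg$core_window[2]])
  })
  gsea <- if (length(common_set) >= 3L)
    stage("gsea", permutation_test(ranked, common_set, n = cfg$n_perm,
                                   seed = cfg$gsea_seed))
  else NULL

  hist_states <- sim$histone$states
  meth_by_state <- stage("integrate", lapply(
    stats::setNames(colnames(hist_states), colnames(hist_states)),
    function(s) methylation_by_state(hist_states[, s], calls[, s])))
  transitions <- if (ncol(hist_states) >= 2L) {
    s1 <- colnames(hist_states)[1]; s2 <- colnames(hist_states)[2]
    stage("integrate", transition_table(hist_states[, s1], hist_states[, s2],
                                        calls[, s2]))
  } else NULL

  manifest <- list(package_version = as.character(utils::packageVersion("promethylome")),
                   seed = cfg$sim$seed, gsea_seed = cfg$gsea_seed,
                   parameter_hash = config_hash(cfg),
                   n_genes = cfg$sim$n_genes,
                   n_cmrs = nrow(cmrs))

  res <- list(annotation = sim$annotation, truth = sim$truth,
              expression = sim$expression, histone = sim$histone,
              track = track, null_track = null_track, fdr = fdr,
              cmrs = cmrs, profile = profile, tables = tables,
              commonality = commonality, tdmrs = tdmrs, ranked = ranked,
              gene_calls = calls, common_set = common_set, gsea = gsea,
              meth_by_state = meth_by_state, transitions = transitions,
              manifest = manifest, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write all pipeline outputs as plain-text tables
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_intervals(res$annotation$cpg_islands, p("cpg_islands.bed"), "BED")
  write_intervals(res$annotation$icrs, p("icrs.bed"), "BED")
  write_tsv(res$annotation$genes, p("genes.tsv"))
  write_tsv(res$annotation$probes, p("probes.tsv"))
  write_tsv(cbind(res$truth$regions, res$truth$levels), p("truth.tsv"))
  scores <- data.frame(probe_id = rownames(res$track$scores),
                       res$track$scores, check.names = FALSE)
  write_tsv(scores, p("scores.tsv"))
  for (s in colnames(res$track$scores))
    write_score_bedgraph(res$track, s, p(sprintf("scores_%s.bedgraph", s)))
  write_tsv(res$fdr, p("fdr.tsv"))
  cm <- as.data.frame(res$cmrs)
  cm$category <- if (nrow(cm) > 0) res$commonality$category else character(0)
  write_tsv(cm, p("cmrs.tsv"))
  write_tsv(res$profile, p("tss_profile.tsv"))
  write_tsv(res$tables$islands, p("table_cpg_islands.tsv"))
  write_tsv(res$tables$zones, p("table_zones.tsv"))
  write_tsv(res$commonality$counts, p("table_commonality.tsv"))
  write_tsv(as.data.frame(res$tdmrs$contrasts), p("tdmr_contrasts.tsv"))
  expr <- data.frame(gene_id = rownames(res$expression), res$expression,
                     check.names = FALSE)
  write_tsv(expr, p("expression.tsv"))
  write_tsv(res$ranked, p("testis_ranking.tsv"))
  if (!is.null(res$gsea))
    write_tsv(data.frame(es = res$gsea$es, nes = res$gsea$nes,
                         p = res$gsea$p, set_size = res$gsea$set_size,
                         n_permutations = res$gsea$n_permutations),
              p("gsea.tsv"))
  for (s in names(res$meth_by_state))
    write_tsv(res$meth_by_state[[s]], p(sprintf("meth_by_state_%s.tsv", s)))
  if (!is.null(res$transitions))
    write_tsv(res$transitions, p("transitions.tsv"))
  writeLines(yaml::as.yaml(res$manifest), p("manifest.yaml"))
  invisible(out_dir)
}
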