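# Shared fixtures. Simulated studies are cached per session so several
# test files can reuse the same run without repeating the simulation.

.sim_cache <- new.env(parent = emptyenv())

cached_study <- function(n_genes, seed, ...) {
  key <- paste0("n", n_genes, "_s", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
    sim <- simulate_methylome_study(cfg)
    track <- score_probes(standardize_arrays(sim$intensities))
    null_track <- score_probes(standardize_arrays(sim$intensities),
                               null_swap = TRUE)
    cmrs <- call_cmrs(track)
    .sim_cache[[key]] <- list(cfg = cfg, sim = sim, track = track,
                              null_track = null_track, cmrs = cmrs)
  }
  .sim_cache[[key]]
}

# small study for property tests
small_study <- function() cached_study(400, seed = 42)
# full-scale study for the acceptance properties
full_study <- function() cached_study(5000, seed = 20260926)

as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

point_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
}

# hand-built score track: one chromosome, evenly spaced probes
make_track <- function(scores, spacing = 350, probe_len = 60,
                       cpg_density = 6, start0 = 1000) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  centers <- start0 + spacing * (seq_len(n) - 1L)
  probes <- data.frame(
    probe_id = sprintf("p%03d", seq_len(n)), chrom = "chrT",
    start = centers - probe_len %/% 2L,
    end = centers + probe_len %/% 2L, center = centers,
    cpg_density = rep_len(cpg_density, n)
  )
  structure(list(probes = probes, scores = scores,
                 params = list(window_bp = 800, trim_frac = 0.1,
                               min_probes = 3, null_swap = FALSE)),
            class = "score_track")
}

# hand-built CMR set from a samples-named score matrix
make_cmr_set <- function(score_matrix, cpg_density = 6) {
  score_matrix <- as.matrix(score_matrix)
  n <- nrow(score_matrix)
  out <- data.frame(region_id = sprintf("r%03d", seq_len(n)),
                    chrom = rep("chrT", n),
                    start = 1000L + 2000L * (seq_len(n) - 1L),
                    end = 2200L + 2000L * (seq_len(n) - 1L),
                    n_probes = rep(3L, n),
                    cpg_density = rep_len(cpg_density, n))
  for (s in colnames(score_matrix))
    out[[paste0("score_", s)]] <- score_matrix[, s]
  for (s in colnames(score_matrix))
    out[[paste0("state_", s)]] <- call_state(score_matrix[, s])
  structure(out, class = c("cmr_set", "data.frame"))
}
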