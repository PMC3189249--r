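# Synthetic MeDIP promoter-array study generator.
#
# One synthetic chromosome ("chrS") is built from fixed-width gene blocks.
# Promoter sequences get their CpGs planted on a jittered grid whose rate
# depends on the promoter CpG class; accidental CG dinucleotides arising
# from the background base composition are removed first, so realised
# window densities track the planted rates closely. Methylation truth is
# planted per region and per sample role, array intensities add probe
# affinity effects and Gaussian log-scale noise, and expression / histone
# states are generated conditionally on the planted methylation.

BASES <- c("A", "C", "G", "T")

t2g <- function(tss, dir, rel) {
  a <- tss + dir * rel[1]
  b <- tss + dir * rel[2]
  c(start = min(a, b), end = max(a, b))
}

gc_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

# jittered CpG grid positions (0-based) within [from, to)
cpg_grid <- function(from, to, step, jitter) {
  if (to - from < step) return(integer(0))
  g <- seq(from + step %/% 2, to - 2L, by = step)
  g <- g + sample(seq(-jitter, jitter), length(g), replace = TRUE)
  g <- g[g >= from & g <= to - 2L]
  g[c(TRUE, diff(g) >= 2L)]
}

#' Generate a synthetic genome annotation
#'
#' Builds the gene models, probe layout, chromosome sequence, CpG islands
#' and imprinting-center records for a simulated promoter-methylome study.
#' Planted special classes (commonly methylated germline promoters,
#' imprinting centers, T-DMRs, mosaic clusters) are assigned here, with
#' exactly `floor(fraction * n_genes)` genes per class, and are always
#' placed on CpG-high promoters so that they pass the density gate.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `methylome_annotation`: a list with `genes`,
#'   `probes`, `cpg_islands`, `icrs` data.frames (0-based half-open
#'   coordinates), the chromosome `sequence`, and the `config`.
#' @export
generate_annotation <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_genes
  spacing <- cfg$gene_spacing

  ids <- sprintf("g%05d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  block0 <- (seq_len(n) - 1L) * spacing
  tss <- block0 + ifelse(strand == "+", 6250L, 3750L)
  dir <- ifelse(strand == "-", -1L, 1L)

  # ---- planted classes ------------------------------------------------
  class <- rep("unmethylated", n)
  k_cluster <- floor(cfg$frac_cluster * n)
  run_len <- 5L
  if (k_cluster > 0L) {
    placed <- 0L
    for (s0 in sample.int(max(1L, n - run_len + 1L))) {
      if (placed >= k_cluster) break
      len <- min(run_len, k_cluster - placed)
      idx <- s0:(s0 + len - 1L)
      if (all(class[idx] == "unmethylated")) {
        class[idx] <- "cluster_mosaic"
        placed <- placed + len
      }
    }
    if (placed < k_cluster)
      stopf("could not place %d cluster genes; increase n_genes", k_cluster)
  }
  free <- which(class == "unmethylated")
  k_cg <- floor(cfg$frac_common_germline * n)
  k_imp <- floor(cfg$frac_imprinted * n)
  k_td <- floor(cfg$frac_tdmr * n)
  if (length(free) < k_cg + k_imp + k_td)
    stopf("n_genes too small for the planted special classes")
  pick <- sample(free, k_cg + k_imp + k_td)
  class[pick[seq_len(k_cg)]] <- "common_germline"
  if (k_imp > 0) class[pick[k_cg + seq_len(k_imp)]] <- "imprinted"
  if (k_td > 0) class[pick[k_cg + k_imp + seq_len(k_td)]] <- "tdmr"

  # T-DMR layer assignment and adult maintenance
  tdmr_layer <- rep(NA_character_, n)
  tdmr_maintained <- rep(FALSE, n)
  td_idx <- which(class == "tdmr")
  if (length(td_idx) > 0L) {
    layers <- c("Ect", "End", "Pme")
    tdmr_layer[td_idx] <- layers[(seq_along(td_idx) - 1L) %% 3L + 1L]
    n_keep <- floor(cfg$frac_tdmr_maintained * length(td_idx))
    if (n_keep > 0L)
      tdmr_maintained[sample(td_idx, n_keep)] <- TRUE
  }

  # ---- promoter CpG classes -------------------------------------------
  special <- class != "unmethylated"
  cpg_class <- rep("intermediate", n)
  cpg_class[special] <- "high"
  n_high <- max(floor(cfg$frac_cpg_high * n), sum(special))
  pool <- which(!special)
  extra_high <- sample(pool, n_high - sum(special))
  cpg_class[extra_high] <- "high"
  pool <- setdiff(pool, extra_high)
  n_low <- min(floor(cfg$frac_cpg_low * n), length(pool))
  cpg_class[sample(pool, n_low)] <- "low"

  # ---- chromosome sequence --------------------------------------------
  N <- n * spacing
  seq_vec <- sample(BASES, N, replace = TRUE, prob = gc_probs(cfg$background_gc))

  has_island <- cpg_class != "low"
  isl <- t(vapply(which(has_island), function(i)
    t2g(tss[i], dir[i], cfg$island_span), c(start = 0, end = 0)))
  if (nrow(isl) > 0L) {
    isl_idx <- unlist(mapply(function(s, e) (s + 1L):e,
                             isl[, "start"], isl[, "end"], SIMPLIFY = FALSE))
    seq_vec[isl_idx] <- sample(BASES, length(isl_idx), replace = TRUE,
                               prob = gc_probs(cfg$island_gc))
  }
  # remove accidental CG dinucleotides (single pass: G -> A)
  acc <- which(seq_vec[-N] == "C" & seq_vec[-1L] == "G")
  if (length(acc) > 0L) seq_vec[acc + 1L] <- "A"

  # planted CpG grids: background everywhere, denser inside islands
  bg_step <- round(500 / cfg$background_cpg_per_500)
  grid <- lapply(seq_len(n), function(i) {
    b0 <- block0[i]
    g_bg <- cpg_grid(b0, b0 + spacing, bg_step, jitter = 20L)
    if (has_island[i]) {
      ii <- t2g(tss[i], dir[i], cfg$island_span)
      rate <- cfg$island_cpg_per_500[[cpg_class[i]]]
      g_is <- cpg_grid(ii["start"], ii["end"], round(500 / rate), jitter = 3L)
      g_bg <- g_bg[g_bg < ii["start"] - 2L | g_bg >= ii["end"] + 2L]
      g_bg <- sort(c(g_bg, g_is))
    }
    g_bg
  })
  gpos <- unlist(grid)
  gpos <- gpos[c(TRUE, diff(gpos) >= 2L)]
  seq_vec[gpos + 1L] <- "C"
  seq_vec[gpos + 2L] <- "G"
  chrom_seq <- paste(seq_vec, collapse = "")

  # ---- probes ----------------------------------------------------------
  np <- cfg$n_probes_per_promoter
  rel <- round(seq(cfg$promoter_span[1], cfg$promoter_span[2],
                   length.out = np))
  centers <- rep(tss, each = np) + rep(dir, each = np) * rel +
    sample(-60:60, n * np, replace = TRUE)
  half_len <- cfg$probe_len %/% 2L
  probes <- data.frame(
    probe_id = sprintf("%s_p%02d", rep(ids, each = np), rep(seq_len(np), n)),
    gene_id = rep(ids, each = np),
    chrom = "chrS",
    start = centers - half_len,
    end = centers + (cfg$probe_len - half_len),
    center = centers
  )
  probes <- probes[order(probes$center), , drop = FALSE]
  rownames(probes) <- NULL
  dens <- probe_cpg_content(probes$center, chrom_seq)
  probes$cpg_density <- dens
  probes$cpg_count_500bp <- round(dens * 5)

  islands_df <- if (nrow(isl) > 0L)
    data.frame(chrom = "chrS", start = as.integer(isl[, "start"]),
               end = as.integer(isl[, "end"]),
               name = ids[has_island]) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())

  imp <- which(class == "imprinted")
  icrs_df <- if (length(imp) > 0L) {
    cc <- t(vapply(imp, function(i) t2g(tss[i], dir[i], cfg$core_region),
                   c(start = 0, end = 0)))
    data.frame(chrom = "chrS", start = as.integer(cc[, "start"]),
               end = as.integer(cc[, "end"]), name = ids[imp])
  } else data.frame(chrom = character(), start = integer(),
                    end = integer(), name = character())

  genes <- data.frame(
    gene_id = ids, chrom = "chrS", tss = tss, strand = strand,
    class = class, cpg_class = cpg_class,
    tdmr_layer = tdmr_layer, tdmr_maintained = tdmr_maintained
  )
  structure(list(genes = genes, probes = probes, cpg_islands = islands_df,
                 icrs = icrs_df, sequence = c(chrS = chrom_seq),
                 config = cfg),
            class = "methylome_annotation")
}

#' @export
print.methylome_annotation <- function(x, ...) {
  cat(sprintf("methylome_annotation: %d genes, %d probes, %d CpG islands, %d ICRs\n",
              nrow(x$genes), nrow(x$probes), nrow(x$cpg_islands),
              nrow(x$icrs)))
  print(table(x$genes$class))
  invisible(x)
}

#' Plant the true methylome
#'
#' Turns the annotation's planted gene classes into per-region, per-sample
#' methylation levels in \[0,1\]. Levels are drawn once per region and
#' shared across samples of the same role, so sample-to-sample differences
#' come only from the planted class structure: germline promoters are
#' methylated in every somatic sample and unmethylated in ES and sperm,
#' imprinting centers sit at the allelic level 0.5 everywhere, T-DMRs are
#' methylated in exactly one germ layer (a configured subset also in the
#' matched adult tissue), cluster genes carry intermediate mosaic levels in
#' all somatic samples, and CpG-poor promoter flanks are constitutively
#' methylated.
#'
#' @param annotation a `methylome_annotation`.
#' @param config the [sim_config()] used to build it.
#' @param roles sample roles, see [default_sample_roles()].
#' @return object of class `methylome_truth`: list with `regions`
#'   (region_id, gene_id, chrom, start, end, class) and `levels`
#'   (regions x samples matrix).
#' @export
generate_truth <- function(annotation, config,
                           roles = default_sample_roles(config$samples)) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 2L))
  g <- annotation$genes
  n <- nrow(g)
  dir <- ifelse(g$strand == "-", -1L, 1L)
  samples <- cfg$samples
  adult_for <- stats::setNames(roles$adult[seq_along(roles$germ_layers)],
                               roles$germ_layers)

  reg <- list(); lev <- list()
  add_region <- function(id, gi, start, end, class, level_by_sample) {
    reg[[length(reg) + 1L]] <<- data.frame(
      region_id = id, gene_id = gi, chrom = "chrS",
      start = as.integer(start), end = as.integer(end), class = class)
    lev[[length(lev) + 1L]] <<- level_by_sample
  }
  base_low <- function() stats::runif(1, 0, 0.04)

  for (i in seq_len(n)) {
    cc <- t2g(g$tss[i], dir[i], cfg$core_region)
    lv <- stats::setNames(rep(base_low(), length(samples)), samples)
    cl <- g$class[i]
    if (cl == "common_germline") {
      lv[roles$somatic] <- stats::runif(1, 0.82, 0.95)
    } else if (cl == "imprinted") {
      lv[] <- 0.5
    } else if (cl == "tdmr") {
      lv[g$tdmr_layer[i]] <- stats::runif(1, 0.82, 0.92)
      if (g$tdmr_maintained[i])
        lv[adult_for[[g$tdmr_layer[i]]]] <- stats::runif(1, 0.82, 0.92)
    } else if (cl == "cluster_mosaic") {
      lv[roles$somatic] <- stats::runif(1, 0.35, 0.75)
    }
    add_region(paste0(g$gene_id[i], "_core"), g$gene_id[i],
               cc["start"], cc["end"], cl, lv)

    if (cl == "unmethylated") {
      # CpG-poor constitutively methylated flanks
      if (stats::runif(1) < cfg$flank_meth_prob) {
        ru <- stats::runif(1, 400, -cfg$promoter_span[1])
        if (-cfg$promoter_span[1] - ru >= 400) {
          fl <- t2g(g$tss[i], dir[i], c(cfg$promoter_span[1], -round(ru)))
          add_region(paste0(g$gene_id[i], "_up"), g$gene_id[i],
                     fl["start"], fl["end"], "low_cpg_constitutive",
                     stats::setNames(rep(stats::runif(1, 0.8, 0.9),
                                         length(samples)), samples))
        }
      }
      if (stats::runif(1) < cfg$flank_meth_prob) {
        rd <- stats::runif(1, 500, cfg$promoter_span[2] - 100)
        fl <- t2g(g$tss[i], dir[i], c(round(rd), cfg$promoter_span[2]))
        add_region(paste0(g$gene_id[i], "_down"), g$gene_id[i],
                   fl["start"], fl["end"], "low_cpg_constitutive",
                   stats::setNames(rep(stats::runif(1, 0.8, 0.9),
                                       length(samples)), samples))
      }
    }
  }
  regions <- do.call(rbind, reg)
  levels <- do.call(rbind, lev)
  rownames(levels) <- regions$region_id
  structure(list(regions = regions, levels = levels, samples = samples),
            class = "methylome_truth")
}

#' @export
print.methylome_truth <- function(x, ...) {
  cat(sprintf("methylome_truth: %d regions x %d samples\n",
              nrow(x$regions), ncol(x$levels)))
  print(table(x$regions$class))
  invisible(x)
}

# per-probe methylation level matrix (probes x samples) from planted truth
probe_methylation <- function(truth, annotation) {
  pr <- annotation$probes
  m <- matrix(0, nrow(pr), length(truth$samples),
              dimnames = list(pr$probe_id, truth$samples))
  by_gene <- split(seq_len(nrow(pr)), pr$gene_id)
  rg <- truth$regions
  for (k in seq_len(nrow(rg))) {
    pi <- by_gene[[rg$gene_id[k]]]
    if (is.null(pi)) next
    hit <- pi[pr$center[pi] >= rg$start[k] & pr$center[pi] < rg$end[k]]
    if (length(hit) > 0L)
      m[hit, ] <- pmax(m[hit, , drop = FALSE],
                       matrix(truth$levels[k, ], length(hit),
                              ncol(m), byrow = TRUE))
  }
  m
}

#' Simulate MeDIP and input tiling arrays
#'
#' Expected MeDIP log2 enrichment per probe is
#' `enrichment_slope * methylation * c/(c + cpg_half)` where `c` is the
#' probe's CpG count per 500 bp — a saturating response to local CpG
#' density. Input arrays have zero expected enrichment. Every array adds
#' the shared per-probe affinity effect plus independent Gaussian noise on
#' the log2 scale (lognormal multiplicative intensity noise).
#'
#' @param truth a `methylome_truth`.
#' @param annotation the matching `methylome_annotation`.
#' @param config the [sim_config()].
#' @return object of class `medip_intensities`: list with `log2` (probes x
#'   arrays matrix), `arrays` (array metadata: array_id, sample, channel,
#'   replicate) and `probes` (the probe table).
#' @export
simulate_arrays <- function(truth, annotation, config) {
  cfg <- config
  if (cfg$noise_sd < 0) stopf("noise_sd must be non-negative")
  set.seed(derive_seed(cfg$seed, 3L))
  pr <- annotation$probes
  meth <- probe_methylation(truth, annotation)
  cpg <- pr$cpg_density * 5  # CpG count per 500 bp
  sat <- cpg / (cpg + cfg$cpg_half)
  enr <- cfg$enrichment_slope * meth * sat  # probes x samples

  r <- cfg$replicates
  arrays <- expand.grid(replicate = seq_len(r),
                        channel = c("MeDIP", "input"),
                        sample = truth$samples,
                        stringsAsFactors = FALSE)
  arrays <- arrays[, c("sample", "channel", "replicate")]
  arrays$array_id <- sprintf("%s.%s.%d", arrays$sample, arrays$channel,
                             arrays$replicate)
  probe_effect <- stats::rnorm(nrow(pr), 0, cfg$probe_effect_sd)
  log2m <- matrix(0, nrow(pr), nrow(arrays),
                  dimnames = list(pr$probe_id, arrays$array_id))
  for (j in seq_len(nrow(arrays))) {
    mu <- probe_effect
    if (arrays$channel[j] == "MeDIP") mu <- mu + enr[, arrays$sample[j]]
    log2m[, j] <- mu + stats::rnorm(nrow(pr), 0, cfg$noise_sd)
  }
  structure(list(log2 = log2m, arrays = arrays, probes = pr),
            class = "medip_intensities")
}

#' Simulate the expression matrix
#'
#' Baseline log2 expression is Gaussian per gene; core-promoter
#' methylation in a sample lowers log2 expression by
#' `expr_suppression * level`. Planted germline genes are highly expressed
#' only in the testis column (which is expression-only and inherits the
#' germ-line methylation state). Columns are globally normalised so that
#' every array mean equals 100 on the linear scale.
#'
#' @inheritParams simulate_arrays
#' @return genes x samples numeric matrix (linear scale, column means 100).
#'   Columns are the non-sperm methylation samples plus the testis column.
#' @export
simulate_expression <- function(truth, annotation, config,
                                roles = default_sample_roles(config$samples)) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 4L))
  g <- annotation$genes
  n <- nrow(g)
  expr_samples <- c(setdiff(cfg$samples, roles$sperm), cfg$testis_sample)

  core <- truth$regions$class != "low_cpg_constitutive" &
    grepl("_core$", truth$regions$region_id)
  core_lev <- truth$levels[core, , drop = FALSE]
  rownames(core_lev) <- truth$regions$gene_id[core]
  core_lev <- core_lev[g$gene_id, , drop = FALSE]

  base <- stats::rnorm(n, cfg$expr_base_log2, cfg$expr_sd_log2)
  germ <- g$class == "common_germline"
  base[germ] <- stats::rnorm(sum(germ), 4, 1)
  testis_base <- base
  testis_base[germ] <- stats::rnorm(sum(germ), 9, 1)

  log2e <- matrix(NA_real_, n, length(expr_samples),
                  dimnames = list(g$gene_id, expr_samples))
  sperm_col <- if (length(roles$sperm) > 0) roles$sperm[1] else NULL
  for (s in expr_samples) {
    if (s == cfg$testis_sample) {
      lev <- if (!is.null(sperm_col)) core_lev[, sperm_col] else 0
      log2e[, s] <- testis_base - cfg$expr_suppression * lev +
        stats::rnorm(n, 0, 0.3)
    } else {
      log2e[, s] <- base - cfg$expr_suppression * core_lev[, s] +
        stats::rnorm(n, 0, 0.3)
    }
  }
  lin <- 2^log2e
  sweep(lin, 2, colMeans(lin), "/") * 100
}

# Solve P(state | methylated) and P(state | unmethylated) so that the
# realised P(methylated | state) hits the target conditionals exactly
# given the methylated fraction pi. When pi is too small to support the
# targets (e.g. ES-like samples where almost nothing is methylated), all
# targets are scaled down by a common factor, preserving their ordering
# (H3K4me3 stays the minimum).
solve_state_probs <- function(targets, pi,
                              ratio = c(bivalent = 0.25, K27 = 0.30,
                                        none = 0.45)) {
  states <- c("K4", "bivalent", "K27", "none")
  t <- targets[states]
  if (pi <= 0 || pi >= 1) {
    q <- c(K4 = 0.7, bivalent = 0.12, K27 = 0.08, none = 0.10)
    return(list(given_meth = q, given_unmeth = q, scaled_targets = t))
  }
  solve_u <- function(t) {
    a <- pi * (1 - t) / ((1 - pi) * t)
    others <- c("bivalent", "K27", "none")
    abar <- sum(ratio[others] * a[others])
    u_k4 <- (1 - abar) / (a[["K4"]] - abar)
    if (!is.finite(u_k4) || u_k4 <= 0 || u_k4 >= 1 || abar >= 1)
      return(NULL)
    u <- c(u_k4, (1 - u_k4) * ratio[others])
    names(u) <- states
    q <- u * a[states]
    list(given_meth = u, given_unmeth = q / sum(q), scaled_targets = t)
  }
  res <- solve_u(t)
  if (is.null(res)) {
    # rescale so that the K4 odds ratio lands at a feasible point
    A <- 2.5
    c_scale <- pi / (t[["K4"]] * ((1 - pi) * A + pi))
    res <- solve_u(pmin(t * c_scale, 0.95))
    if (is.null(res)) stopf("cannot solve histone state probabilities (pi = %g)", pi)
  }
  res
}

#' Simulate histone states and peak calls
#'
#' Per histone sample, each gene gets a promoter state in
#' \{K4, K27, bivalent, none\} drawn conditionally on its core-promoter
#' methylation, with conditional state frequencies solved so the realised
#' P(methylated | state) matches `config$p_meth_given_state` — H3K4me3 is
#' configured far below the other states, giving the mutually exclusive
#' DNA/H3K4me3 pattern. Peak intervals overlapping TSS +/- 2 kb are
#' emitted for the assigned marks; genes in state `none` emit no peak.
#' Genes that gain methylation at differentiation (germline and cluster
#' promoters) consequently lose H3K4me3 between the ES-like and
#' differentiated samples.
#'
#' @inheritParams simulate_arrays
#' @return object of class `histone_sim`: list with `states` (genes x
#'   histone samples character matrix) and `peaks` (per sample, per mark
#'   interval data.frames).
#' @export
simulate_histone <- function(truth, annotation, config) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 5L))
  g <- annotation$genes
  n <- nrow(g)
  core <- grepl("_core$", truth$regions$region_id)
  core_lev <- truth$levels[core, , drop = FALSE]
  rownames(core_lev) <- truth$regions$gene_id[core]
  core_lev <- core_lev[g$gene_id, , drop = FALSE]

  states <- matrix(NA_character_, n, length(cfg$histone_samples),
                   dimnames = list(g$gene_id, cfg$histone_samples))
  peaks <- list()
  for (s in cfg$histone_samples) {
    m <- core_lev[, s] >= 0.5
    pi <- mean(m)
    pr <- solve_state_probs(cfg$p_meth_given_state, pi)
    st <- character(n)
    st[m] <- sample(names(pr$given_meth), sum(m), replace = TRUE,
                    prob = pr$given_meth)
    st[!m] <- sample(names(pr$given_unmeth), sum(!m), replace = TRUE,
                     prob = pr$given_unmeth)
    states[, s] <- st

    mk_peaks <- function(sel, half) {
      k <- sum(sel)
      jit <- function() sample(-200:200, k, replace = TRUE)
      data.frame(chrom = rep("chrS", k),
                 start = g$tss[sel] - half + jit(),
                 end = g$tss[sel] + half + jit(),
                 name = g$gene_id[sel])
    }
    peaks[[s]] <- list(K4 = mk_peaks(st %in% c("K4", "bivalent"), 800L),
                       K27 = mk_peaks(st %in% c("K27", "bivalent"), 1500L))
  }
  structure(list(states = states, peaks = peaks,
                 samples = cfg$histone_samples),
            class = "histone_sim")
}

#' Run the complete generator
#'
#' @param config a [sim_config()].
#' @return list with `annotation`, `truth`, `intensities`, `expression`,
#'   `histone` and the `config`.
#' @export
simulate_methylome_study <- function(config = sim_config()) {
  ann <- generate_annotation(config)
  truth <- generate_truth(ann, config)
  ints <- simulate_arrays(truth, ann, config)
  expr <- simulate_expression(truth, ann, config)
  hist <- simulate_histone(truth, ann, config)
  list(annotation = ann, truth = truth, intensities = ints,
       expression = expr, histone = hist, config = config)
}
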