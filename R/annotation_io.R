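# Interval I/O, probe CpG content and promoter CpG classes, TSS zones.
#
# All in-memory intervals are 0-based half-open (BED convention). GFF3 is
# converted to/from its 1-based closed convention at the file boundary.

#' Read a genomic interval set
#'
#' @param path file path.
#' @param format one of `"BED"` (0-based half-open), `"GFF"` (1-based
#'   closed, converted on read) or `"TSV"` (header `chrom start end ...`,
#'   0-based half-open).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) plus `name` when present. Rows are sorted by chrom/start.
#' @export
read_intervals <- function(path, format = c("BED", "GFF", "TSV")) {
  format <- match.arg(toupper(format), c("BED", "GFF", "TSV"))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (format == "BED") {
    bad <- which(vapply(parts, length, 1L) < 3L)
    if (length(bad) > 0L)
      stopf("malformed BED line %d in %s", idx[bad[1]], path)
    df <- data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
      end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
      name = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, "")
    )
  } else if (format == "GFF") {
    bad <- which(vapply(parts, length, 1L) < 5L)
    if (length(bad) > 0L)
      stopf("malformed GFF line %d in %s", idx[bad[1]], path)
    df <- data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      start = suppressWarnings(as.integer(vapply(parts, `[`, "", 4L))) - 1L,
      end = suppressWarnings(as.integer(vapply(parts, `[`, "", 5L))),
      name = vapply(parts, function(p) if (length(p) >= 9L) p[9L] else NA_character_, "")
    )
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    assert_cols(df, c("chrom", "start", "end"), path)
    if (!"name" %in% names(df)) df$name <- NA_character_
    df <- df[, c("chrom", "start", "end",
                 setdiff(names(df), c("chrom", "start", "end")))]
  }
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad) > 0L)
    stopf("malformed line %d in %s: non-numeric coordinates", idx[bad[1]], path)
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L)
    stopf("malformed line %d in %s: start >= end", idx[bad[1]], path)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a genomic interval set
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param path output file.
#' @param format `"BED"`, `"GFF"` (emitted 1-based closed) or `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, format = c("BED", "GFF", "TSV")) {
  format <- match.arg(toupper(format), c("BED", "GFF", "TSV"))
  assert_cols(intervals, c("chrom", "start", "end"), "interval set")
  nm <- if ("name" %in% names(intervals)) intervals$name else NA_character_
  nm <- ifelse(is.na(nm), ".", nm)
  if (format == "BED") {
    out <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                   as.integer(intervals$start), as.integer(intervals$end), nm)
    writeLines(out, path)
  } else if (format == "GFF") {
    out <- sprintf("%s\tpromethylome\tregion\t%d\t%d\t.\t.\t.\t%s",
                   intervals$chrom, as.integer(intervals$start) + 1L,
                   as.integer(intervals$end), nm)
    writeLines(c("##gff-version 3", out), path)
  } else {
    utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

count_cpg <- function(s) {
  # non-overlapping left-to-right scan for the CG dinucleotide
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Probe CpG content
#'
#' CpG density of the window centered on a probe: 100 x (number of CG
#' dinucleotides found by a non-overlapping left-to-right scan) / window
#' length. Windows are truncated at chromosome ends and the realised window
#' length is used.
#'
#' @param probe_center 0-based position(s) of the probe center.
#' @param sequence chromosome sequence (single string).
#' @param window_bp window width in bp (default 500).
#' @return numeric vector of densities in percent.
#' @export
probe_cpg_content <- function(probe_center, sequence, window_bp = 500L) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stopf("empty sequence")
  L <- nchar(sequence)
  half <- window_bp %/% 2L
  s0 <- pmax(0L, as.integer(probe_center) - half)
  e0 <- pmin(L, as.integer(probe_center) + (window_bp - half))
  win <- substring(sequence, s0 + 1L, e0)
  cnt <- vapply(win, count_cpg, 0L, USE.NAMES = FALSE)
  100 * cnt / (e0 - s0)
}

base_counts <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  c(C = sum(v == "C"), G = sum(v == "G"), L = length(v))
}

#' Classify a promoter by CpG density (HCP / ICP / LCP)
#'
#' Sliding 500-bp windows over the region -700..+200 bp of the TSS
#' (strand-aware). HCP if any window reaches CpG observed/expected >= 0.75
#' together with GC fraction >= 0.55 (inclusive); LCP if no window reaches
#' observed/expected 0.48; otherwise ICP. Observed/expected is
#' N_CpG * L / (N_C * N_G). CpG counts, GC content and the C*G product are
#' strand-symmetric, so the plus-strand genomic window is scanned for both
#' strands.
#'
#' @param tss 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param sequence chromosome sequence.
#' @param region bp interval relative to the TSS scanned for windows.
#' @param window_bp,step_bp sliding-window width and step.
#' @param hcp_oe,hcp_gc,lcp_oe class thresholds.
#' @return one of `"HCP"`, `"ICP"`, `"LCP"`; `NA` (with a warning) when the
#'   sequence does not cover the region.
#' @export
classify_promoter_cpg <- function(tss, strand, sequence,
                                  region = c(-700L, 200L),
                                  window_bp = 500L, step_bp = 25L,
                                  hcp_oe = 0.75, hcp_gc = 0.55,
                                  lcp_oe = 0.48) {
  dir <- if (strand == "-") -1L else 1L
  g <- sort(tss + dir * region)
  if (g[1] < 0L || g[2] > nchar(sequence)) {
    warning("promoter region outside sequence; unclassified")
    return(NA_character_)
  }
  starts <- seq(g[1], g[2] - window_bp, by = step_bp)
  if (length(starts) == 0L) starts <- g[1]
  best_oe <- 0
  hcp <- FALSE
  for (s0 in starts) {
    win <- substring(sequence, s0 + 1L, s0 + window_bp)
    bc <- base_counts(win)
    ncpg <- count_cpg(win)
    oe <- if (bc["C"] > 0 && bc["G"] > 0)
      ncpg * bc["L"] / (bc["C"] * bc["G"]) else 0
    gc <- (bc["C"] + bc["G"]) / bc["L"]
    best_oe <- max(best_oe, oe)
    if (oe >= hcp_oe && gc >= hcp_gc) hcp <- TRUE
  }
  if (hcp) "HCP" else if (best_oe < lcp_oe) "LCP" else "ICP"
}

#' Assign regions to their nearest TSS and promoter zone
#'
#' Each region is assigned to the gene whose TSS is nearest to the region
#' midpoint; equidistant ties go to the lexicographically lower gene id.
#' The signed offset is strand-aware (negative = upstream on the coding
#' strand). Zones: `core` for offsets in `[core_zone[1], core_zone[2]]`
#' (default -1000..+500), `tss_up` upstream of that, `tss_down` downstream.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param core_zone length-2 numeric, core zone bounds in bp.
#' @return `regions` with columns `gene_id`, `tss_offset`, `zone` appended.
#' @export
assign_region_to_tss <- function(regions, genes,
                                 core_zone = c(-1000L, 500L)) {
  assert_cols(genes, c("gene_id", "chrom", "tss", "strand"), "genes")
  if (nrow(genes) == 0L) stopf("need at least one gene")
  mid <- interval_mid(regions$start, regions$end)
  gene_id <- character(nrow(regions))
  offset <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) g <- genes  # fall back to global nearest
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    pos <- findInterval(mid[ri], g$tss)
    left <- pmax(pos, 1L)
    right <- pmin(pos + 1L, nrow(g))
    dl <- abs(mid[ri] - g$tss[left])
    dr <- abs(mid[ri] - g$tss[right])
    pick_left <- dl < dr | (dl == dr & g$gene_id[left] <= g$gene_id[right])
    j <- ifelse(pick_left, left, right)
    gene_id[ri] <- g$gene_id[j]
    offset[ri] <- ifelse(g$strand[j] == "-", g$tss[j] - mid[ri],
                         mid[ri] - g$tss[j])
  }
  zone <- ifelse(offset < core_zone[1], "tss_up",
                 ifelse(offset > core_zone[2], "tss_down", "core"))
  regions$gene_id <- gene_id
  regions$tss_offset <- offset
  regions$zone <- zone
  regions
}
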