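#' Derive coverage and density columns of a chromosome summary table
#'
#' Takes per-chromosome raw columns (pseudomolecule length, aligned bp,
#' read counts and bp, contig count, SNP count), appends a totals row
#' summed over chromosomes, and derives: coverage percentage (1 decimal),
#' mean contig length in bp (integer, total aligned bp over total
#' contigs), SNP spacing in kb per SNP (1 decimal), and uncovered Mb
#' (1 decimal). Derived totals are computed from the summed raw columns,
#' never by averaging per-chromosome percentages.
#'
#' @param rows a `data.frame` with columns `chromosome, pseudomolecule_bp,
#'   aligned_bp, n_reads, read_bp, n_contigs, n_snps`.
#' @return The input plus a `"total"` row and derived columns
#'   `coverage_pct, mean_contig_bp, kb_per_snp, uncovered_mb` (`kb_per_snp`
#'   `NA` where `n_snps` is 0).
#' @export
derive_summary <- function(rows) {
  need <- c("chromosome", "pseudomolecule_bp", "aligned_bp", "n_reads",
            "read_bp", "n_contigs", "n_snps")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(rows) < 1) stop("need at least one chromosome row")
  if (any(rows$aligned_bp > rows$pseudomolecule_bp)) stop("aligned_bp exceeds pseudomolecule_bp")
  num <- need[-1]
  tot <- c(chromosome = "total", as.list(colSums(rows[, num, drop = FALSE])))
  out <- rbind(rows[, need], as.data.frame(tot, stringsAsFactors = FALSE))
  out$coverage_pct <- round(100 * out$aligned_bp / out$pseudomolecule_bp, 1)
  out$mean_contig_bp <- as.integer(round(out$aligned_bp / out$n_contigs))
  out$kb_per_snp <- ifelse(out$n_snps > 0,
                           round(out$pseudomolecule_bp / out$n_snps / 1000, 1),
                           NA_real_)
  out$uncovered_mb <- round((out$pseudomolecule_bp - out$aligned_bp) / 1e6, 1)
  rownames(out) <- NULL
  out
}

#' Read a chromosome summary table
#'
#' TSV with the raw columns expected by [derive_summary()].
#' @param path TSV path.
#' @return A `data.frame` of raw per-chromosome columns.
#' @export
read_chromosome_summary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$chromosome <- as.character(df$chromosome)
  df
}

#' Windowed SNP density profile
#'
#' Tiles each chromosome with fixed windows starting at position 1, counts
#' SNPs per window, and flags windows whose density strictly exceeds
#' `high_threshold` SNPs per kb. Windows without any SNP are reported with
#' a `zero` flag (candidate SNP deserts).
#'
#' @param map a [snp_map].
#' @param window window size in bp (default 500 kb).
#' @param high_threshold high-density flag threshold in SNPs per kb
#'   (default 0.5, strict inequality).
#' @return A `data.frame`: `chrom, start, end, n_snps, density` (SNPs/kb,
#'   over the window size), `high, zero`.
#' @export
density_profile <- function(map, window = 5e5, high_threshold = 0.5) {
  lens <- chrom_lengths(map)
  res <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    starts <- seq(1, L, by = window)
    ends <- pmin(starts + window - 1, L)
    pos <- map$pos[map$chrom == ch]
    counts <- vapply(seq_along(starts),
                     function(i) sum(pos >= starts[i] & pos <= ends[i]), 0L)
    res[[length(res) + 1]] <- data.frame(
      chrom = ch, start = starts, end = ends, n_snps = counts,
      density = counts / (window / 1000), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$high <- out$density > high_threshold
  out$zero <- out$n_snps == 0
  rownames(out) <- NULL
  out
}

#' Mean SNP spacing
#'
#' Genome length divided by the SNP count, with the value rounded to the
#' nearest 100 kb — the rounded spacing drives the window-size candidate
#' mapping of [choose_window()]. A rice-sized 382-Mb genome with 1917 SNPs
#' gives 199,348 bp, i.e. 200 kb.
#'
#' @param genome_bp total genome length in bp.
#' @param n_snps number of SNPs (> 0).
#' @return A list with `spacing_bp` (exact) and `rounded_bp` (nearest
#'   100 kb).
#' @export
mean_spacing <- function(genome_bp, n_snps) {
  if (n_snps <= 0) stop("n_snps must be positive")
  s <- genome_bp / n_snps
  list(spacing_bp = s, rounded_bp = round(s / 1e5) * 1e5)
}

#' Total designed assay SNPs
#'
#' Array designs come in fixed multiplex sizes; the designed SNP total is
#' the sum of plex size times the number of arrays of that size (e.g.
#' three 768-plex arrays plus one 384-plex array design 2688 SNPs).
#'
#' @param plex_sizes integer vector of multiplex sizes.
#' @param n_arrays number of arrays of each size.
#' @return Integer total of designed SNPs.
#' @export
designed_snp_total <- function(plex_sizes, n_arrays) {
  if (length(plex_sizes) != length(n_arrays)) stop("length mismatch")
  sum(as.integer(plex_sizes) * as.integer(n_arrays))
}
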