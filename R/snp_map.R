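#' Construct a SNP map
#'
#' The SNP map is the coordinate backbone of the package: an ordered table of
#' biallelic loci with 1-based physical positions. Chromosome lengths are
#' carried as an attribute so that block spans can be clamped to the true
#' chromosome termini and genome fractions use the full genome length as
#' denominator.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based bp positions, strictly increasing
#'   within each chromosome.
#' @param id unique SNP identifiers.
#' @param allele_a,allele_b the two alleles (single nucleotides).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   every chromosome appearing in `chrom` must be present.
#' @return A `data.frame` of class `snp_map` with columns
#'   `chrom, pos, id, allele_a, allele_b` and attribute `chrom_lengths`.
#' @export
snp_map <- function(chrom, pos, id, allele_a, allele_b, chrom_lengths) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos), id = as.character(id),
    allele_a = as.character(allele_a), allele_b = as.character(allele_b),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$id)) {
    stop("duplicate SNP id(s): ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(df$allele_a == df$allele_b)) {
    stop("SNP with identical alleles: ", df$id[df$allele_a == df$allele_b][1])
  }
  ord <- order(match(df$chrom, unique(df$chrom)), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on ", ch)
    }
    if (!ch %in% names(chrom_lengths)) {
      stop("no chromosome length supplied for ", ch)
    }
    if (any(p < 1) || any(p > chrom_lengths[[ch]])) {
      stop("SNP position outside [1, length] on ", ch)
    }
  }
  attr(df, "chrom_lengths") <- chrom_lengths
  class(df) <- c("snp_map", "data.frame")
  df
}

#' Chromosome lengths of a SNP map
#' @param map a `snp_map`.
#' @return Named numeric vector of bp lengths.
#' @export
chrom_lengths <- function(map) attr(map, "chrom_lengths")

#' Total genome length of a SNP map
#' @param map a `snp_map`.
#' @return Sum of chromosome lengths in bp.
#' @export
genome_length <- function(map) sum(chrom_lengths(map))

#' Read / write a SNP map as TSV
#'
#' The TSV has columns `chrom, pos, id, allele_a, allele_b`. Chromosome
#' lengths are stored in header comment lines of the form
#' `##length <chrom> <bp>` so that write/read round-trips are lossless.
#'
#' @param path file path.
#' @return `read_snp_map`: a [snp_map]. `write_snp_map`: `path`, invisibly.
#' @export
read_snp_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^##length\t", lines, value = TRUE)
  if (length(hdr) == 0) stop("SNP map is missing ##length header lines")
  parts <- strsplit(hdr, "\t", fixed = TRUE)
  lens <- setNames(
    as.numeric(vapply(parts, `[`, "", 3L)),
    vapply(parts, `[`, "", 2L)
  )
  body <- lines[!startsWith(lines, "##")]
  df <- read.delim(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE,
                   colClasses = "character")
  snp_map(df$chrom, as.integer(df$pos), df$id, df$allele_a, df$allele_b, lens)
}

#' @rdname read_snp_map
#' @param map a `snp_map` to write.
#' @export
write_snp_map <- function(map, path) {
  lens <- chrom_lengths(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##length\t%s\t%d", names(lens), as.integer(lens)), con)
  writeLines(paste(c("chrom", "pos", "id", "allele_a", "allele_b"), collapse = "\t"), con)
  writeLines(do.call(paste, c(unclass(map)[c("chrom", "pos", "id", "allele_a", "allele_b")],
                              list(sep = "\t"))), con)
  invisible(path)
}

#' Read a SNP map from a VCF
#'
#' Uses the VCF `##contig` header lines for chromosome lengths. Records with
#' more than one ALT allele are rejected: the panel analysis is defined on
#' biallelic SNPs only.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return A [snp_map].
#' @export
read_snp_map_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop dimensions
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    bad <- fix[grepl(",", alt, fixed = TRUE), "ID"][1]
    stop("not biallelic: VCF record ", bad)
  }
  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
  lens <- as.numeric(sub('.*length=([0-9]+).*', "\\1", contig))
  snp_map(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "ID"],
          fix[, "REF"], alt, setNames(lens, ids))
}
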