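#' Read / write a raw genotype call matrix
#'
#' Rows are cultivars, columns are SNP ids, cells are unordered allele pairs
#' like `"A/A"` or `"A/G"`; `"./."` encodes a missing (no-signal) call.
#' When a `snp_map` is supplied every non-missing call is validated against
#' the SNP's two alleles.
#'
#' @param path TSV path; first column `cultivar`, remaining columns SNP ids.
#' @param map optional [snp_map] used to validate calls.
#' @return `read_genotypes`: a character matrix (cultivars x SNPs).
#' @export
read_genotypes <- function(path, map = NULL) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "cultivar") stop("first column must be 'cultivar'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cultivar
  if (anyDuplicated(rownames(m))) stop("duplicate cultivar id")
  if (!is.null(map)) validate_calls(m, map)
  m
}

#' @rdname read_genotypes
#' @param raw character call matrix to write.
#' @export
write_genotypes <- function(raw, path) {
  df <- data.frame(cultivar = rownames(raw), raw, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_calls <- function(raw, map) {
  miss <- setdiff(colnames(raw), map$id)
  if (length(miss)) stop("genotype matrix has SNPs absent from map: ", miss[1])
  for (j in colnames(raw)) {
    ok <- c(map$allele_a[map$id == j], map$allele_b[map$id == j])
    calls <- raw[, j]
    parts <- strsplit(calls[calls != MISSING_CALL], "/", fixed = TRUE)
    bad <- which(!vapply(parts, function(a) all(a %in% ok), TRUE))
    if (length(bad)) {
      cult <- rownames(raw)[calls != MISSING_CALL][bad[1]]
      stop("invalid call at SNP ", j, " for cultivar ", cult)
    }
  }
  invisible(TRUE)
}

#' Read genotypes from a VCF
#'
#' GT fields are translated to allele-pair calls using REF/ALT; `.` alleles
#' give a missing call. Multi-allelic records are rejected.
#'
#' @param path VCF path.
#' @return Character call matrix (cultivars x SNPs).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("not biallelic: VCF record ", fix[grepl(",", fix[, "ALT"]), "ID"][1])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- matrix(MISSING_CALL, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), fix[, "ID"]))
  for (i in seq_len(nrow(gt))) {
    alleles <- c(fix[i, "REF"], fix[i, "ALT"])
    g <- gt[i, ]
    parts <- strsplit(g, "[/|]")
    call <- vapply(parts, function(a) {
      if (length(a) != 2 || any(a == ".") || anyNA(a)) return(MISSING_CALL)
      paste(alleles[as.integer(a) + 1L], collapse = "/")
    }, "")
    call[is.na(g)] <- MISSING_CALL
    out[, i] <- call
  }
  out
}

#' Read / write a pedigree
#'
#' CSV columns `cultivar, mother, father, year`; empty parent fields mark
#' founders (landraces). Cultivars are assigned to development-era groups by
#' [assign_groups()].
#'
#' @param path CSV path.
#' @return A `data.frame` of class `pedigree` with character columns
#'   `cultivar, mother, father` (parents `NA` for founders) and integer
#'   `year`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  pedigree(df$cultivar,
           ifelse(df$mother == "", NA, df$mother),
           ifelse(df$father == "", NA, df$father),
           suppressWarnings(as.integer(df$year)))
}

#' @rdname read_pedigree
#' @param ped pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(cultivar = ped$cultivar,
                    mother = ifelse(is.na(ped$mother), "", ped$mother),
                    father = ifelse(is.na(ped$father), "", ped$father),
                    year = ped$year)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a pedigree
#'
#' @param cultivar,mother,father cultivar ids; parents `NA` for founders.
#' @param year development year (integer or `NA`).
#' @return A `data.frame` of class `pedigree`.
#' @export
pedigree <- function(cultivar, mother = NA, father = NA, year = NA) {
  df <- data.frame(cultivar = as.character(cultivar),
                   mother = as.character(mother), father = as.character(father),
                   year = as.integer(year), stringsAsFactors = FALSE)
  if (anyDuplicated(df$cultivar)) stop("duplicate cultivar in pedigree")
  has_one <- xor(is.na(df$mother), is.na(df$father))
  if (any(has_one)) stop("cultivar with a single parent: ", df$cultivar[has_one][1])
  parents <- c(df$mother, df$father)
  unknown <- setdiff(parents[!is.na(parents)], df$cultivar)
  if (length(unknown)) stop("parent not in pedigree: ", unknown[1])
  topo_order(df)  # errors on cycles
  class(df) <- c("pedigree", "data.frame")
  df
}

# Topological order of pedigree rows (founders first); errors on cycles.
topo_order <- function(ped) {
  ids <- ped$cultivar
  deps <- lapply(seq_along(ids), function(i) {
    p <- c(ped$mother[i], ped$father[i])
    p[!is.na(p)]
  })
  done <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) all(deps[[i]] %in% done), TRUE)]
    if (!length(ready)) stop("cycle in pedigree")
    done <- c(done, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  match(done, ids)
}

#' Assign development-era groups to a pedigree
#'
#' Cultivars are stratified by development year into three breeding-era
#' groups: Group 1 (landraces and early cultivars, up to `cut1`), Group 2
#' (`cut1 + 1` to `cut2`), Group 3 (after `cut2`). Defaults follow the
#' eras of the Japanese rice panel: up to 1930, 1931-1974, 1975 onward.
#'
#' @param ped a [pedigree].
#' @param cut1,cut2 last year of Groups 1 and 2.
#' @return The pedigree with an added integer `group` column (`NA` when the
#'   year is unknown).
#' @export
assign_groups <- function(ped, cut1 = 1930, cut2 = 1974) {
  ped$group <- ifelse(is.na(ped$year), NA_integer_,
               ifelse(ped$year <= cut1, 1L, ifelse(ped$year <= cut2, 2L, 3L)))
  ped
}

#' Code raw calls against two reference cultivars
#'
#' Every call is classified relative to the two reference cultivars
#' (the donor-parent role and the sequenced-reference role): homozygous and
#' equal to the first reference gives `P1`, equal to the second `P2`, one
#' allele from each `HET`, no signal `MISSING`. A homozygous call matching
#' neither reference (possible only before QC removes uncodable SNPs) is
#' coded `OTHER`.
#'
#' @param raw character call matrix from [read_genotypes()].
#' @param map [snp_map] covering the matrix columns.
#' @param refA,refB reference cultivar ids, present as rows of `raw`; each
#'   must be homozygous and non-missing at all coded SNPs.
#' @return Character matrix of states with attributes `refA`, `refB` and
#'   class `coded_geno`.
#' @export
code_calls <- function(raw, map, refA, refB) {
  if (!all(c(refA, refB) %in% rownames(raw))) stop("reference cultivar absent from matrix")
  raw <- raw[, map$id, drop = FALSE]
  norm <- normalize_calls(raw)
  a <- norm[refA, ]
  b <- norm[refB, ]
  if (any(a == MISSING_CALL) || any(b == MISSING_CALL)) {
    stop("reference cultivar has missing calls at coded SNPs")
  }
  if (any(is_het(a)) || any(is_het(b))) {
    stop("reference cultivar heterozygous at coded SNPs")
  }
  if (any(a == b)) {
    stop("references carry the same genotype at SNP ",
         colnames(raw)[a == b][1], "; remove uncodable SNPs first (QC rule 4)")
  }
  out <- matrix(STATE_OTHER, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  out[norm == MISSING_CALL] <- STATE_MISSING
  out[is_het(norm)] <- STATE_HET
  out[sweep(norm, 2, a, `==`)] <- STATE_P1
  out[sweep(norm, 2, b, `==`)] <- STATE_P2
  structure(out, refA = refA, refB = refB, class = "coded_geno")
}

# "G/A" and "A/G" are the same unordered call; sort allele pairs.
normalize_calls <- function(raw) {
  u <- unique(as.vector(raw))
  key <- vapply(strsplit(u, "/", fixed = TRUE),
                function(a) paste(sort(a), collapse = "/"), "")
  m <- matrix(key[match(raw, u)], nrow(raw), ncol(raw), dimnames = dimnames(raw))
  m
}

is_het <- function(calls) {
  parts <- strsplit(calls, "/", fixed = TRUE)
  vapply(parts, function(a) length(a) == 2 && a[1] != a[2] && !any(a == "."), TRUE)
}

#' Array quality-control filter
#'
#' Applies the five discard rules used for SNP-array screening. A SNP is
#' discarded when it has (1) no signals in any sample, (2) no signal in
#' either reference cultivar, (3) no signals in more than `missing_frac` of
#' the samples, (4) no polymorphism (all non-missing calls identical, or the
#' two references carry the same genotype, which makes the SNP uncodable),
#' or (5) more than `het_frac` of the signals heterozygous. Thresholds are
#' strict inequalities ("more than 10%").
#'
#' @param raw character call matrix.
#' @param map [snp_map] for the matrix columns.
#' @param refA,refB reference cultivar ids.
#' @param missing_frac,het_frac discard thresholds, defaults 0.10.
#' @param het_over_nonmissing if `TRUE` (default) the rule-5 denominator is
#'   the number of non-missing calls; if `FALSE`, all samples.
#' @return A list with `map` (retained [snp_map]) and `report`, a
#'   `data.frame` with one row per discarded SNP: `id`, `rule` (the lowest
#'   violated rule number), `stat` (the triggering statistic) and `rules`
#'   (all violated rules as a string like `"3,5"`).
#' @export
qc_filter <- function(raw, map, refA, refB, missing_frac = 0.10,
                      het_frac = 0.10, het_over_nonmissing = TRUE) {
  raw <- raw[, map$id, drop = FALSE]
  norm <- normalize_calls(raw)
  n <- nrow(norm)
  het <- matrix(is_het(norm), n, ncol(norm), dimnames = dimnames(norm))
  id <- character(0); rule <- integer(0); stat <- numeric(0); rules <- character(0)
  for (j in seq_len(ncol(norm))) {
    calls <- norm[, j]
    n_missing <- sum(calls == MISSING_CALL)
    viol <- integer(0); stats <- numeric(0)
    if (n_missing == n) { viol <- c(viol, 1L); stats <- c(stats, n_missing) }
    if (calls[refA] == MISSING_CALL || calls[refB] == MISSING_CALL) {
      viol <- c(viol, 2L); stats <- c(stats, NA_real_)
    }
    mf <- n_missing / n
    if (mf > missing_frac) { viol <- c(viol, 3L); stats <- c(stats, mf) }
    nm <- calls[calls != MISSING_CALL]
    mono <- length(nm) > 0 && length(unique(nm)) == 1
    refs_equal <- calls[refA] != MISSING_CALL && calls[refA] == calls[refB]
    if (mono || refs_equal) { viol <- c(viol, 4L); stats <- c(stats, NA_real_) }
    denom <- if (het_over_nonmissing) max(length(nm), 1L) else n
    hf <- sum(het[, j]) / denom
    if (hf > het_frac) { viol <- c(viol, 5L); stats <- c(stats, hf) }
    if (length(viol)) {
      id <- c(id, colnames(norm)[j])
      rule <- c(rule, viol[1])
      stat <- c(stat, stats[1])
      rules <- c(rules, paste(viol, collapse = ","))
    }
  }
  report <- data.frame(id = id, rule = rule, stat = stat, rules = rules,
                       stringsAsFactors = FALSE)
  keep <- !(map$id %in% id)
  retained <- map[keep, , drop = FALSE]
  attr(retained, "chrom_lengths") <- chrom_lengths(map)
  class(retained) <- class(map)
  rownames(retained) <- NULL
  list(map = retained, report = report)
}
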