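# Rice pseudomolecule lengths (bp) used as the default simulated genome.
RICE_CHROM_LENGTHS <- c(
  chr01 = 45064769, chr02 = 36823111, chr03 = 37257345, chr04 = 35863200,
  chr05 = 30039014, chr06 = 32124789, chr07 = 30357780, chr08 = 28530027,
  chr09 = 23843360, chr10 = 23661561, chr11 = 30828668, chr12 = 27757321
)

#' Simulate a rice-like breeding panel with known truth
#'
#' The canned study condition used to validate block recovery: a 12
#' chromosome, 382-Mb genome carrying 1917 uniformly placed SNPs; six
#' landrace founders plus one unrelated reference founder (the sequenced
#' reference role, used as the second coding reference); a three-tier
#' pedigree in which two founder crosses feed two intermediate crosses
#' whose cross yields the target cultivar, and three progeny are bred by
#' crossing the target back into the pedigree (the donor/recipient
#' constellation of the consensus-block analysis). Every cross is advanced
#' by `g` single-seed-descent selfing generations and fixed to full
#' homozygosity.
#'
#' @param seed integer seed controlling every random draw.
#' @param n_snps SNP count (default 1917).
#' @param g selfing generations per cross (default 6).
#' @param cM_per_Mb recombination density (default 4).
#' @param missing_rate,het_rate assay noise rates (default 0).
#' @return A list: `map`, `founders`, `ped`, `raw`, `truth`, plus the
#'   role ids `target` (`"T"`), `reference` (`"REF"`), `recipients`.
#' @export
simulate_panel <- function(seed = 1, n_snps = 1917, g = 6, cM_per_Mb = 4.0,
                           missing_rate = 0, het_rate = 0) {
  map <- simulate_genome(RICE_CHROM_LENGTHS, n_snps = n_snps, seed = seed)
  founder_ids <- c(paste0("L", 1:6), "REF")
  founders <- simulate_founders(map, length(founder_ids), maf = 0.5,
                                seed = seed + 1, ids = founder_ids)
  ped <- pedigree(
    cultivar = c(founder_ids, "A1", "A2", "B1", "B2", "T", "R1", "R2", "R3"),
    mother = c(rep(NA, 7), "L1", "L3", "A1", "A2", "B1", "T", "T", "T"),
    father = c(rep(NA, 7), "L2", "L4", "L5", "L6", "B2", "B1", "A2", "B2"),
    year = c(rep(1900, 7), 1920, 1925, 1935, 1940, 1956, 1988, 1990, 1992)
  )
  b <- breed(ped, founders, map, g = g, fix_residual_het = TRUE,
             cM_per_Mb = cM_per_Mb, seed = seed + 2)
  raw <- b$raw
  if (missing_rate > 0 || het_rate > 0) {
    raw <- apply_assay_noise(raw, map, missing_rate, het_rate, seed = seed + 3)
  }
  list(map = map, founders = founders, ped = ped, raw = raw, truth = b$truth,
       target = "T", reference = "REF", recipients = c("R1", "R2", "R3"))
}

#' Score founder-segment recovery against simulator truth
#'
#' Truth segments are first projected onto marker resolution: segments
#' containing no retained SNP are invisible to the assay, so adjacent
#' same-founder segments separated only by such slivers are merged. Every
#' projected segment of the target cultivar that is at least `min_length`
#' long and contains at least `min_snps` retained SNPs then counts as
#' recovered when an attributed block carries the correct founder,
#' overlaps it, and each block boundary is within one inter-SNP interval
#' of the truth boundary (at most one retained SNP lies strictly between
#' them; truth breakpoints fall between SNPs and attributed boundaries at
#' inter-SNP midpoints, so one interval is the attainable resolution).
#'
#' @param blocks attributed block table from [assign_ancestry()].
#' @param truth simulator truth for the target cultivar
#'   (`chrom, start, end, founder`).
#' @param map the retained [snp_map].
#' @param min_length,min_snps eligibility thresholds for truth segments
#'   (defaults 500 kb, 5 SNPs).
#' @return A `data.frame` with one row per eligible truth segment:
#'   `chrom, start, end, founder, n_snps, recovered`, plus attribute
#'   `recovery_rate` (fraction recovered).
#' @export
segment_recovery <- function(blocks, truth, map, min_length = 5e5, min_snps = 5) {
  truth <- project_truth(truth, map)
  res <- list()
  for (i in seq_len(nrow(truth))) {
    ch <- truth$chrom[i]; s <- truth$start[i]; e <- truth$end[i]
    if (e - s < min_length) next
    n <- sum(map$chrom == ch & map$pos >= s & map$pos < e)
    if (n < min_snps) next
    cand <- blocks[blocks$chrom == ch & blocks$origin == truth$founder[i] &
                   blocks$end > s & blocks$start < e, , drop = FALSE]
    rec <- FALSE
    if (nrow(cand)) {
      ov <- pmin(cand$end, e) - pmax(cand$start, s)
      bl <- cand[which.max(ov), ]
      rec <- boundary_ok(bl$start, s, ch, map) && boundary_ok(bl$end, e, ch, map)
    }
    res[[length(res) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                         founder = truth$founder[i],
                                         n_snps = n, recovered = rec,
                                         stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               founder = character(0), n_snps = integer(0), recovered = logical(0))
  rownames(out) <- NULL
  attr(out, "recovery_rate") <- if (nrow(out)) mean(out$recovered) else NA_real_
  out
}

# Marker-resolution projection of a truth tiling: drop segments without any
# retained SNP, then merge consecutive same-founder segments (the dropped
# slivers are invisible to the assay).
project_truth <- function(truth, map) {
  res <- list()
  for (ch in unique(truth$chrom)) {
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    pos <- map$pos[map$chrom == ch]
    has <- vapply(seq_len(nrow(tr)),
                  function(i) any(pos >= tr$start[i] & pos < tr$end[i]), TRUE)
    tr <- tr[has, , drop = FALSE]
    if (!nrow(tr)) next
    keep <- c(TRUE, tr$founder[-1] != tr$founder[-nrow(tr)])
    grp <- cumsum(keep)
    res[[length(res) + 1]] <- data.frame(
      chrom = ch,
      start = as.numeric(tapply(tr$start, grp, min)),
      end = as.numeric(tapply(tr$end, grp, max)),
      founder = tr$founder[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# One-interval boundary agreement: at most one retained SNP lies strictly
# between the recovered and the true boundary coordinate.
boundary_ok <- function(got, want, ch, map) {
  pos <- map$pos[map$chrom == ch]
  sum(pos > min(got, want) & pos < max(got, want)) <= 1
}

#' Simulate a three-group diversity panel
#'
#' Emulates the panel structure used for the haplotype-diversity analysis:
#' Group 1 is a set of independent landrace founders; each Group 2 cultivar
#' is a cross of two random landraces; Group 3 cultivars are bred from a
#' small set of elite Group 2 parents (a breeding bottleneck, which is what
#' depresses the modern group's haplotype diversity). All crosses are
#' advanced by `g` selfing generations and fixed. Two Group 3 cultivars
#' double as the coding references.
#'
#' @param seed integer seed.
#' @param n_snps designed SNP count (default 3834; roughly half survive QC
#'   against the two references).
#' @param n_g1,n_g2,n_g3 group sizes (defaults 38, 49, 64).
#' @param n_elite number of Group 2 parents available to Group 3 crosses
#'   (default 6).
#' @param g selfing generations per cross (default 6).
#' @param cM_per_Mb recombination density (default 4).
#' @return A list: `map`, `ped` (with `group` column), `raw`, `groups`
#'   (named vector), `refA`, `refB`.
#' @export
simulate_diversity_panel <- function(seed = 1, n_snps = 3834, n_g1 = 38,
                                     n_g2 = 49, n_g3 = 64, n_elite = 6,
                                     g = 6, cM_per_Mb = 4.0) {
  map <- simulate_genome(RICE_CHROM_LENGTHS, n_snps = n_snps, seed = seed)
  g1 <- sprintf("G1_%02d", seq_len(n_g1))
  g2 <- sprintf("G2_%02d", seq_len(n_g2))
  g3 <- sprintf("G3_%02d", seq_len(n_g3))
  founders <- simulate_founders(map, n_g1, maf = 0.5, seed = seed + 1, ids = g1)
  set.seed(seed + 2)
  pick2 <- function(pool) sample(pool, 2)
  p2 <- t(vapply(g2, function(x) pick2(g1), character(2)))
  elites <- g2[seq_len(n_elite)]
  p3 <- t(vapply(g3, function(x) pick2(elites), character(2)))
  ped <- pedigree(
    cultivar = c(g1, g2, g3),
    mother = c(rep(NA, n_g1), p2[, 1], p3[, 1]),
    father = c(rep(NA, n_g1), p2[, 2], p3[, 2]),
    year = c(rep(1900, n_g1),
             1931 + seq_len(n_g2) %% 44,
             1975 + seq_len(n_g3) %% 31))
  ped <- assign_groups(ped)
  b <- breed(ped, founders, map, g = g, fix_residual_het = TRUE,
             cM_per_Mb = cM_per_Mb, seed = seed + 3)
  groups <- setNames(ped$group, ped$cultivar)
  list(map = map, ped = ped, raw = b$raw, groups = groups,
       refA = g3[n_g3], refB = g3[n_g3 - 1])
}
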