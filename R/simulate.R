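#' Simulate a SNP genome backbone
#'
#' Generates a multi-chromosome genome and a panel of biallelic SNP loci,
#' either at fixed spacing or uniformly at random. Defaults emulate a rice
#' sized genome typed at roughly one SNP per 200 kb.
#'
#' @param chromosome_lengths numeric vector of chromosome lengths in bp
#'   (names become chromosome labels; unnamed vectors get `chr01`, ...).
#' @param n_snps total SNP count for `spacing_mode = "uniform"`; SNPs are
#'   spread over chromosomes in proportion to their length.
#' @param spacing fixed inter-SNP spacing in bp for
#'   `spacing_mode = "fixed"`; SNPs sit at `spacing, 2*spacing, ...`,
#'   strictly inside the chromosome.
#' @param spacing_mode `"uniform"` (random positions) or `"fixed"`.
#' @param seed integer seed; the same configuration and seed give an
#'   identical map.
#' @return A [snp_map].
#' @export
simulate_genome <- function(chromosome_lengths, n_snps = NULL, spacing = NULL,
                            spacing_mode = c("uniform", "fixed"), seed = 1) {
  spacing_mode <- match.arg(spacing_mode)
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- sprintf("chr%02d", seq_along(chromosome_lengths))
  }
  lens <- chromosome_lengths
  set.seed(seed)
  if (spacing_mode == "fixed") {
    if (is.null(spacing) || spacing <= 0) stop("fixed spacing requires spacing > 0")
    chrom <- character(0); pos <- integer(0)
    for (ch in names(lens)) {
      p <- seq(spacing, lens[[ch]], by = spacing)
      p <- p[p < lens[[ch]]]
      chrom <- c(chrom, rep(ch, length(p)))
      pos <- c(pos, as.integer(p))
    }
  } else {
    if (is.null(n_snps) || n_snps < 1) stop("uniform mode requires n_snps >= 1")
    total <- sum(lens)
    offsets <- cumsum(c(0, lens[-length(lens)]))
    names(offsets) <- names(lens)
    repeat {
      u <- sort(ceiling(runif(n_snps) * total))
      idx <- findInterval(u - 1, cumsum(lens))
      ch <- names(lens)[idx + 1]
      p <- as.integer(u - offsets[ch])
      if (!anyDuplicated(paste(ch, p))) break
    }
    chrom <- ch; pos <- p
  }
  if (length(pos) == 0) stop("configuration yields zero SNPs")
  nts <- c("A", "C", "G", "T")
  a <- sample(nts, length(pos), replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(nts, x), 1), "")
  snp_map(chrom, pos, sprintf("snp%05d", seq_along(pos)), a, b, lens)
}

#' Simulate homozygous founder lines
#'
#' Each founder carries one allele per SNP drawn independently: allele B
#' with probability `maf`, allele A otherwise. Founders are fully
#' homozygous, emulating a landrace stratum of inbred lines.
#'
#' @param map a [snp_map].
#' @param n number of founders (at least 2, so that crossing is possible).
#' @param maf probability of the B allele, in (0, 0.5].
#' @param seed integer seed.
#' @param ids optional founder ids (default `F1, F2, ...`).
#' @return A `founder_set`: integer matrix (founders x SNPs, values 0 = A,
#'   1 = B) with the map attached as attribute `map`.
#' @export
simulate_founders <- function(map, n, maf = 0.3, seed = 1, ids = NULL) {
  if (n < 2) stop("need at least 2 founders for crossing")
  if (maf < 0 || maf > 0.5) stop("maf must be in [0, 0.5]")
  if (maf == 0) warning("maf = 0: every SNP will be monomorphic across founders")
  set.seed(seed)
  if (is.null(ids)) ids <- paste0("F", seq_len(n))
  m <- matrix(rbinom(n * nrow(map), 1L, maf), n, nrow(map),
              dimnames = list(ids, map$id))
  structure(m, map = map, class = "founder_set")
}

# A haplotype is a list (one element per chromosome) of data.frames with
# half-open bp segments [start, end) and the founder each descends from.
founder_haplotype <- function(map, founder_id) {
  lens <- chrom_lengths(map)
  setNames(lapply(names(lens), function(ch) {
    data.frame(start = 1, end = lens[[ch]] + 1, founder = founder_id,
               stringsAsFactors = FALSE)
  }), names(lens))
}

merge_segments <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep <- c(TRUE, seg$founder[-1] != seg$founder[-nrow(seg)])
  grp <- cumsum(keep)
  out <- data.frame(start = tapply(seg$start, grp, min),
                    end = tapply(seg$end, grp, max),
                    founder = seg$founder[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Restrict a segment table to [from, to) (half-open).
clip_segments <- function(seg, from, to) {
  sel <- seg$end > from & seg$start < to
  s <- seg[sel, , drop = FALSE]
  s$start <- pmax(s$start, from)
  s$end <- pmin(s$end, to)
  s
}

#' Simulate one meiosis
#'
#' Produces a gamete from a diploid individual under a Haldane (no crossover
#' interference) model: crossover count per chromosome is Poisson with mean
#' equal to the chromosome map length in Morgans
#' (`length_bp * cM_per_Mb / 1e8`), crossover positions are uniform, and the
#' gamete alternates between the two parental homologues. The implied
#' recombination fraction between two points at distance `d` Morgans is
#' `(1 - exp(-2 d)) / 2`.
#'
#' @param parent list with elements `hap1`, `hap2` (haplotype segment lists).
#' @param map a [snp_map] (provides chromosome lengths).
#' @param cM_per_Mb recombination density, centimorgans per megabase.
#' @param seed optional seed; by default the current RNG stream is used so
#'   that breeding schemes are reproducible from a single seed.
#' @return A haplotype: per-chromosome founder segment tables.
#' @export
meiosis <- function(parent, map, cM_per_Mb = 4.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(map)
  out <- setNames(vector("list", length(lens)), names(lens))
  for (ch in names(lens)) {
    L <- lens[[ch]]
    morgans <- L * cM_per_Mb / 1e8
    n_xo <- rpois(1, morgans)
    xo <- sort(unique(ceiling(runif(n_xo) * (L - 1))))
    bounds <- c(1, xo + 1, L + 1)
    cur <- sample(1:2, 1)
    pieces <- vector("list", length(bounds) - 1)
    for (k in seq_len(length(bounds) - 1)) {
      src <- if (cur == 1) parent$hap1[[ch]] else parent$hap2[[ch]]
      pieces[[k]] <- clip_segments(src, bounds[k], bounds[k + 1])
      cur <- 3 - cur
    }
    out[[ch]] <- merge_segments(do.call(rbind, pieces))
  }
  out
}

# Founder-of-origin per SNP for one haplotype.
hap_founders_at_snps <- function(hap, map) {
  out <- character(nrow(map))
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    seg <- hap[[ch]]
    idx <- findInterval(map$pos[sel], seg$start)
    out[sel] <- seg$founder[idx]
  }
  out
}

# Allele codes (0/1) per SNP for one haplotype, looked up in the founders.
hap_alleles <- function(hap, map, founders) {
  f <- hap_founders_at_snps(hap, map)
  founders[cbind(match(f, rownames(founders)), seq_len(nrow(map)))]
}

#' Breed a pedigree of inbred cultivars
#'
#' Walks the pedigree in topological order. Founders take their simulated
#' homozygous genomes. Each cross produces an F1 (one gamete from each
#' parent), which is advanced by `g` generations of single-seed-descent
#' selfing; optionally, residual heterozygous regions are then forced to a
#' random homozygote (segment-wise: wherever the two homologues descend
#' from different founders, one homologue is copied over the other with
#' probability 1/2), yielding a fully homozygous-by-descent cultivar.
#' Founder-of-origin truth is tracked through every meiosis.
#'
#' @param ped a [pedigree]; founders must be rows of `founders`.
#' @param founders a `founder_set` from [simulate_founders()].
#' @param map the [snp_map].
#' @param g selfing generations after each cross (default 6).
#' @param fix_residual_het force fixation of residual heterozygosity
#'   (default `TRUE`).
#' @param cM_per_Mb recombination density (default 4).
#' @param seed integer seed for the whole breeding scheme.
#' @return A list with `raw` (character call matrix, all pedigree members x
#'   SNPs), `truth` (a `data.frame`: `cultivar, chrom, start, end, founder`,
#'   half-open bp segments tiling each chromosome) and `individuals`
#'   (internal haplotype pairs, mainly for diagnostics).
#' @export
breed <- function(ped, founders, map, g = 6, fix_residual_het = TRUE,
                  cM_per_Mb = 4.0, seed = 1) {
  set.seed(seed)
  ord <- topo_order(ped)
  indiv <- list()
  for (i in ord) {
    id <- ped$cultivar[i]
    mo <- ped$mother[i]; fa <- ped$father[i]
    if (is.na(mo)) {
      if (!id %in% rownames(founders)) stop("founder ", id, " absent from founder set")
      h <- founder_haplotype(map, id)
      indiv[[id]] <- list(hap1 = h, hap2 = h)
    } else {
      if (is.null(indiv[[mo]]) || is.null(indiv[[fa]])) stop("parent bred out of order")
      x <- list(hap1 = meiosis(indiv[[mo]], map, cM_per_Mb),
                hap2 = meiosis(indiv[[fa]], map, cM_per_Mb))
      for (k in seq_len(g)) {
        x <- list(hap1 = meiosis(x, map, cM_per_Mb),
                  hap2 = meiosis(x, map, cM_per_Mb))
      }
      if (fix_residual_het) x <- fix_heterozygosity(x, map)
      indiv[[id]] <- x
    }
  }
  raw <- matrix(NA_character_, length(indiv), nrow(map),
                dimnames = list(names(indiv), map$id))
  for (id in names(indiv)) {
    a1 <- hap_alleles(indiv[[id]]$hap1, map, founders)
    a2 <- hap_alleles(indiv[[id]]$hap2, map, founders)
    n1 <- ifelse(a1 == 0, map$allele_a, map$allele_b)
    n2 <- ifelse(a2 == 0, map$allele_a, map$allele_b)
    raw[id, ] <- paste(pmin(n1, n2), pmax(n1, n2), sep = "/")
  }
  truth <- do.call(rbind, lapply(names(indiv), function(id) {
    hap <- indiv[[id]]$hap1
    do.call(rbind, lapply(names(hap), function(ch) {
      data.frame(cultivar = id, chrom = ch, start = hap[[ch]]$start,
                 end = hap[[ch]]$end, founder = hap[[ch]]$founder,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(truth) <- NULL
  list(raw = raw, truth = truth, individuals = indiv)
}

# Segment-wise forced fixation: in every maximal interval where the two
# homologues descend from different founders, copy one homologue over the
# other with probability 1/2.
fix_heterozygosity <- function(x, map) {
  for (ch in names(x$hap1)) {
    s1 <- x$hap1[[ch]]; s2 <- x$hap2[[ch]]
    bounds <- sort(unique(c(s1$start, s1$end, s2$start, s2$end)))
    f1 <- s1$founder[findInterval(bounds[-length(bounds)], s1$start)]
    f2 <- s2$founder[findInterval(bounds[-length(bounds)], s2$start)]
    differ <- f1 != f2
    if (!any(differ)) next
    grp <- cumsum(c(TRUE, diff(differ) != 0))
    out1 <- character(length(f1)); out2 <- character(length(f1))
    for (gi in unique(grp)) {
      sel <- grp == gi
      if (differ[sel][1]) {
        pick <- if (runif(1) < 0.5) f1[sel] else f2[sel]
        out1[sel] <- pick; out2[sel] <- pick
      } else {
        out1[sel] <- f1[sel]; out2[sel] <- f2[sel]
      }
    }
    x$hap1[[ch]] <- merge_segments(data.frame(
      start = bounds[-length(bounds)], end = bounds[-1], founder = out1,
      stringsAsFactors = FALSE))
    x$hap2[[ch]] <- merge_segments(data.frame(
      start = bounds[-length(bounds)], end = bounds[-1], founder = out2,
      stringsAsFactors = FALSE))
  }
  x
}

#' Apply array assay noise
#'
#' Independently per call, with probability `missing_rate` the call becomes
#' missing (`"./."`); otherwise, with probability `het_rate`, it is replaced
#' by a heterozygous mis-call of the SNP's two alleles. Emulates array
#' dropout and spurious heterozygous signals screened by [qc_filter()].
#'
#' @param raw character call matrix.
#' @param map [snp_map] (supplies the alleles for het mis-calls).
#' @param missing_rate,het_rate probabilities in \[0, 1) with sum < 1.
#' @param seed integer seed.
#' @return Noisy call matrix of the same shape.
#' @export
apply_assay_noise <- function(raw, map, missing_rate = 0, het_rate = 0, seed = 1) {
  if (missing_rate < 0 || het_rate < 0 || missing_rate + het_rate >= 1) {
    stop("rates must be nonnegative and sum to less than 1")
  }
  if (missing_rate == 0 && het_rate == 0) return(raw)
  set.seed(seed)
  raw <- raw[, map$id, drop = FALSE]
  u <- matrix(runif(length(raw)), nrow(raw), ncol(raw))
  het_call <- matrix(rep(paste(pmin(map$allele_a, map$allele_b),
                               pmax(map$allele_a, map$allele_b), sep = "/"),
                         each = nrow(raw)), nrow(raw), ncol(raw))
  out <- raw
  out[u < missing_rate + het_rate] <- het_call[u < missing_rate + het_rate]
  out[u < missing_rate] <- MISSING_CALL
  out
}

#' Write truth ancestry as BED-like TSV
#'
#' Columns `cultivar, chrom, start0, end0, founder` with 0-based half-open
#' coordinates.
#' @param truth truth table from [breed()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  out <- data.frame(cultivar = truth$cultivar, chrom = truth$chrom,
                    start0 = as.integer(truth$start - 1),
                    end0 = as.integer(truth$end - 1), founder = truth$founder)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
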