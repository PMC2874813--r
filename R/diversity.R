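#' Lewontin's D-prime between two SNPs
#'
#' Two-locus haplotype frequencies are read directly from the homozygous
#' two-locus states (the panel is inbred, so haplotypes are observed, not
#' phased). Cultivars heterozygous or missing at either SNP are excluded.
#' `D = p(AB) - p(A) p(B)`; `D' = |D| / Dmax`, where `Dmax` is
#' `min(p(A) p(b), p(a) p(B))` when `D > 0` and `min(p(A) p(B), p(a) p(b))`
#' when `D < 0`. Pairs monomorphic after exclusion are undefined.
#'
#' @param coded a `coded_geno` matrix.
#' @param map the retained [snp_map].
#' @param snp_i,snp_j SNP ids.
#' @param cultivars optional subset of cultivar ids (e.g. one group).
#' @return A list (`ld_record`): `snp_i, snp_j, distance` (bp; `NA` when
#'   the SNPs sit on different chromosomes), `d_prime` (signed `D` kept as
#'   `d`), `n_used`. `d_prime` is `NA` for undefined pairs.
#' @export
dprime <- function(coded, map, snp_i, snp_j, cultivars = NULL) {
  if (is.null(cultivars)) cultivars <- rownames(coded)
  a <- coded[cultivars, snp_i]
  b <- coded[cultivars, snp_j]
  hom <- c(STATE_P1, STATE_P2)
  use <- a %in% hom & b %in% hom
  ci <- map$chrom[map$id == snp_i]; cj <- map$chrom[map$id == snp_j]
  dist <- if (identical(ci, cj)) abs(map$pos[map$id == snp_j] - map$pos[map$id == snp_i]) else NA_real_
  rec <- list(snp_i = snp_i, snp_j = snp_j, distance = dist,
              d = NA_real_, d_prime = NA_real_, n_used = sum(use))
  class(rec) <- "ld_record"
  if (sum(use) == 0) return(rec)
  pA <- mean(a[use] == STATE_P1)
  pB <- mean(b[use] == STATE_P1)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(rec)
  pAB <- mean(a[use] == STATE_P1 & b[use] == STATE_P1)
  D <- pAB - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  rec$d <- D
  rec$d_prime <- if (D == 0) 0 else abs(D) / Dmax
  rec
}

#' Binned LD-decay profile
#'
#' Computes D-prime for every intra-chromosome SNP pair within `max_dist`
#' of each other, then bins pairs by physical distance and reports the
#' median D-prime per bin (the median damps the influence of outliers).
#'
#' @param coded a `coded_geno` matrix.
#' @param map the retained [snp_map].
#' @param chroms chromosomes to use (default: first chromosome of the map,
#'   matching the convention of profiling decay on chromosome 1).
#' @param cultivars optional cultivar subset (e.g. the landrace group).
#' @param max_dist maximum pair distance in bp (default 5000 kb).
#' @param bin bin width in bp (default 200 kb).
#' @return A list with `pairs` (per-pair `data.frame`) and `profile`
#'   (`bin_start, bin_end, median_dprime, n_pairs`; only populated bins).
#' @export
ld_decay_profile <- function(coded, map, chroms = unique(map$chrom)[1],
                             cultivars = NULL, max_dist = 5e6, bin = 2e5) {
  res <- list()
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    if (length(sel) < 2) next
    pos <- map$pos[sel]; ids <- map$id[sel]
    for (i in seq_len(length(sel) - 1)) {
      js <- which(pos > pos[i] & pos - pos[i] <= max_dist)
      js <- js[js > i]
      for (j in js) {
        r <- dprime(coded, map, ids[i], ids[j], cultivars)
        if (!is.na(r$d_prime)) {
          res[[length(res) + 1]] <- data.frame(
            snp_i = ids[i], snp_j = ids[j], distance = r$distance,
            d_prime = r$d_prime, n_used = r$n_used, stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(res)) do.call(rbind, res) else
    data.frame(snp_i = character(0), snp_j = character(0),
               distance = numeric(0), d_prime = numeric(0), n_used = integer(0))
  if (nrow(pairs)) {
    b <- floor((pairs$distance - 1) / bin)
    agg <- stats::aggregate(list(median_dprime = pairs$d_prime),
                            by = list(bin_i = b), FUN = median)
    cnt <- as.data.frame(table(bin_i = b), stringsAsFactors = FALSE)
    agg$n_pairs <- cnt$Freq[match(agg$bin_i, as.numeric(cnt$bin_i))]
    profile <- data.frame(bin_start = agg$bin_i * bin + 1,
                          bin_end = (agg$bin_i + 1) * bin,
                          median_dprime = agg$median_dprime,
                          n_pairs = agg$n_pairs)
    profile <- profile[order(profile$bin_start), , drop = FALSE]
    rownames(profile) <- NULL
  } else {
    profile <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                          median_dprime = numeric(0), n_pairs = integer(0))
  }
  list(pairs = pairs, profile = profile)
}

#' Choose a sliding-window size from an LD-decay profile
#'
#' The decay distance is the left edge of the first bin whose median
#' D-prime falls below `theta` times the first bin's median; the window
#' size is the candidate closest to `decay distance / mean_spacing`. With
#' the panel's 200-kb mean SNP spacing, a 2-Mb decay maps to a 10-SNP
#' window.
#'
#' @param profile profile `data.frame` from [ld_decay_profile()].
#' @param mean_spacing mean inter-SNP distance in bp (see [mean_spacing()]).
#' @param candidates candidate window sizes in SNPs.
#' @param theta decay criterion as a fraction of the first-bin median
#'   (default 0.5).
#' @return The chosen window size `k` (integer), with attribute
#'   `decay_distance` (bp; `NA` when no bin decays, in which case the
#'   largest candidate is returned with a warning).
#' @export
choose_window <- function(profile, mean_spacing, candidates = c(2, 5, 10, 15),
                          theta = 0.5) {
  if (nrow(profile) == 0) stop("empty LD profile")
  ref <- profile$median_dprime[1]
  hit <- which(profile$median_dprime < theta * ref)
  if (!length(hit)) {
    warning("no decay below ", theta, " of the first-bin median; using largest candidate")
    return(structure(max(candidates), decay_distance = NA_real_))
  }
  decay <- profile$bin_start[hit[1]] - 1  # left edge of the decayed bin
  k <- candidates[which.min(abs(candidates - decay / mean_spacing))]
  structure(k, decay_distance = decay)
}

#' Sliding-window haplotype diversity
#'
#' Moves a `k`-SNP window along each chromosome one SNP at a time. For each
#' window and cultivar group, the haplotype of a cultivar is its string of
#' `k` homozygous states; cultivars with a heterozygous or missing call
#' anywhere in the window are excluded from the haplotype count. The
#' diversity index is the number of distinct haplotypes divided by the full
#' group size. Chromosomes with fewer than `k` SNPs, or whose mean window
#' physical length exceeds `max_window_mb` megabases (too sparse for the
#' index to be meaningful), are skipped with a warning.
#'
#' @param coded a `coded_geno` matrix.
#' @param map the retained [snp_map].
#' @param groups named integer/character vector: group label per cultivar.
#' @param k window size in SNPs (default 10).
#' @param max_window_mb sparse-chromosome skip threshold (default 10 Mb).
#' @return A long `data.frame`: `chrom, win, start, end` (bp of first/last
#'   SNP), `group, n_hap, n_eligible, n_cultivars, index` (`NA` when no
#'   cultivar in the group is eligible).
#' @export
haplotype_windows <- function(coded, map, groups, k = 10, max_window_mb = 10) {
  groups <- groups[names(groups) %in% rownames(coded)]
  res <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    m <- length(sel)
    if (m < k) {
      warning("chromosome ", ch, " has fewer than ", k, " SNPs; skipped")
      next
    }
    lens <- map$pos[sel[k:m]] - map$pos[sel[1:(m - k + 1)]]
    if (mean(lens) > max_window_mb * 1e6) {
      warning("chromosome ", ch, " mean ", k, "-SNP window exceeds ",
              max_window_mb, " Mb; skipped")
      next
    }
    sub <- coded[names(groups), map$id[sel], drop = FALSE]
    ok <- sub == STATE_P1 | sub == STATE_P2
    for (w in seq_len(m - k + 1)) {
      cols <- w:(w + k - 1)
      elig <- rowSums(ok[, cols, drop = FALSE]) == k
      strings <- if (any(elig)) {
        apply(sub[elig, cols, drop = FALSE], 1, paste, collapse = "")
      } else character(0)
      for (gr in sort(unique(groups))) {
        in_g <- groups[elig] == gr
        n_hap <- length(unique(strings[in_g]))
        n_g <- sum(groups == gr)
        res[[length(res) + 1]] <- data.frame(
          chrom = ch, win = w, start = map$pos[sel[w]],
          end = map$pos[sel[w + k - 1]], group = gr,
          n_hap = n_hap, n_eligible = sum(in_g), n_cultivars = n_g,
          index = if (sum(in_g) == 0) NA_real_ else n_hap / n_g,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) stop("no usable chromosome for the requested window size")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Friedman test across cultivar groups
#'
#' Compares diversity indices among groups using windows as blocks: within
#' each window the group indices are ranked (average ranks on ties) and the
#' Friedman chi-square statistic with tie correction is computed, with a
#' chi-square approximation on `groups - 1` degrees of freedom. Windows
#' with an undefined index in any group are dropped. Delegates to
#' [stats::friedman.test()].
#'
#' @param windows output of [haplotype_windows()].
#' @param per_chromosome if `TRUE`, one test per chromosome; otherwise one
#'   genome-wide test over all windows.
#' @return A `data.frame` with `chrom` (`"*"` genome-wide), `statistic`,
#'   `df`, `p_value`, `n_windows`.
#' @export
friedman_groups <- function(windows, per_chromosome = FALSE) {
  run_one <- function(w, label) {
    wide <- stats::reshape(w[, c("chrom", "win", "group", "index")],
                           idvar = c("chrom", "win"), timevar = "group",
                           direction = "wide")
    mat <- as.matrix(wide[, -(1:2), drop = FALSE])
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) < 3) stop("fewer than 3 complete windows; Friedman approximation invalid")
    k <- ncol(mat)
    if (all(apply(mat, 1, function(r) length(unique(r)) == 1))) {
      # every window fully tied: no rank information, no group effect
      return(data.frame(chrom = label, statistic = 0, df = k - 1,
                        p_value = 1, n_windows = nrow(mat),
                        stringsAsFactors = FALSE))
    }
    ft <- stats::friedman.test(mat)
    data.frame(chrom = label, statistic = unname(ft$statistic),
               df = unname(ft$parameter), p_value = ft$p.value,
               n_windows = nrow(mat), stringsAsFactors = FALSE)
  }
  if (per_chromosome) {
    do.call(rbind, lapply(unique(windows$chrom),
                          function(ch) run_one(windows[windows$chrom == ch, ], ch)))
  } else {
    run_one(windows, "*")
  }
}
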