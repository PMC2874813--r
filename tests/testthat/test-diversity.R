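test_that("D-prime reproduces hand-computed two-locus tables", {
  map <- two_locus_map()
  # complete disequilibrium: only AB and ab haplotypes
  expect_equal(dprime(two_locus_coded(5, 0, 0, 5), map, "s1", "s2")$d_prime, 1)
  # equilibrium: all four haplotypes at 0.25
  expect_equal(dprime(two_locus_coded(5, 5, 5, 5), map, "s1", "s2")$d_prime, 0)
  # frequencies 0.4 / 0.1 / 0.2 / 0.3: D = 0.10, Dmax = 0.20, D' = 0.5
  r <- dprime(two_locus_coded(4, 1, 2, 3), map, "s1", "s2")
  expect_equal(r$d, 0.1)
  expect_equal(r$d_prime, 0.5)
  expect_equal(r$n_used, 10)
  # monomorphic after exclusion: undefined
  expect_true(is.na(dprime(two_locus_coded(5, 0, 5, 0), map, "s1", "s2")$d_prime))
})

test_that("D-prime matches the brute-force Lewontin oracle and label swaps", {
  set.seed(91)
  map <- two_locus_map()
  for (i in 1:200) {
    n <- sample(c(10, 25, 40), 1)
    counts <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    co <- two_locus_coded(counts[1], counts[2], counts[3], counts[4])
    got <- dprime(co, map, "s1", "s2")$d_prime
    want <- oracle_dprime(counts[1], counts[2], counts[3], counts[4])
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want, tolerance = 1e-12)
    # swapping allele labels at locus 1 leaves |D'| unchanged
    sw <- co
    sw[, "s1"] <- ifelse(co[, "s1"] == "P1", "P2", "P1")
    got_sw <- dprime(sw, map, "s1", "s2")$d_prime
    if (!is.na(want)) expect_equal(got_sw, want, tolerance = 1e-12)
  }
})

test_that("HET and MISSING cultivars are excluded from the pair count", {
  map <- two_locus_map()
  co <- two_locus_coded(5, 0, 0, 5)
  co[1, "s1"] <- "HET"
  co[2, "s2"] <- "MISSING"
  r <- dprime(co, map, "s1", "s2")
  expect_equal(r$n_used, 8)
  expect_equal(r$d_prime, 1)
})

test_that("LD profiles bin pairs and behave on degenerate panels", {
  # identical cultivars: every pair monomorphic, profile empty
  s <- small_sim(seed = 61)
  ident <- s$coded[rep("T", 6), ]
  rownames(ident) <- paste0("c", 1:6)
  class(ident) <- "coded_geno"
  p <- ld_decay_profile(ident, s$qc_map, chroms = "chr01")
  expect_equal(nrow(p$profile), 0)
  # two-founder panel without recombination: perfect LD in every bin
  s0 <- small_sim(seed = 63, cM_per_Mb = 0)
  two <- s0$coded[c("F1", "F2", "F1", "F2", "F1", "F2"), ]
  rownames(two) <- paste0("c", 1:6)
  class(two) <- "coded_geno"
  p2 <- ld_decay_profile(two, s0$qc_map, chroms = "chr01")
  expect_gt(nrow(p2$profile), 0)
  expect_true(all(p2$profile$median_dprime == 1))
  # distances respect the cutoff and bins are 200 kb wide
  expect_true(all(p2$pairs$distance <= 5e6))
  expect_equal(unique(p2$profile$bin_end - p2$profile$bin_start), 2e5 - 1)
})

test_that("median D-prime decays with distance on recombining panels", {
  s <- small_sim(seed = 65)
  panel <- s$coded
  p <- ld_decay_profile(panel, s$qc_map, chroms = c("chr01", "chr02"))
  expect_gt(nrow(p$profile), 3)
  rho <- suppressWarnings(
    stats::cor(p$profile$bin_start, p$profile$median_dprime, method = "spearman"))
  expect_lte(rho, 0)
})

test_that("window size selection maps decay distance to the nearest candidate", {
  prof <- data.frame(bin_start = seq(1, 4.8e6 + 1, by = 2e5),
                     bin_end = seq(2e5, 5e6, by = 2e5))
  prof$median_dprime <- ifelse(prof$bin_start < 2e6, 0.8, 0.3)
  prof$n_pairs <- 10
  expect_equal(as.numeric(choose_window(prof, 2e5)), 10)
  expect_equal(attr(choose_window(prof, 2e5), "decay_distance"), 2e6)
  prof$median_dprime <- ifelse(prof$bin_start < 4e5, 0.8, 0.3)
  expect_equal(as.numeric(choose_window(prof, 2e5)), 2)
  flat <- transform(prof, median_dprime = 1)
  expect_warning(k <- choose_window(flat, 2e5), "largest")
  expect_equal(as.numeric(k), 15)
})

test_that("window haplotype counts match the distinct-string oracle", {
  lens <- c(chrA = 2e6)
  map <- snp_map(chrom = rep("chrA", 3), pos = c(5e5, 1e6, 1.5e6),
                 id = paste0("s", 1:3), allele_a = rep("A", 3),
                 allele_b = rep("G", 3), chrom_lengths = lens)
  co <- coded_rows(map, a = "112", b = "112", c = "122", d = "222")
  groups <- setNames(rep(1, 4), c("a", "b", "c", "d"))
  w <- haplotype_windows(co, map, groups, k = 3)
  expect_equal(nrow(w), 1)
  expect_equal(w$n_hap, 3)
  expect_equal(w$index, 0.75)
  # all cultivars identical: index = 1/n
  co2 <- coded_rows(map, a = "112", b = "112", c = "112", d = "112")
  w2 <- haplotype_windows(co2, map, groups, k = 3)
  expect_equal(w2$index, 0.25)
})

test_that("the window walk is exhaustive and agrees with a set-of-strings oracle", {
  s <- small_sim(seed = 67)
  groups <- setNames(rep(1:2, length.out = nrow(s$coded)), rownames(s$coded))
  k <- 5
  w <- haplotype_windows(s$coded, s$qc_map, groups, k = k)
  for (ch in unique(w$chrom)) {
    m <- sum(s$qc_map$chrom == ch)
    expect_equal(length(unique(w$win[w$chrom == ch])), m - k + 1)
  }
  # spot-check 30 random windows against an independent tally
  set.seed(68)
  rows <- w[sample(nrow(w), 30), ]
  for (i in seq_len(nrow(rows))) {
    ch <- rows$chrom[i]; win <- rows$win[i]; gr <- rows$group[i]
    ids <- s$qc_map$id[s$qc_map$chrom == ch][win:(win + k - 1)]
    members <- names(groups)[groups == gr]
    strs <- apply(s$coded[members, ids, drop = FALSE], 1, paste, collapse = "")
    ok <- !grepl("HET|MISSING", strs)
    expect_equal(rows$n_hap[i], length(unique(strs[ok])))
    expect_equal(rows$index[i], length(unique(strs[ok])) / length(members))
  }
  # duplicating a cultivar never increases the haplotype count
  dup <- s$coded[c(rownames(s$coded), "T"), ]
  rownames(dup) <- c(rownames(s$coded), "Tdup")
  class(dup) <- "coded_geno"
  g2 <- setNames(c(groups, groups[["T"]]), rownames(dup))
  w_dup <- haplotype_windows(dup, s$qc_map, g2, k = k)
  expect_true(all(w_dup$n_hap[w_dup$group == groups[["T"]]] <=
                  w$n_hap[w$group == groups[["T"]]] + 0))
})

test_that("sparse chromosomes are skipped with a warning", {
  lens <- c(chrA = 2e7, chrB = 2e7)
  map <- snp_map(chrom = c(rep("chrA", 10), rep("chrB", 2)),
                 pos = c(seq(1e6, 10e6, by = 1e6), c(1e6, 1.9e7)),
                 id = paste0("s", 1:12), allele_a = rep("A", 12),
                 allele_b = rep("G", 12), chrom_lengths = lens)
  co <- structure(matrix(sample(c("P1", "P2"), 4 * 12, TRUE), 4, 12,
                         dimnames = list(paste0("c", 1:4), map$id)),
                  class = "coded_geno")
  groups <- setNames(rep(1, 4), paste0("c", 1:4))
  expect_warning(w <- haplotype_windows(co, map, groups, k = 3), "chrB")
  expect_true(all(w$chrom == "chrA"))
})

test_that("the Friedman comparison matches hand-ranked fixtures", {
  mk <- function(vals) {
    # three windows x three groups
    data.frame(chrom = "chrA", win = rep(1:3, each = 3),
               start = 0, end = 1, group = rep(1:3, 3),
               n_hap = 1, n_eligible = 3, n_cultivars = 3,
               index = vals)
  }
  # identical groups in every window: statistic 0, p = 1
  f0 <- friedman_groups(mk(rep(c(0.5, 0.5, 0.5), 3)))
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)
  # strictly ordered the same way in all three windows: Fr = 6
  f6 <- friedman_groups(mk(c(0.1, 0.2, 0.3, 0.15, 0.3, 0.6, 0.2, 0.5, 0.9)))
  expect_equal(f6$statistic, 6)
  # rank-based: invariant under within-window monotone transforms
  f6b <- friedman_groups(mk(c(0.1, 0.2, 0.3, 0.15, 0.3, 0.6, 0.2, 0.5, 0.9)^3))
  expect_equal(f6b$statistic, f6$statistic)
  expect_error(friedman_groups(mk(rep(0.5, 9))[1:6, ]), "fewer than 3")
})

test_that("a breeding bottleneck depresses the modern group's diversity index", {
  dp <- simulate_diversity_panel(seed = 29, n_snps = 800, n_g1 = 10,
                                 n_g2 = 10, n_g3 = 12, n_elite = 2)
  qc <- qc_filter(dp$raw, dp$map, refA = dp$refA, refB = dp$refB)
  coded <- code_calls(dp$raw[, qc$map$id], qc$map, refA = dp$refA, refB = dp$refB)
  w <- suppressWarnings(haplotype_windows(coded, qc$map, dp$groups, k = 5))
  m <- tapply(w$index, w$group, mean, na.rm = TRUE)
  expect_gt(m[["1"]], m[["3"]])
  fr <- friedman_groups(w)
  expect_gt(fr$statistic, 0)
  expect_lt(fr$p_value, 0.05)
})
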