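test_that("identity runs break on mismatch/HET, bridge MISSING, and are maximal", {
  map <- tiny_map()[1:4, ]
  attr(map, "chrom_lengths") <- c(chrA = 3e6)
  class(map) <- c("snp_map", "data.frame")
  co <- coded_rows(map, t1 = "1121", a1 = "1111", t2 = "1M1H", a2 = "1111")
  r <- identical_runs(co["t1", ], co["a1", ], map)
  expect_equal(r$first, c(1, 4))
  expect_equal(r$last, c(2, 4))
  expect_equal(r$n_match, c(2, 1))
  # MISSING at SNP 2 is bridged; HET at SNP 4 breaks
  r2 <- identical_runs(co["t2", ], co["a2", ], map)
  expect_equal(r2$first, 1)
  expect_equal(r2$last, 3)
  expect_equal(r2$n_match, 2)
  # a bounded bridge gap splits the run
  r3 <- identical_runs(co["t2", ], co["a2", ], map, max_gap = 0)
  expect_equal(r3$n_match, c(1, 1))
})

test_that("identity runs equal a brute-force enumeration on random rows", {
  set.seed(71)
  lens <- c(chrA = 5e6, chrB = 3e6)
  for (rep in 1:25) {
    n <- 40
    map <- snp_map(chrom = rep(names(lens), c(25, 15)),
                   pos = c(sort(sample.int(5e6 - 1, 25)), sort(sample.int(3e6 - 1, 15))),
                   id = paste0("r", 1:n), allele_a = rep("A", n),
                   allele_b = rep("G", n), chrom_lengths = lens)
    states <- c("P1", "P2", "HET", "MISSING")
    t_row <- setNames(sample(states, n, TRUE, prob = c(.4, .4, .1, .1)), map$id)
    p_row <- setNames(sample(states, n, TRUE, prob = c(.4, .4, .1, .1)), map$id)
    got <- identical_runs(t_row, p_row, map)
    want <- oracle_runs(t_row, p_row, map)
    expect_equal(got, want)
  }
})

test_that("runs convert to midpoint-bounded blocks with the length filter", {
  lens <- c(chrA = 3e6)
  map <- snp_map(chrom = rep("chrA", 7), pos = seq(2e5, 2.6e6, by = 4e5),
                 id = paste0("s", 1:7), allele_a = rep("A", 7),
                 allele_b = rep("G", 7), chrom_lengths = lens)
  runs <- data.frame(chrom = "chrA", first = 2L, last = 6L, n_match = 5L)
  b <- runs_to_blocks(runs, map, min_length = 5e5)
  expect_equal(b$start, 4e5)
  expect_equal(b$end, 2.4e6)
  expect_equal(b$length, 2e6)
  expect_equal(b$density, 5 / 20)  # SNPs per 100 kb
  # run reaching the chromosome ends clamps to the termini
  all_run <- data.frame(chrom = "chrA", first = 1L, last = 7L, n_match = 7L)
  b2 <- runs_to_blocks(all_run, map, min_length = 5e5)
  expect_equal(b2$start, 1)
  expect_equal(b2$end, 3e6 + 1)
  # 499-kb span dropped, 500-kb span kept (boundary inclusive)
  one <- data.frame(chrom = "chrA", first = 3L, last = 3L, n_match = 1L)
  expect_equal(nrow(runs_to_blocks(one, map, min_length = 4e5 + 1)), 0)
  expect_equal(nrow(runs_to_blocks(one, map, min_length = 4e5)), 1)
})

test_that("donor fraction is the summed block share of the genome", {
  s <- small_sim(seed = 41)
  expect_equal(donor_fraction("T", "T", s$coded, s$qc_map), 1)
  # symmetry on complete noise-free calls
  f1 <- donor_fraction("T", "X1", s$coded, s$qc_map)
  f2 <- donor_fraction("X1", "T", s$coded, s$qc_map)
  expect_equal(f1, f2)
  expect_gt(f1, 0)
})

test_that("consensus blocks intersect per-recipient donor identity", {
  s <- small_sim(seed = 43)
  # single recipient: consensus equals that recipient's donor blocks
  one <- consensus_blocks("T", "X1", s$coded, s$qc_map)
  own <- donor_blocks("T", "X1", s$coded, s$qc_map)
  expect_equal(one[, c("chrom", "start", "end")], own[, c("chrom", "start", "end")])
  # hand-made interval intersection: [0,10) & [5,20) -> [5,10)
  a <- data.frame(start = 0, end = 10)
  b <- data.frame(start = 5, end = 20)
  expect_equal(pedhap:::intersect_intervals(a, b), data.frame(start = 5, end = 10))
})

test_that("consensus equals the per-SNP AND oracle on simulated recipients", {
  s <- small_sim(seed = 45)
  recips <- c("X1", "X2", "F1")
  got <- consensus_blocks("T", recips, s$coded, s$qc_map, min_length = 5e5)
  # oracle: AND the per-SNP comparison states, then run the block machinery
  sts <- lapply(recips, function(r)
    pedhap:::compare_states(s$coded[r, s$qc_map$id], s$coded["T", s$qc_map$id]))
  comb <- Reduce(function(a, b)
    ifelse(a == "break" | b == "break", "break",
           ifelse(a == "bridge" | b == "bridge", "bridge", "match")), sts)
  fake_t <- setNames(ifelse(comb == "break", "P2", ifelse(comb == "bridge", "MISSING", "P1")),
                     s$qc_map$id)
  fake_p <- setNames(rep("P1", nrow(s$qc_map)), s$qc_map$id)
  want <- runs_to_blocks(identical_runs(fake_t, fake_p, s$qc_map), s$qc_map,
                         min_length = 5e5)
  expect_equal(got[, c("chrom", "start", "end")], want[, c("chrom", "start", "end")])
})

test_that("dense-long flag uses strict thresholds on both axes", {
  blocks <- data.frame(chrom = "chrA", start = 0,
                       end = c(2.2e6, 2.2e6, 1.9e6),
                       length = c(2.2e6, 2.2e6, 1.9e6),
                       n_snps = c(30, 20, 40))
  blocks$density <- blocks$n_snps / (blocks$length / 1e5)
  f <- flag_dense_long_blocks(blocks)
  expect_equal(nrow(f), 1)
  expect_equal(f$n_snps, 30)
  # exactly 2 Mb or exactly 1 SNP/100 kb is not "more than"
  edge <- data.frame(chrom = "chrA", start = 0, end = 2e6, length = 2e6,
                     n_snps = 20, density = 1)
  expect_equal(nrow(flag_dense_long_blocks(edge)), 0)
})

test_that("blocks trace to the deepest uniquely matching ancestor", {
  # chromosome with 6 SNPs; target matches mother and maternal grandmother
  lens <- c(chrA = 3e6)
  map <- snp_map(chrom = rep("chrA", 6), pos = seq(2e5, 2.7e6, by = 5e5),
                 id = paste0("s", 1:6), allele_a = rep("A", 6),
                 allele_b = rep("G", 6), chrom_lengths = lens)
  ped <- pedigree(c("gm", "gf", "om", "of", "mo", "fa", "T"),
                  c(NA, NA, NA, NA, "gm", "om", "mo"),
                  c(NA, NA, NA, NA, "gf", "of", "fa"),
                  rep(1900, 7))
  co <- coded_rows(map,
    T  = "111111",
    mo = "111111", fa = "222222",
    gm = "111111", gf = "222122",
    om = "122222", of = "221212")
  aa <- assign_ancestry("T", ped, co, map)
  expect_equal(aa$blocks$origin, "gm")
  expect_equal(aa$blocks$path, "T>mo>gm")
  expect_equal(aa$blocks$start, 1)
  expect_equal(aa$blocks$end, 3e6 + 1)
  # both parents identical over the block: unidentified (gray)
  co2 <- coded_rows(map, T = "111111", mo = "111111", fa = "111111",
                    gm = "122222", gf = "212121", om = "221122", of = "212211")
  aa2 <- assign_ancestry("T", ped, co2, map)
  expect_equal(aa2$blocks$origin, "unidentified")
})

test_that("zero-recombination simulations recover whole-chromosome founders", {
  s <- small_sim(seed = 47, cM_per_Mb = 0)
  aa <- assign_ancestry("T", s$ped, s$coded, s$qc_map)
  tr <- s$truth[s$truth$cultivar == "T", ]
  rec <- segment_recovery(aa$blocks, tr, s$qc_map, min_snps = 1)
  expect_equal(attr(rec, "recovery_rate"), 1)
  expect_true(all(aa$blocks$origin %in% tr$founder))
})

test_that("attributed blocks never overlap within a chromosome", {
  s <- small_sim(seed = 49)
  aa <- assign_ancestry("T", s$ped, s$coded, s$qc_map)
  for (ch in unique(aa$blocks$chrom)) {
    b <- aa$blocks[aa$blocks$chrom == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # ancestry fractions are valid and identified + unidentified <= 1
  tab <- aa$ancestry
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
  tot <- sum(tab$fraction[!tab$origin %in% "identified_total"])
  expect_lte(tot, 1 + 1e-9)
})
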