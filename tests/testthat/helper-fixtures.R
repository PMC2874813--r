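# Small fixtures shared across test files; everything is built in code.

# A hand-laid two-chromosome map: chrA 3 Mb with SNPs every 400 kb from
# 200 kb, chrB 1 Mb with a single SNP at 500 kb.
tiny_map <- function() {
  snp_map(chrom = c(rep("chrA", 7), "chrB"),
          pos = c(seq(2e5, 2.6e6, by = 4e5), 5e5),
          id = paste0("s", 1:8),
          allele_a = rep("A", 8), allele_b = rep("G", 8),
          chrom_lengths = c(chrA = 3e6, chrB = 1e6))
}

# Coded rows over a map, from compact state strings like "112M" (1 = P1,
# 2 = P2, H = HET, M = MISSING).
coded_rows <- function(map, ...) {
  rows <- list(...)
  dec <- c(`1` = "P1", `2` = "P2", H = "HET", M = "MISSING")
  m <- t(vapply(rows, function(s) dec[strsplit(s, "")[[1]]],
                character(nrow(map))))
  dimnames(m) <- list(names(rows), map$id)
  structure(m, refA = NA, refB = NA, class = "coded_geno")
}

# Independent run-enumeration oracle: split at hard mismatches, trim each
# chunk to its first/last matching SNP.
oracle_runs <- function(trow, prow, map) {
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    a <- trow[map$id[idx]]; b <- prow[map$id[idx]]
    st <- ifelse(a == "MISSING" | b == "MISSING", "bridge",
          ifelse(a %in% c("P1", "P2") & b %in% c("P1", "P2") & a == b,
                 "match", "break"))
    chunk <- cumsum(st == "break")
    for (g in unique(chunk[st != "break"])) {
      members <- idx[chunk == g & st != "break"]
      hit <- members[st[match(members, idx)] == "match"]
      if (!length(hit)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, first = min(hit), last = max(hit),
        n_match = length(hit), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), first = integer(0),
                      last = integer(0), n_match = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Independent Lewontin D' oracle from two-locus haplotype counts, using the
# feasible-range formulation of Dmax (p11 bounded by its Frechet limits).
oracle_dprime <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p11 <- n11 / n
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- p11 - pA * pB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA, pB) - pA * pB else pA * pB - max(0, pA + pB - 1)
  abs(D) / dmax
}

# Coded two-locus matrix realizing given haplotype counts (inbred panel:
# each cultivar is one haplotype, doubled).
two_locus_coded <- function(n11, n10, n01, n00) {
  states <- rbind(
    matrix(rep(c("P1", "P1"), n11), ncol = 2, byrow = TRUE),
    matrix(rep(c("P1", "P2"), n10), ncol = 2, byrow = TRUE),
    matrix(rep(c("P2", "P1"), n01), ncol = 2, byrow = TRUE),
    matrix(rep(c("P2", "P2"), n00), ncol = 2, byrow = TRUE))
  dimnames(states) <- list(paste0("c", seq_len(nrow(states))), c("s1", "s2"))
  structure(states, class = "coded_geno")
}

two_locus_map <- function(dist = 1e5) {
  snp_map(chrom = c("chrA", "chrA"), pos = c(1e5, 1e5 + dist),
          id = c("s1", "s2"), allele_a = c("A", "A"), allele_b = c("G", "G"),
          chrom_lengths = c(chrA = 1e6 + dist))
}

# Small breeding simulation shared by block/ancestry tests.
small_sim <- function(seed = 5, cM_per_Mb = 4, n_founders = 5, n_snps = 400,
                      g = 6) {
  lens <- setNames(rep(25e6, 4), paste0("chr0", 1:4))
  map <- simulate_genome(lens, n_snps = n_snps, seed = seed)
  ids <- c(paste0("F", seq_len(n_founders - 1)), "REF")
  founders <- simulate_founders(map, n_founders, maf = 0.5, seed = seed + 1,
                                ids = ids)
  ped <- pedigree(
    cultivar = c(ids, "X1", "X2", "T"),
    mother = c(rep(NA, n_founders), "F1", "F3", "X1"),
    father = c(rep(NA, n_founders), "F2", "F4", "X2"),
    year = c(rep(1900, n_founders), 1930, 1940, 1960))
  b <- breed(ped, founders, map, g = g, fix_residual_het = TRUE,
             cM_per_Mb = cM_per_Mb, seed = seed + 2)
  qc <- qc_filter(b$raw, map, refA = "T", refB = "REF")
  coded <- code_calls(b$raw[, qc$map$id], qc$map, refA = "T", refB = "REF")
  list(map = map, qc_map = qc$map, coded = coded, ped = ped, raw = b$raw,
       truth = b$truth, founders = founders)
}
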