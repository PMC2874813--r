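# Per-SNP comparison of two coded rows: "match" (equal homozygous states),
# "bridge" (MISSING at either cultivar: neither matches nor breaks),
# "break" (differing homozygous states, or HET at either cultivar).
compare_states <- function(a, b) {
  out <- rep("break", length(a))
  out[a == STATE_MISSING | b == STATE_MISSING] <- "bridge"
  hom <- a %in% c(STATE_P1, STATE_P2, STATE_OTHER) &
         b %in% c(STATE_P1, STATE_P2, STATE_OTHER)
  out[hom & a == b] <- "match"
  out
}

#' Maximal identity runs between two cultivars
#'
#' Scans each chromosome for maximal runs of SNPs at which the two coded
#' rows carry the same homozygous state. A differing homozygous state or a
#' heterozygous call at either cultivar terminates a run; a missing call
#' neither matches nor terminates (it is bridged, up to `max_gap`
#' consecutive bridged SNPs). Runs are trimmed so that they start and end
#' on matching SNPs.
#'
#' @param target_row,partner_row named character vectors of coded states
#'   over the same retained SNP ids.
#' @param map the retained [snp_map].
#' @param max_gap maximum number of consecutive bridged SNPs inside a run
#'   (default `Inf`: unlimited bridging).
#' @return A `data.frame` with one row per run: `chrom`, `first`, `last`
#'   (row indices into `map`), `n_match` (matching SNPs inside).
#' @export
identical_runs <- function(target_row, partner_row, map, max_gap = Inf) {
  target_row <- target_row[map$id]; partner_row <- partner_row[map$id]
  st <- compare_states(target_row, partner_row)
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    s <- st[idx]
    run_first <- NA_integer_; run_last <- NA_integer_; n_match <- 0L; gap <- 0L
    flush <- function() {
      if (!is.na(run_first)) {
        res[[length(res) + 1]] <<- data.frame(
          chrom = ch, first = idx[run_first], last = idx[run_last],
          n_match = n_match, stringsAsFactors = FALSE)
      }
      run_first <<- NA_integer_; run_last <<- NA_integer_; n_match <<- 0L; gap <<- 0L
    }
    for (k in seq_along(s)) {
      if (s[k] == "match") {
        if (is.na(run_first)) run_first <- k
        run_last <- k; n_match <- n_match + 1L; gap <- 0L
      } else if (s[k] == "bridge") {
        gap <- gap + 1L
        if (gap > max_gap) flush()
      } else {
        flush()
      }
    }
    flush()
  }
  if (!length(res)) {
    return(data.frame(chrom = character(0), first = integer(0),
                      last = integer(0), n_match = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Physical span of a run: midpoints to the flanking non-member SNPs,
# clamped to the chromosome termini. Half-open [start, end), boundary
# rounded toward the lower coordinate.
run_span <- function(first, last, map) {
  ch <- map$chrom[first]
  idx <- which(map$chrom == ch)
  L <- chrom_lengths(map)[[ch]]
  start <- if (first == idx[1]) 1 else (map$pos[first - 1] + map$pos[first]) %/% 2
  end <- if (last == idx[length(idx)]) L + 1 else (map$pos[last] + map$pos[last + 1]) %/% 2
  c(start = start, end = end)
}

#' Convert identity runs to physical haplotype blocks
#'
#' Each run becomes a physical interval bounded by the midpoints between
#' its first/last matching SNP and the adjacent non-member SNPs (chromosome
#' termini when the run reaches the first or last SNP). Blocks shorter than
#' `min_length` are dropped. Density is reported as matching SNPs per
#' 100 kb.
#'
#' @param runs output of [identical_runs()].
#' @param map the retained [snp_map].
#' @param min_length minimum block length in bp (default 500 kb).
#' @return A `data.frame` of blocks: `chrom, start, end, length, n_snps,
#'   density, origin` (origin `NA` until attributed).
#' @export
runs_to_blocks <- function(runs, map, min_length = 5e5) {
  if (nrow(runs) == 0) return(empty_blocks())
  spans <- t(vapply(seq_len(nrow(runs)),
                    function(i) run_span(runs$first[i], runs$last[i], map),
                    c(start = 0, end = 0)))
  out <- data.frame(chrom = runs$chrom, start = spans[, "start"],
                    end = spans[, "end"], n_snps = runs$n_match,
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out$density <- out$n_snps / (out$length / 1e5)
  out$origin <- NA_character_
  out <- out[out$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "length", "n_snps", "density", "origin")]
}

empty_blocks <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             length = numeric(0), n_snps = integer(0), density = numeric(0),
             origin = character(0), stringsAsFactors = FALSE)
}

# Is the target row identical to the candidate row over map rows in `idx`
# under the run rules (no homozygous mismatch, no HET, at least one match)?
identical_over <- function(target_row, candidate_row, map, idx) {
  st <- compare_states(target_row[map$id[idx]], candidate_row[map$id[idx]])
  all(st != "break") && any(st == "match")
}

#' Attribute haplotype blocks to pedigree ancestors
#'
#' Extracts the target's identity blocks versus its two parents (maximal
#' regions at least `min_length` long matching the mother only, the father
#' only, or both) and traces each single-parent block upward through the
#' pedigree. At every generation the block region is re-segmented by
#' identity against the current ancestor's own parents: sub-regions
#' matching one parent only recurse into that parent, sub-regions matching
#' both parents become `"unidentified"` (they may have come through either
#' lineage), and sub-regions matching neither stop at the current ancestor.
#' Attribution therefore reaches the deepest uniquely consistent ancestor,
#' splitting blocks wherever an intermediate ancestor's own recombination
#' breakpoints fall inside them. Lineages whose genotypes are absent from
#' the matrix terminate at the last genotyped ancestor.
#'
#' @param target target cultivar id.
#' @param ped a [pedigree].
#' @param coded a `coded_geno` matrix.
#' @param map the retained [snp_map].
#' @param min_length minimum block length in bp (default 500 kb), applied
#'   to the first-generation blocks; deeper splits are kept whole.
#' @return A list with `blocks` (`chrom, start, end, length, n_snps,
#'   density, origin, path`; `path` is the pedigree chain walked) and
#'   `ancestry`, a `data.frame` of per-origin total block length and genome
#'   fraction (including `"unidentified"` and an `identified_total` row).
#' @export
assign_ancestry <- function(target, ped, coded, map, min_length = 5e5) {
  if (!target %in% rownames(coded)) stop("target not genotyped")
  if (!target %in% ped$cultivar || is.na(ped_mother(ped, target))) {
    stop("target has no recorded parents")
  }
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    L <- chrom_lengths(map)[[ch]]
    res <- c(res, attribute_region(target, target, ped, coded, map, idx,
                                   1, L + 1, target, min_length, top = TRUE))
  }
  blocks <- if (length(res)) do.call(rbind, res) else {
    b <- empty_blocks(); b$path <- character(0); b
  }
  rownames(blocks) <- NULL
  list(blocks = blocks, ancestry = ancestry_table(blocks, map))
}

ped_mother <- function(ped, id) {
  m <- ped$mother[ped$cultivar == id]
  if (length(m) == 0) NA_character_ else m
}
ped_father <- function(ped, id) {
  f <- ped$father[ped$cultivar == id]
  if (length(f) == 0) NA_character_ else f
}

# Recursive attribution of the region [lo, hi) on one chromosome (map rows
# `idx`), known to be identical to `node` (trivially so when node is the
# target itself). The unique-parent test runs at block granularity: the
# region goes to a parent iff that parent is identical over the whole
# region and the other is not; if both are, the region is "unidentified".
# When neither parent spans the region, it is a mosaic: the region is
# re-segmented by the maximal identity runs versus each parent. Stretches
# matched by both parents' runs are genuine ambiguity when they are at
# least `min_length` long (emitted "unidentified"); shorter ones are
# boundary noise from coincidental matches and are split at their midpoint
# between the flanking single-parent stretches.
attribute_region <- function(target, node, ped, coded, map, idx, lo, hi,
                             path, min_length, top = FALSE) {
  mo <- ped_mother(ped, node); fa <- ped_father(ped, node)
  emit_node <- function() {
    if (top) list() else list(make_block(map, idx, lo, hi, node, path))
  }
  if (is.na(mo)) return(emit_node())
  mo_g <- mo %in% rownames(coded); fa_g <- fa %in% rownames(coded)
  if (!mo_g && !fa_g) return(emit_node())
  mo_full <- mo_g && identical_over(coded[target, ], coded[mo, ], map, idx)
  fa_full <- fa_g && identical_over(coded[target, ], coded[fa, ], map, idx)
  if (mo_full && fa_full) {
    return(list(make_block(map, idx, lo, hi, "unidentified", path)))
  }
  if (mo_full) {
    return(attribute_region(target, mo, ped, coded, map, idx, lo, hi,
                            paste(path, mo, sep = ">"), min_length))
  }
  if (fa_full) {
    return(attribute_region(target, fa, ped, coded, map, idx, lo, hi,
                            paste(path, fa, sep = ">"), min_length))
  }
  # mosaic: re-segment by per-parent maximal runs within the region
  sub <- map[idx, , drop = FALSE]
  attr(sub, "chrom_lengths") <- chrom_lengths(map)
  class(sub) <- class(map)
  in_m <- run_membership(if (mo_g) identical_runs(coded[target, ], coded[mo, ], sub) else NULL,
                         length(idx))
  in_f <- run_membership(if (fa_g) identical_runs(coded[target, ], coded[fa, ], sub) else NULL,
                         length(idx))
  lab <- resolve_labels(in_m, in_f, map$pos[idx], min_length)
  out <- list()
  runs <- split(seq_along(lab), cumsum(c(TRUE, lab[-1] != lab[-length(lab)])))
  pos <- map$pos[idx]
  for (k in seq_along(runs)) {
    r <- runs[[k]]
    l <- lab[r[1]]
    sub_lo <- if (k == 1) lo else (pos[r[1] - 1] + pos[r[1]]) %/% 2
    sub_hi <- if (k == length(runs)) hi else (pos[tail(r, 1)] + pos[tail(r, 1) + 1]) %/% 2
    if (top && (sub_hi - sub_lo) < min_length) next
    sub_idx <- idx[r]
    if (l == "none") {
      if (!top) out <- c(out, list(make_block(map, sub_idx, sub_lo, sub_hi, node, path)))
    } else if (l == "both") {
      out <- c(out, list(make_block(map, sub_idx, sub_lo, sub_hi,
                                    "unidentified", path)))
    } else {
      nxt <- if (l == "M") mo else fa
      out <- c(out, attribute_region(target, nxt, ped, coded, map, sub_idx,
                                     sub_lo, sub_hi,
                                     paste(path, nxt, sep = ">"), min_length))
    }
  }
  out
}

# Logical membership vector: which of the n region SNPs fall inside a
# maximal identity run (bridged SNPs interior to a run count as covered).
run_membership <- function(runs, n) {
  out <- rep(FALSE, n)
  if (!is.null(runs) && nrow(runs)) {
    for (i in seq_len(nrow(runs))) out[runs$first[i]:runs$last[i]] <- TRUE
  }
  out
}

# Per-SNP labels "M", "F", "both", "none" with contested stretches
# (covered by runs of both parents) resolved. A stretch counts as genuine
# shared ancestry (kept "both") only when it spans at least min_length bp
# AND contains at least `min_snps_both` SNPs: chance identity between two
# unrelated inbred lines halves per independent biallelic SNP, so requiring
# 10 supporting SNPs bounds the false-ambiguity rate near 0.1% per
# position. Shorter stretches are boundary noise from coincidental matches
# and are split at their midpoint between the flanking single-parent
# labels (or absorbed entirely when only one side flanks).
resolve_labels <- function(in_m, in_f, pos, min_length, min_snps_both = 10) {
  lab <- rep("none", length(in_m))
  lab[in_m & !in_f] <- "M"
  lab[!in_m & in_f] <- "F"
  lab[in_m & in_f] <- "both"
  w <- which(lab == "both")
  if (!length(w)) return(lab)
  zones <- split(w, cumsum(c(TRUE, diff(w) != 1)))
  for (z in zones) {
    if (!length(z)) next
    span <- span_bp(z, pos)
    if (span >= min_length && length(z) >= min_snps_both) next
    left <- if (z[1] > 1) lab[z[1] - 1] else NA
    right <- if (tail(z, 1) < length(lab)) lab[tail(z, 1) + 1] else NA
    left <- if (identical(left, "M") || identical(left, "F")) left else NA
    right <- if (identical(right, "M") || identical(right, "F")) right else NA
    if (is.na(left) && is.na(right)) next
    if (is.na(left)) { lab[z] <- right; next }
    if (is.na(right) || left == right) { lab[z] <- left; next }
    cut <- ceiling(length(z) / 2)
    lab[z[seq_len(cut)]] <- left
    lab[z[-seq_len(cut)]] <- right
  }
  lab
}

# bp span of a set of consecutive SNP indices, midpoint-bounded.
span_bp <- function(z, pos) {
  lo <- if (z[1] > 1) (pos[z[1] - 1] + pos[z[1]]) %/% 2 else pos[z[1]]
  hi <- if (tail(z, 1) < length(pos)) (pos[tail(z, 1)] + pos[tail(z, 1) + 1]) %/% 2
        else pos[tail(z, 1)]
  hi - lo
}

make_block <- function(map, idx, lo, hi, origin, path) {
  len <- hi - lo
  data.frame(chrom = map$chrom[idx[1]], start = lo, end = hi, length = len,
             n_snps = length(idx), density = length(idx) / (len / 1e5),
             origin = origin, path = path, stringsAsFactors = FALSE)
}

ancestry_table <- function(blocks, map) {
  G <- genome_length(map)
  if (nrow(blocks) == 0) {
    return(data.frame(origin = character(0), total_bp = numeric(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(total_bp = blocks$length),
                          by = list(origin = blocks$origin), FUN = sum)
  agg$fraction <- agg$total_bp / G
  named <- agg$origin != "unidentified"
  rbind(agg,
        data.frame(origin = "identified_total",
                   total_bp = sum(agg$total_bp[named]),
                   fraction = sum(agg$fraction[named])))
}

#' Genome fraction a recipient shares with a donor
#'
#' Sum of the lengths of all donor-identity blocks of at least `min_length`
#' divided by the total genome length.
#'
#' @param donor,recipient cultivar ids.
#' @param coded a `coded_geno` matrix.
#' @param map the retained [snp_map].
#' @param min_length minimum block length in bp (default 500 kb).
#' @return A fraction in \[0, 1\].
#' @export
donor_fraction <- function(donor, recipient, coded, map, min_length = 5e5) {
  runs <- identical_runs(coded[recipient, ], coded[donor, ], map)
  blocks <- runs_to_blocks(runs, map, min_length)
  sum(blocks$length) / genome_length(map)
}

#' Donor-identity blocks of a recipient
#'
#' Convenience wrapper: maximal identity runs of `recipient` vs `donor`
#' converted to physical blocks.
#' @inheritParams donor_fraction
#' @return Block `data.frame` as from [runs_to_blocks()].
#' @export
donor_blocks <- function(donor, recipient, coded, map, min_length = 5e5) {
  runs_to_blocks(identical_runs(coded[recipient, ], coded[donor, ], map),
                 map, min_length)
}

#' Consensus haplotype blocks among several recipients
#'
#' Intersects the donor-identity blocks of every recipient: a consensus
#' region is an interval over which each recipient is identical to the
#' donor. Regions shorter than `min_length` are dropped. Regions at least
#' `long_threshold` long are additionally labeled with the donor's own
#' ancestral origin when `donor_ancestry` (block table from
#' [assign_ancestry()] run on the donor) is supplied: the origin of the
#' donor block with the largest overlap.
#'
#' @param donor donor cultivar id.
#' @param recipients character vector of recipient ids (at least one).
#' @param coded a `coded_geno` matrix.
#' @param map the retained [snp_map].
#' @param min_length minimum consensus length in bp (default 500 kb).
#' @param long_threshold length above which regions are origin-labeled
#'   (default 1 Mb).
#' @param donor_ancestry optional donor block table with `origin`.
#' @return A `data.frame`: `chrom, start, end, length, n_snps, long,
#'   origin`.
#' @export
consensus_blocks <- function(donor, recipients, coded, map, min_length = 5e5,
                             long_threshold = 1e6, donor_ancestry = NULL) {
  if (length(recipients) < 1) stop("need at least one recipient")
  per <- lapply(recipients, function(r) donor_blocks(donor, r, coded, map,
                                                     min_length = 0))
  res <- list()
  for (ch in unique(map$chrom)) {
    segs <- lapply(per, function(b) b[b$chrom == ch, , drop = FALSE])
    cur <- segs[[1]][, c("start", "end")]
    for (b in segs[-1]) cur <- intersect_intervals(cur, b[, c("start", "end")])
    if (nrow(cur)) res[[length(res) + 1]] <- data.frame(chrom = ch, cur)
  }
  if (!length(res)) {
    out <- empty_blocks(); out$long <- logical(0); return(out)
  }
  out <- do.call(rbind, res)
  out$length <- out$end - out$start
  out <- out[out$length >= min_length, , drop = FALSE]
  out$n_snps <- vapply(seq_len(nrow(out)), function(i) {
    sum(map$chrom == out$chrom[i] & map$pos >= out$start[i] & map$pos < out$end[i])
  }, 0L)
  out$long <- out$length >= long_threshold
  out$origin <- NA_character_
  if (!is.null(donor_ancestry) && any(out$long)) {
    for (i in which(out$long)) {
      da <- donor_ancestry[donor_ancestry$chrom == out$chrom[i], , drop = FALSE]
      if (!nrow(da)) next
      ov <- pmin(da$end, out$end[i]) - pmax(da$start, out$start[i])
      if (max(ov) > 0) out$origin[i] <- da$origin[which.max(ov)]
    }
  }
  rownames(out) <- NULL
  out
}

# Intersection of two sets of disjoint sorted half-open intervals.
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, , drop = FALSE])
  res <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
    ok <- e > s
    if (any(ok)) res[[length(res) + 1]] <- data.frame(start = s[ok], end = e[ok])
  }
  if (!length(res)) return(a[0, , drop = FALSE])
  out <- do.call(rbind, res)
  out[order(out$start), , drop = FALSE]
}

#' Flag long, SNP-dense haplotype blocks
#'
#' Returns the blocks strictly longer than `min_len` whose SNP density is
#' strictly above `min_density` (SNPs per 100 kb) — the blocks whose
#' ancestral attribution is best supported.
#'
#' @param blocks block `data.frame` with `length` and `density`.
#' @param min_len length threshold in bp (default 2 Mb).
#' @param min_density density threshold in SNPs per 100 kb (default 1).
#' @return The flagged subset of `blocks`.
#' @export
flag_dense_long_blocks <- function(blocks, min_len = 2e6, min_density = 1) {
  blocks[blocks$length > min_len & blocks$density > min_density, , drop = FALSE]
}

#' Write blocks as BED
#'
#' 0-based half-open BED with `name` = origin (or partner) and `score` =
#' SNP count.
#' @param blocks block table.
#' @param path output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  name <- if (all(is.na(blocks$origin))) "." else ifelse(is.na(blocks$origin), ".", blocks$origin)
  out <- data.frame(chrom = blocks$chrom, start = as.integer(blocks$start - 1),
                    end = as.integer(blocks$end - 1), name = name,
                    score = blocks$n_snps)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
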