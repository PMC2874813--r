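#' Read CDS gene models from GFF3
#'
#' Extracts CDS features, grouped into gene models by their `Parent` (or
#' `ID`) attribute. Models whose total CDS length is not a multiple of 3
#' after phase adjustment are flagged; SNPs falling in flagged models get
#' effect class `"unknown"`.
#'
#' @param path GFF3 path.
#' @return A named list of models; each has `gene`, `chrom`, `strand`,
#'   `exons` (`data.frame` `start, end`, 1-based inclusive, sorted),
#'   `phase` (of the first codon on the coding strand) and `flagged`.
#' @export
read_cds_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", path)
  par_list <- cds$Parent
  gene <- if (!is.null(par_list)) {
    vapply(as.list(par_list), function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, length(cds))
  gene[is.na(gene)] <- as.character(cds$ID[is.na(gene)])
  models <- list()
  for (g in unique(gene)) {
    sub <- cds[gene == g]
    ord <- order(GenomicRanges::start(sub))
    sub <- sub[ord]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    exons <- data.frame(start = GenomicRanges::start(sub),
                        end = GenomicRanges::end(sub))
    ph <- sub$phase
    phase <- if (strand == "+") ph[1] else ph[length(ph)]
    if (is.null(phase) || is.na(phase)) phase <- 0L
    total <- sum(exons$end - exons$start + 1) - phase
    models[[g]] <- list(gene = g, chrom = as.character(GenomicRanges::seqnames(sub))[1],
                        strand = strand, exons = exons, phase = as.integer(phase),
                        flagged = (total %% 3) != 0)
  }
  models
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spliced CDS coordinates (genomic positions in coding order) for a model.
cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)),
                       function(i) model$exons$start[i]:model$exons$end[i]))
  if (model$strand == "-") pos <- rev(pos)
  if (model$phase > 0) pos <- pos[-seq_len(model$phase)]
  pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify SNP effects against CDS models
#'
#' For every SNP overlapping a CDS, the affected codon is rebuilt from the
#' reference sequence on the coding strand (reverse-complemented for
#' minus-strand genes), the reference allele is checked against the genome,
#' and the substituted codon is translated under the standard genetic code.
#' Classes: `synonymous`, `nonsynonymous`, `stop_gained` (alternative codon
#' is a stop, reference is not), `stop_lost`, `noncoding` (outside every
#' CDS), `unknown` (model flagged as length-inconsistent). A substitution
#' destroying the initiator ATG is classed `nonsynonymous` with
#' `note = "start_lost"`.
#'
#' @param map a [snp_map] (alleles `allele_a`/`allele_b`; one of the two
#'   must match the reference base at the SNP position).
#' @param models gene models from [read_cds_models()].
#' @param genome a [Biostrings::DNAStringSet] of reference chromosomes.
#' @return A `data.frame` with one row per (SNP, overlapping gene) pair —
#'   plus one `gene = NA` row per noncoding SNP: `id, gene, class,
#'   ref_codon, alt_codon, ref_aa, alt_aa, note`.
#' @export
classify_snp_effects <- function(map, models, genome) {
  res <- list()
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(map))) {
    chrom <- map$chrom[i]; pos <- map$pos[i]
    ref_base <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
    alleles <- c(map$allele_a[i], map$allele_b[i])
    if (!ref_base %in% alleles) {
      stop("reference allele mismatch at SNP ", map$id[i],
           ": genome has ", ref_base)
    }
    alt_base <- setdiff(alleles, ref_base)[1]
    hit <- FALSE
    for (model in models) {
      if (model$chrom != chrom) next
      if (!any(pos >= model$exons$start & pos <= model$exons$end)) next
      hit <- TRUE
      if (model$flagged) {
        res[[length(res) + 1]] <- effect_row(map$id[i], model$gene, "unknown")
        next
      }
      cpos <- cds_positions(model)
      k <- match(pos, cpos)
      if (is.na(k)) {  # inside exon bounds but trimmed by phase
        res[[length(res) + 1]] <- effect_row(map$id[i], model$gene, "unknown")
        next
      }
      codon_i <- (k - 1) %/% 3
      cidx <- cpos[(codon_i * 3 + 1):(codon_i * 3 + 3)]
      bases <- vapply(cidx, function(p)
        as.character(Biostrings::subseq(genome[[chrom]], p, p)), "")
      if (model$strand == "-") bases <- unname(COMPLEMENT[bases])
      ref_codon <- paste(bases, collapse = "")
      within <- which(cidx == pos)
      sub_base <- if (model$strand == "-") unname(COMPLEMENT[alt_base]) else alt_base
      alt_bases <- bases
      alt_bases[within] <- sub_base
      alt_codon <- paste(alt_bases, collapse = "")
      ref_aa <- code[[ref_codon]]
      alt_aa <- code[[alt_codon]]
      cls <- if (ref_aa == alt_aa) "synonymous"
             else if (alt_aa == "*" && ref_aa != "*") "stop_gained"
             else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
             else "nonsynonymous"
      note <- if (codon_i == 0 && ref_codon == "ATG" && alt_codon != "ATG") {
        if (cls == "synonymous") cls <- "nonsynonymous"
        "start_lost"
      } else NA_character_
      res[[length(res) + 1]] <- effect_row(map$id[i], model$gene, cls,
                                           ref_codon, alt_codon, ref_aa, alt_aa,
                                           note)
    }
    if (!hit) res[[length(res) + 1]] <- effect_row(map$id[i], NA_character_, "noncoding")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

effect_row <- function(id, gene, class, ref_codon = NA, alt_codon = NA,
                       ref_aa = NA, alt_aa = NA, note = NA_character_) {
  data.frame(id = id, gene = gene, class = class,
             ref_codon = as.character(ref_codon), alt_codon = as.character(alt_codon),
             ref_aa = as.character(ref_aa), alt_aa = as.character(alt_aa),
             note = note, stringsAsFactors = FALSE)
}

CLASS_SEVERITY <- c(stop_gained = 4, stop_lost = 4, nonsynonymous = 3,
                    synonymous = 2, unknown = 1, noncoding = 0)

#' Summarize SNP effect classes
#'
#' Counts and fractions per effect class over coding SNPs (for SNPs hitting
#' several genes, the most severe class counts: stop > nonsynonymous >
#' synonymous), and per gene hit (a gene counts as nonsynonymous-hit when
#' any of its SNPs is nonsynonymous or stop-affecting; genes with both a
#' synonymous and a nonsynonymous SNP are also tallied separately).
#' Percentages are printed to one decimal.
#'
#' @param effects output of [classify_snp_effects()].
#' @return A list of class `effect_summary`: `n_coding_snps`,
#'   `n_nonsynonymous`, `n_synonymous`, `n_stop_gained`, `n_stop_lost`,
#'   `n_genes`, `n_genes_nonsyn`, `n_genes_syn`, `n_genes_both`, and the
#'   derived `pct_nonsyn_snps`, `pct_syn_snps`, `pct_genes_nonsyn`,
#'   `pct_genes_syn`, `pct_genes_both` (all `NA`-safe on empty input).
#' @export
summarize_effects <- function(effects) {
  coding <- effects[!effects$class %in% c("noncoding", "unknown") &
                    !is.na(effects$gene), , drop = FALSE]
  if (nrow(coding)) {
    sev <- CLASS_SEVERITY[coding$class]
    per_snp <- coding[order(coding$id, -sev), , drop = FALSE]
    per_snp <- per_snp[!duplicated(per_snp$id), , drop = FALSE]
  } else per_snp <- coding
  nonsyn_cls <- c("nonsynonymous", "stop_gained", "stop_lost")
  genes <- unique(coding$gene)
  g_non <- unique(coding$gene[coding$class %in% nonsyn_cls])
  g_syn <- unique(coding$gene[coding$class == "synonymous"])
  effect_summary(n_coding_snps = nrow(per_snp),
                 n_nonsynonymous = sum(per_snp$class %in% nonsyn_cls),
                 n_synonymous = sum(per_snp$class == "synonymous"),
                 n_stop_gained = sum(per_snp$class == "stop_gained"),
                 n_stop_lost = sum(per_snp$class == "stop_lost"),
                 n_genes = length(genes),
                 n_genes_nonsyn = length(g_non),
                 n_genes_syn = length(g_syn),
                 n_genes_both = length(intersect(g_non, g_syn)))
}

#' Effect-class fractions from counts
#'
#' The same arithmetic as [summarize_effects()], starting from tabulated
#' counts (e.g. a published coding-SNP tally): percentages of coding SNPs
#' and of hit genes, rounded to one decimal.
#'
#' @param n_coding_snps,n_nonsynonymous,n_synonymous counts of coding SNPs.
#' @param n_stop_gained,n_stop_lost stop-affecting SNP counts.
#' @param n_genes,n_genes_nonsyn,n_genes_syn,n_genes_both gene tallies.
#' @return A list of class `effect_summary` (see [summarize_effects()]).
#' @export
effect_summary <- function(n_coding_snps = 0, n_nonsynonymous = 0,
                           n_synonymous = 0, n_stop_gained = 0,
                           n_stop_lost = 0, n_genes = 0, n_genes_nonsyn = 0,
                           n_genes_syn = 0, n_genes_both = 0) {
  pct <- function(x, n) if (n > 0) round(100 * x / n, 1) else NA_real_
  structure(list(
    n_coding_snps = n_coding_snps, n_nonsynonymous = n_nonsynonymous,
    n_synonymous = n_synonymous, n_stop_gained = n_stop_gained,
    n_stop_lost = n_stop_lost, n_genes = n_genes,
    n_genes_nonsyn = n_genes_nonsyn, n_genes_syn = n_genes_syn,
    n_genes_both = n_genes_both,
    pct_nonsyn_snps = pct(n_nonsynonymous, n_coding_snps),
    pct_syn_snps = pct(n_synonymous, n_coding_snps),
    pct_genes_nonsyn = pct(n_genes_nonsyn, n_genes),
    pct_genes_syn = pct(n_genes_syn, n_genes),
    pct_genes_both = pct(n_genes_both, n_genes)
  ), class = "effect_summary")
}
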