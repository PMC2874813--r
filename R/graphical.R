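#' Convert a coded genotype row to physical color segments
#'
#' Consecutive SNPs sharing a state merge into one segment; segment borders
#' sit at the midpoint between adjacent SNPs (rounded toward the lower
#' coordinate), and the first/last SNP's state extends to the chromosome
#' termini, so the segments of each chromosome tile it exactly. A
#' chromosome with no retained SNPs yields a single MISSING segment.
#'
#' @param coded_row named character vector of states over the map's SNPs.
#' @param map the retained [snp_map].
#' @return A `data.frame`: `chrom, start, end, state` (half-open bp).
#' @export
segment_row <- function(coded_row, map) {
  lens <- chrom_lengths(map)
  res <- list()
  for (ch in names(lens)) {
    sel <- which(map$chrom == ch)
    L <- lens[[ch]]
    if (!length(sel)) {
      res[[length(res) + 1]] <- data.frame(chrom = ch, start = 1, end = L + 1,
                                           state = STATE_MISSING,
                                           stringsAsFactors = FALSE)
      next
    }
    st <- unname(coded_row[map$id[sel]])
    pos <- map$pos[sel]
    keep <- c(TRUE, st[-1] != st[-length(st)])
    first <- which(keep)
    last <- c(first[-1] - 1L, length(st))
    start <- ifelse(first == 1L, 1, (pos[pmax(first - 1, 1)] + pos[first]) %/% 2)
    end <- ifelse(last == length(st), L + 1, (pos[last] + pos[pmin(last + 1, length(st))]) %/% 2)
    res[[length(res) + 1]] <- data.frame(chrom = ch, start = start, end = end,
                                         state = st[first], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

GG_COLORS <- c(P1 = "#1f6fd0", P2 = "#f5d000", HET = "#145a20",
               MISSING = "#9a9a9a", OTHER = "#b06fd0")

#' Render graphical genotypes as SVG
#'
#' Draws one horizontal bar per cultivar, chromosomes side by side. Segment
#' width is `round(length_bp * scale / 1e6)` pixels, floored at `min_px`
#' (at the default 13 px/Mb a segment shorter than about 77 kb collapses
#' to a single pixel). Colors: P1 blue, P2 yellow, HET dark green, MISSING
#' gray. Output is deterministic: the same input yields a byte-identical
#' document.
#'
#' @param coded a `coded_geno` matrix (or a subset of its rows).
#' @param map the retained [snp_map].
#' @param path output SVG path; `NULL` returns the SVG text invisibly.
#' @param scale pixels per Mb (default 13).
#' @param min_px minimum segment width in pixels (default 1).
#' @param row_height bar height in pixels.
#' @param order optional cultivar ordering (e.g. by development year).
#' @return The SVG document as a character vector of lines, invisibly.
#' @export
render_graphical <- function(coded, map, path = NULL, scale = 13, min_px = 1,
                             row_height = 12, order = rownames(coded)) {
  lens <- chrom_lengths(map)
  gap <- 4L
  chrom_px <- vapply(lens, function(L) seg_px(L, scale, min_px), 0L)
  x0 <- cumsum(c(0L, head(chrom_px + gap, -1)))
  names(x0) <- names(lens)
  width <- sum(chrom_px) + gap * (length(lens) - 1)
  height <- length(order) * (row_height + 2L)
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   max(width, 1L), max(height, 1L)))
  y <- 0L
  for (cult in order) {
    segs <- segment_row(coded[cult, ], map)
    for (ch in names(lens)) {
      s <- segs[segs$chrom == ch, , drop = FALSE]
      x <- x0[[ch]]
      for (i in seq_len(nrow(s))) {
        w <- seg_px(s$end[i] - s$start[i], scale, min_px)
        out <- c(out, sprintf(
          '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"><title>%s %s:%d-%d %s</title></rect>',
          x, y, w, row_height, GG_COLORS[[s$state[i]]], cult, ch,
          as.integer(s$start[i]), as.integer(s$end[i] - 1), s$state[i]))
        x <- x + w
      }
    }
    y <- y + row_height + 2L
  }
  out <- c(out, "</svg>")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Pixel width of a physical length
#'
#' `round(length_bp * scale / 1e6)`, floored at `min_px` — the cell-width
#' arithmetic of the graphical genotype (13 px per Mb; anything below about
#' 77 kb becomes a single pixel).
#' @param length_bp segment length in bp.
#' @param scale pixels per Mb (default 13).
#' @param min_px minimum width (default 1).
#' @return Integer pixel width.
#' @export
seg_px <- function(length_bp, scale = 13, min_px = 1) {
  max(as.integer(round(length_bp * scale / 1e6)), as.integer(min_px))
}

#' Write genotype segments as BED
#'
#' 0-based half-open BED with the state as the name column.
#' @param segments output of [segment_row()].
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  out <- data.frame(chrom = segments$chrom,
                    start = as.integer(segments$start - 1),
                    end = as.integer(segments$end - 1),
                    name = segments$state)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
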