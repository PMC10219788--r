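# Deterministic SVG 1.1 writer: plain text, fixed number formatting, fonts
# referenced by name only, so identical inputs yield byte-identical files.

svg_num <- function(x) sprintf("%.2f", x)

svg_open <- function(width, height) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            svg_num(width), svg_num(height), svg_num(width), svg_num(height)))
}

svg_rect <- function(x, y, w, h, fill, stroke = "none", class = NULL,
                     stroke_width = 1) {
  sprintf('<rect%s x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
          if (is.null(class)) "" else sprintf(' class="%s"', class),
          svg_num(x), svg_num(y), svg_num(w), svg_num(h), fill, stroke,
          svg_num(stroke_width))
}

svg_line <- function(x1, y1, x2, y2, stroke = "#000000", class = NULL,
                     stroke_width = 1) {
  sprintf('<line%s x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
          if (is.null(class)) "" else sprintf(' class="%s"', class),
          svg_num(x1), svg_num(y1), svg_num(x2), svg_num(y2), stroke,
          svg_num(stroke_width))
}

svg_text <- function(x, y, text, size = 10, fill = "#000000", class = NULL,
                     anchor = "start", extra = "") {
  sprintf('<text%s x="%s" y="%s" font-family="Helvetica" font-size="%s" fill="%s" text-anchor="%s"%s>%s</text>',
          if (is.null(class)) "" else sprintf(' class="%s"', class),
          svg_num(x), svg_num(y), svg_num(size), fill, anchor, extra,
          xml_escape(text))
}

svg_polygon <- function(points, fill, stroke = "none", class = NULL) {
  pts <- paste(vapply(points, function(p) {
    paste0(svg_num(p[1]), ",", svg_num(p[2]))
  }, character(1)), collapse = " ")
  sprintf('<polygon%s points="%s" fill="%s" stroke="%s"/>',
          if (is.null(class)) "" else sprintf(' class="%s"', class),
          pts, fill, stroke)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

PATH_PALETTE <- c("#F1C232", "#6FA8DC", "#93C47D", "#C27BA0", "#E06666",
                  "#76A5AF", "#A64D79", "#B45F06", "#674EA7", "#999999")

# fixed residue palette (Clustal-like groups for amino acids)
AA_COLORS <- c(A = "#80A0F0", C = "#F08080", D = "#C048C0", E = "#C048C0",
               F = "#80A0F0", G = "#F09048", H = "#15A4A4", I = "#80A0F0",
               K = "#F01505", L = "#80A0F0", M = "#80A0F0", N = "#15C015",
               P = "#C0C000", Q = "#15C015", R = "#F01505", S = "#15C015",
               T = "#15C015", V = "#80A0F0", W = "#80A0F0", Y = "#15A4A4")
NT_COLORS <- c(A = "#5CB85C", C = "#428BCA", G = "#F0AD4E", T = "#D9534F",
               U = "#D9534F")

#' Render the locus annotation plot as SVG
#'
#' One horizontal track per record, in record order: a coordinate ruler,
#' outlined grey glyphs for non-conserved candidate ORFs, filled glyphs
#' (one color per conserved path) for path members, tick marks for
#' Shine-Dalgarno annotations, and an arrowhead marking the mORF 5' end at
#' the right edge of each upstream region. Output is deterministic SVG 1.1.
#'
#' @param records an [upstream_set()].
#' @param paths list of `conserved_path` objects (may be empty).
#' @param all_candidates named list of candidate ORF lists, as from
#'   [find_orfs()] (may be `NULL` if `paths` is non-empty).
#' @param out output SVG path.
#' @param width figure width in px.
#' @return `out`, invisibly.
#' @export
render_annotation_plot <- function(records, paths, all_candidates = NULL,
                                   out, width = 900) {
  stopifnot(inherits(records, "upstream_set"))
  if (length(records) == 0L) stop("no records to plot")
  if ((is.null(paths) || !length(paths)) &&
      (is.null(all_candidates) || !sum(lengths(all_candidates)))) {
    stop("nothing to plot: no paths and no candidates")
  }
  n <- length(records)
  track_h <- 46; top <- 30; left <- 170; right <- 25
  height <- top + n * track_h + 15
  maxlen <- max(nchar(records$sequence))
  xscale <- (width - left - right) / maxlen
  px <- function(pos) left + pos * xscale

  conserved_keys <- list()
  for (pi in seq_along(paths)) {
    for (o in paths[[pi]]$members) {
      conserved_keys[[member_key(o)]] <- pi
    }
  }

  lines <- svg_open(width, height)
  lines <- c(lines, svg_text(left, 16, sprintf("upstream regions (%d record(s), max %d nt)",
                                               n, maxlen), size = 11))
  for (i in seq_len(n)) {
    y0 <- top + (i - 1) * track_h
    ry <- y0 + 26
    slen <- nchar(records$sequence[i])
    lines <- c(lines, svg_text(8, ry + 4, records$id[i], size = 10,
                               class = "track-label"))
    lines <- c(lines, svg_line(px(0), ry, px(slen), ry, stroke = "#555555",
                               class = "track-ruler"))
    # mORF 5' end glyph at the right edge of the upstream region
    lines <- c(lines, svg_polygon(list(c(px(slen), ry - 7), c(px(slen), ry + 7),
                                       c(px(slen) + 9, ry)),
                                  fill = "none", stroke = "#2E7D32",
                                  class = "morf-start"))
    draw <- function(o) {
      key <- member_key(o)
      x <- px(o$start); w <- max((o$end - o$start) * xscale, 1)
      if (!is.null(conserved_keys[[key]])) {
        col <- PATH_PALETTE[(conserved_keys[[key]] - 1) %% length(PATH_PALETTE) + 1]
        el <- svg_rect(x, ry - 8, w, 16, fill = col, stroke = "#000000",
                       class = "orf-conserved")
      } else {
        el <- svg_rect(x, ry - 6, w, 12, fill = "none", stroke = "#9E9E9E",
                       class = "orf-candidate")
      }
      sd_el <- character(0)
      if (!is.null(o$sd)) {
        sx <- px(o$sd$window_start + o$sd$match_offset)
        sd_el <- svg_line(sx, ry - 13, sx, ry - 9, stroke = "#D32F2F",
                          class = "sd-mark", stroke_width = 2)
      }
      c(el, sd_el)
    }
    cands <- all_candidates[[records$id[i]]]
    drawn <- character(0)
    if (!is.null(cands)) {
      for (o in cands) {
        if (!identical(o$strand, "+")) next
        lines <- c(lines, draw(o)); drawn <- c(drawn, member_key(o))
      }
    }
    for (p in paths) {                 # members not among listed candidates
      o <- p$members[[records$id[i]]]
      if (!is.null(o) && !(member_key(o) %in% drawn)) lines <- c(lines, draw(o))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, out)
  invisible(out)
}

#' Render a sequence logo as SVG
#'
#' One letter stack per alignment column; letter heights are proportional to
#' `freq * info` (bits), columns scaled so that the maximum attainable
#' information spans the stack height. Zero-information columns render as
#' empty stacks. Deterministic output.
#'
#' @param logo a `logo_matrix` from [logo_stats()].
#' @param out output SVG path.
#' @return `out`, invisibly.
#' @export
render_logo <- function(logo, out) {
  stopifnot(inherits(logo, "logo_matrix"))
  nc <- ncol(logo$freq)
  if (nc == 0L) stop("empty logo")
  colw <- 22; stack_h <- 120; left <- 40; top <- 15; bottom <- 30
  width <- left + nc * colw + 15
  height <- top + stack_h + bottom
  max_bits <- log2(length(logo$alphabet))
  pal <- if (length(logo$alphabet) == 4L) NT_COLORS else AA_COLORS
  lines <- svg_open(width, height)
  lines <- c(lines,
             svg_line(left, top, left, top + stack_h, stroke = "#000000"),
             svg_text(left - 5, top + 8, sprintf("%.1f", max_bits), size = 8,
                      anchor = "end"),
             svg_text(left - 5, top + stack_h, "0", size = 8, anchor = "end"))
  for (j in seq_len(nc)) {
    x <- left + (j - 1) * colw
    ybase <- top + stack_h
    ord <- order(logo$freq[, j], seq_len(nrow(logo$freq))) # tallest drawn last
    for (i in ord) {
      f <- logo$freq[i, j]
      if (f <= 0) next
      h <- f * logo$info[j] / max_bits * stack_h
      if (h < 0.05) next
      sym <- rownames(logo$freq)[i]
      col <- if (!is.na(pal[sym])) pal[sym] else "#333333"
      lines <- c(lines, svg_text(
        x + colw / 2, ybase, sym, size = 10, fill = unname(col),
        class = "logo-letter", anchor = "middle",
        extra = sprintf(' transform="translate(0,%s) scale(1,%s) translate(0,%s)"',
                        svg_num(ybase), svg_num(h / 10), svg_num(-ybase))))
      ybase <- ybase - h
    }
    lines <- c(lines, svg_text(x + colw / 2, top + stack_h + 14,
                               as.character(j), size = 8, anchor = "middle",
                               class = "logo-col-index"))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, out)
  invisible(out)
}

#' Render a multiple sequence alignment panel as SVG
#'
#' One row per sequence (input order), residues drawn as colored cells with
#' the residue letter, gaps as white cells; row labels are the record ids.
#' Deterministic output.
#'
#' @param aln a `uorf_alignment` from [center_star_msa()].
#' @param out output SVG path.
#' @return `out`, invisibly.
#' @export
render_msa <- function(aln, out) {
  stopifnot(inherits(aln, "uorf_alignment"))
  cw <- 14; ch <- 18; left <- 150; top <- 10
  width <- left + aln$n_cols * cw + 10
  height <- top + length(aln$ids) * ch + 10
  pal <- if (aln$alphabet == "nucleotide") NT_COLORS else AA_COLORS
  lines <- svg_open(width, height)
  for (i in seq_along(aln$ids)) {
    y <- top + (i - 1) * ch
    lines <- c(lines, svg_text(8, y + ch - 5, aln$ids[i], size = 10,
                               class = "msa-label"))
    chars <- strsplit(aln$rows[i], "", fixed = TRUE)[[1]]
    for (j in seq_along(chars)) {
      x <- left + (j - 1) * cw
      if (chars[j] == "-") {
        lines <- c(lines, svg_rect(x, y, cw, ch, fill = "#FFFFFF",
                                   stroke = "#DDDDDD", class = "msa-gap"))
      } else {
        col <- pal[chars[j]]
        lines <- c(lines, svg_rect(x, y, cw, ch,
                                   fill = if (is.na(col)) "#BBBBBB" else unname(col),
                                   stroke = "#FFFFFF", class = "msa-cell"),
                   svg_text(x + cw / 2, y + ch - 5, chars[j], size = 10,
                            anchor = "middle", class = "msa-letter"))
      }
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, out)
  invisible(out)
}
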