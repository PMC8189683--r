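# Minimal deterministic SVG emission. All geometry is formatted with fixed
# precision and no timestamps or random ids, so re-rendering the same model
# is byte-identical.

fmt <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))

svg_header <- function(width, height) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(width), fmt(height), fmt(width), fmt(height)),
    '<defs>',
    '<pattern id="hatch" width="6" height="6" patternTransform="rotate(45)" patternUnits="userSpaceOnUse">',
    '<line x1="0" y1="0" x2="0" y2="6" stroke="#555555" stroke-width="1.5"/>',
    '</pattern>',
    '</defs>')
}

svg_text <- function(x, y, s, size = 11, anchor = "start", style = "") {
  sprintf('<text x="%s" y="%s" font-family="Helvetica,Arial,sans-serif" font-size="%s" text-anchor="%s"%s>%s</text>',
          fmt(x), fmt(y), fmt(size), anchor,
          if (nzchar(style)) paste0(" ", style) else "", xml_escape(s))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# arrow polygon for one gene glyph; points right for '+' strand (strands are
# already normalized so the query points right)
gene_arrow_points <- function(x, width, y, half_height, strand) {
  head_len <- min(8, 0.4 * width)
  if (strand != "-") {
    pts <- rbind(c(x, y - half_height),
                 c(x + width - head_len, y - half_height),
                 c(x + width, y),
                 c(x + width - head_len, y + half_height),
                 c(x, y + half_height))
  } else {
    pts <- rbind(c(x + width, y - half_height),
                 c(x + head_len, y - half_height),
                 c(x, y),
                 c(x + head_len, y + half_height),
                 c(x + width, y + half_height))
  }
  paste(apply(pts, 1L, function(p) paste(fmt(p[1L]), fmt(p[2L]), sep = ",")),
        collapse = " ")
}

ROW_HEIGHT <- 52
ROW_TOP <- 30
GENE_HALF_H <- 9
LABEL_W <- 150

#' Render the neighbourhood diagram as SVG text
#'
#' Draws one row per query: a left label (query accession and assembly) and
#' one arrow glyph per gene, to scale, coloured and numbered by
#' conservation group. Output is deterministic: the same model renders to
#' byte-identical text.
#'
#' @param model A `render_model` from [build_render_model()].
#' @return A single string of SVG markup.
#' @export
render_diagram_svg <- function(model) {
  stopifnot(inherits(model, "render_model"))
  rows <- model$rows
  xmax <- max(vapply(rows, function(r) max(r$x + r$width), 0)) + LABEL_W + 20
  h <- ROW_TOP + ROW_HEIGHT * length(rows) + 10
  out <- svg_header(xmax, h)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    nb <- model$neighbourhoods[[i]]
    y <- ROW_TOP + ROW_HEIGHT * (i - 1L) + ROW_HEIGHT / 2
    lab <- sprintf("%s (%s)%s", nb$query_protein_id, nb$assembly_id,
                   if (nb$flipped) " *" else "")
    out <- c(out, svg_text(4, y + 4, lab, size = 11))
    for (j in seq_len(nrow(r))) {
      out <- c(out, sprintf('<polygon points="%s" fill="%s" stroke="%s" stroke-width="1.5"/>',
                            gene_arrow_points(LABEL_W + r$x[j], r$width[j], y,
                                              GENE_HALF_H, r$strand[j]),
                            r$fill[j], r$stroke[j]))
      if (nzchar(r$label[j]))
        out <- c(out, svg_text(LABEL_W + r$x[j] + r$width[j] / 2, y - GENE_HALF_H - 3,
                               r$label[j], size = 10, anchor = "middle"))
    }
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}
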