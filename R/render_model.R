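#' Resolve layout geometry for one neighbourhood row
#'
#' Computes to-scale x-extents and style tokens for every gene of one
#' neighbourhood. Gene lengths and intergenic gaps are proportional to their
#' base-pair spans at `bp_per_px`; the row is anchored so the query start
#' falls at `anchor_px`, which lets callers align queries vertically across
#' rows. Truncated sides simply end at the last real gene - no placeholder
#' glyphs are emitted.
#'
#' Styles: conserved genes are filled with their group colour (the query
#' family with the reserved query colour); non-conserved coding genes are
#' unfilled with a grey border; pseudogenes are grey-filled with a blue
#' border; non-coding genes use a hatch fill.
#'
#' @param nb A `neighbourhood`.
#' @param nb_index Index of this neighbourhood in the run (to look up nodes).
#' @param assignment A `group_assignment` covering the neighbourhood.
#' @param palette Colour map from [assign_colours()].
#' @param bp_per_px Scale in base pairs per pixel (> 0).
#' @param anchor_px Pixel x at which the query gene starts.
#' @return Data.frame with one row per gene in drawn order: `slot`, `x`,
#'   `width`, `strand`, `kind`, `protein_id`, `group_id`, `label`, `fill`,
#'   `stroke`, `start`, `end`, `product`.
#' @export
layout_row <- function(nb, nb_index, assignment, palette, bp_per_px = 20,
                       anchor_px = 0) {
  stopifnot(inherits(nb, "neighbourhood"), inherits(assignment, "group_assignment"),
            bp_per_px > 0)
  g <- nb$genes
  if (any(g$end < g$start)) stop("zero-length gene in neighbourhood", call. = FALSE)
  qs <- g$start[g$slot == 0L]
  nodes <- assignment$nodes[assignment$nodes$nb == nb_index, , drop = FALSE]

  out <- data.frame(slot = g$slot,
                    x = anchor_px + (g$start - qs) / bp_per_px,
                    width = (g$end - g$start + 1) / bp_per_px,
                    strand = g$strand, kind = g$kind,
                    protein_id = g$protein_id,
                    group_id = NA_integer_, label = "",
                    fill = STYLE_NONCONSERVED_FILL,
                    stroke = STYLE_NONCONSERVED_STROKE,
                    start = g$start, end = g$end, product = g$product,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (out$kind[i] == "pseudogene") {
      out$fill[i] <- STYLE_PSEUDO_FILL; out$stroke[i] <- STYLE_PSEUDO_STROKE
    } else if (out$kind[i] == "noncoding") {
      out$fill[i] <- STYLE_NONCODING_FILL; out$stroke[i] <- STYLE_NONCODING_STROKE
    } else {
      j <- which(nodes$slot == out$slot[i])
      if (length(j) == 1L && !is.na(nodes$group_id[j])) {
        gid <- nodes$group_id[j]
        out$group_id[i] <- gid
        out$label[i] <- as.character(gid)
        out$fill[i] <- unname(palette[as.character(gid)])
        out$stroke[i] <- STYLE_DEFAULT_STROKE
      }
      # coding but unnumbered (non-conserved, or missing sequence):
      # keep the empty/grey-border default
    }
  }
  out
}

#' Build the full render model for a run
#'
#' Combines neighbourhoods, group assignment and palette into a resolved
#' model holding per-row geometry and the legend table. Rows keep query
#' input order and are anchored so all query genes start in one vertical
#' column.
#'
#' @param neighbourhoods List of `neighbourhood` objects, in query input
#'   order.
#' @param assignment A `group_assignment` over those neighbourhoods.
#' @param palette From [assign_colours()].
#' @param bp_per_px Scale in base pairs per pixel.
#' @return A `render_model`: list with `rows` (list of layout data.frames),
#'   `neighbourhoods`, `legend` (one row per numbered group: `group_id`,
#'   `colour`, `product` (most common member annotation), `protein_ids`,
#'   `member_count`, `neighbourhood_count`), `bp_per_px`, `palette`,
#'   `assignment`.
#' @export
build_render_model <- function(neighbourhoods, assignment, palette,
                               bp_per_px = 20) {
  stopifnot(length(neighbourhoods) >= 1L)
  # anchor: leave room for the widest upstream extent
  up_px <- vapply(seq_along(neighbourhoods), function(i) {
    g <- neighbourhoods[[i]]$genes
    (g$start[g$slot == 0L] - min(g$start)) / bp_per_px
  }, 0)
  anchor <- max(up_px) + 10
  rows <- lapply(seq_along(neighbourhoods), function(i)
    layout_row(neighbourhoods[[i]], i, assignment, palette, bp_per_px, anchor))

  legend <- build_legend(neighbourhoods, assignment, palette)
  structure(list(rows = rows, neighbourhoods = neighbourhoods,
                 legend = legend, bp_per_px = bp_per_px,
                 palette = palette, assignment = assignment),
            class = "render_model")
}

build_legend <- function(neighbourhoods, assignment, palette) {
  grp <- assignment$groups
  if (nrow(grp) == 0L)
    return(data.frame(group_id = integer(0), colour = character(0),
                      product = character(0), protein_ids = character(0),
                      member_count = integer(0), neighbourhood_count = integer(0)))
  nodes <- assignment$nodes
  # product annotations come from the neighbourhood gene tables
  prod_of <- function(nb, slot) {
    g <- neighbourhoods[[nb]]$genes
    g$product[g$slot == slot]
  }
  rows <- lapply(seq_len(nrow(grp)), function(k) {
    gid <- grp$group_id[k]
    sel <- which(!is.na(nodes$group_id) & nodes$group_id == gid)
    prods <- vapply(sel, function(j) prod_of(nodes$nb[j], nodes$slot[j]), "")
    prods <- prods[nzchar(prods)]
    rep_prod <- if (length(prods)) names(sort(table(prods), decreasing = TRUE))[1L] else ""
    data.frame(group_id = gid,
               colour = unname(palette[as.character(gid)]),
               product = rep_prod,
               protein_ids = paste(sort(unique(nodes$protein_id[sel])), collapse = ","),
               member_count = grp$member_count[k],
               neighbourhood_count = grp$neighbourhood_count[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.render_model <- function(x, ...) {
  cat(sprintf("<render_model> %d row(s), %d legend group(s), %g bp/px\n",
              length(x$rows), nrow(x$legend), x$bp_per_px))
  invisible(x)
}
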