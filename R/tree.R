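#' Build a guide tree over the query proteins
#'
#' Neighbour-joining on pairwise distances `1 - fractional identity`, where
#' fractional identity comes from the built-in local aligner. The tree is
#' midpoint-rooted. Leaves are processed in lexicographic name order so tie
#' situations resolve deterministically; negative branch lengths produced by
#' neighbour joining are clamped to zero (with a warning).
#'
#' @param sequences Named character vector of query protein sequences
#'   (names are the query identifiers; at least 2).
#' @return An [ape::phylo] tree, midpoint-rooted, with non-negative branch
#'   lengths.
#' @export
build_guide_tree <- function(sequences) {
  if (length(sequences) < 2L)
    stop("need at least 2 query sequences to build a tree; run with tree = \"off\"",
         call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))) ||
      anyDuplicated(names(sequences)))
    stop("query sequences must have unique non-empty names", call. = FALSE)
  sequences <- sequences[order(names(sequences))]  # deterministic tie-breaks
  d <- 1 - sw_pid_matrix(sequences) / 100
  tr <- if (length(sequences) == 2L) {
    # nj needs >= 3 leaves; a 2-leaf tree is a single split
    ape::read.tree(text = sprintf("(%s:%f,%s:%f);", names(sequences)[1L],
                                  d[1, 2] / 2, names(sequences)[2L], d[1, 2] / 2))
  } else {
    ape::nj(as.dist(d))
  }
  if (any(tr$edge.length < 0)) {
    warning("negative neighbour-joining branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr <- phangorn::midpoint(tr)
  if (any(tr$edge.length < 0)) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# node coordinates for a simple left-to-right cladogram: x = distance from
# root, y = tip index in plotting (cladewise) order, internal = mean of
# children
tree_coords <- function(phy) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  x <- ape::node.depth.edgelength(phy)
  y <- numeric(ntip + nnode)
  tip_order <- phy$edge[phy$edge[, 2L] <= ntip, 2L]
  y[tip_order] <- seq_along(tip_order)
  for (i in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[i, 1L]
    ch <- phy$edge[phy$edge[, 1L] == p, 2L]
    y[p] <- mean(y[ch])
  }
  list(phy = phy, x = x, y = y, ntip = ntip, tip_order = tip_order)
}

FLAG_W <- 16
FLAG_H <- 14
TREE_ROW_H <- 40

#' Render a tree annotated with pennant flags
#'
#' Draws the tree as a left-to-right cladogram and, beside each leaf, a
#' horizontal strip of triangular pennant flags - one per gene of that
#' query's neighbourhood, in drawn order, coloured and numbered exactly as
#' in the main diagram. Strips are left-padded so the query flag of every
#' row falls in one vertical column.
#'
#' @param tree An [ape::phylo] whose tip labels are exactly the query
#'   identifiers of the model (any order).
#' @param model A `render_model`.
#' @return A single string of SVG markup (deterministic).
#' @export
annotate_tree <- function(tree, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "render_model"))
  queries <- vapply(model$neighbourhoods, function(nb) nb$query_protein_id, "")
  missing_in_tree <- setdiff(queries, tree$tip.label)
  extra_in_tree <- setdiff(tree$tip.label, queries)
  if (length(missing_in_tree) || length(extra_in_tree))
    stop(sprintf("tree leaves and queries differ: missing from tree [%s]; not queries [%s]",
                 paste(missing_in_tree, collapse = ", "),
                 paste(extra_in_tree, collapse = ", ")), call. = FALSE)

  co <- tree_coords(tree)
  phy <- co$phy
  tree_w <- 220
  xs <- if (max(co$x) > 0) co$x / max(co$x) * (tree_w - 10) else co$x
  ys <- co$y * TREE_ROW_H + 20

  max_up <- max(vapply(model$neighbourhoods, function(nb) sum(nb$genes$slot < 0), 0L))
  max_total <- max(vapply(model$neighbourhoods, function(nb) nrow(nb$genes), 0L))
  label_w <- 10 + 8 * max(nchar(phy$tip.label))
  strip_x0 <- tree_w + label_w
  width <- strip_x0 + (max_total + 1) * FLAG_W + 20
  height <- (co$ntip + 1) * TREE_ROW_H + 20

  out <- svg_header(width, height)
  # tree edges as elbows: vertical at parent's x, then horizontal to child
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    out <- c(out,
      sprintf('<polyline points="%s,%s %s,%s %s,%s" fill="none" stroke="#000000" stroke-width="1.2"/>',
              fmt(xs[p]), fmt(ys[p]), fmt(xs[p]), fmt(ys[ch]), fmt(xs[ch]), fmt(ys[ch])))
  }
  # leaf labels and flag strips (leaves in plotting order)
  for (tip in co$tip_order) {
    qid <- phy$tip.label[tip]
    i <- match(qid, queries)
    r <- model$rows[[i]]
    y <- ys[tip]
    out <- c(out, svg_text(tree_w + 4, y + 4, qid, size = 11))
    n_up <- sum(r$slot < 0)
    pad <- (max_up - n_up) * FLAG_W
    for (j in seq_len(nrow(r))) {
      fx <- strip_x0 + pad + (j - 1L) * FLAG_W
      pts <- paste(c(paste(fmt(fx), fmt(y - FLAG_H / 2), sep = ","),
                     paste(fmt(fx + FLAG_W - 3), fmt(y), sep = ","),
                     paste(fmt(fx), fmt(y + FLAG_H / 2), sep = ",")),
                   collapse = " ")
      out <- c(out, sprintf('<polygon points="%s" fill="%s" stroke="%s" stroke-width="1"/>',
                            pts, r$fill[j], r$stroke[j]))
      if (nzchar(r$label[j]))
        out <- c(out, svg_text(fx + 4, y - FLAG_H / 2 - 2, r$label[j],
                               size = 8, anchor = "middle"))
    }
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}
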