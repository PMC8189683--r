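#' Assign conservation groups to clustered proteins
#'
#' Components present in at least two distinct neighbourhoods are
#' *conserved* and receive consecutive group numbers `1..G`; numbering
#' follows descending neighbourhood count, then descending member count,
#' then first occurrence in input order (neighbourhood index, then drawn
#' slot order). Components confined to a single neighbourhood are not
#' conserved and stay unnumbered (drawn empty with a grey border). The
#' component containing the query proteins always receives a group number
#' (its reserved style marks it as the query family even when only one
#' query was analysed). Pseudogene and non-coding slots are never grouped.
#'
#' @param components Named integer vector from [cluster_components()].
#' @param graph The `hit_graph` the components were computed on.
#' @return A `group_assignment` object: list with `nodes` (data.frame:
#'   `node`, `nb`, `slot`, `protein_id`, `component`, `group_id` (`NA` when
#'   unnumbered), `conserved`, `is_query_family`) and `groups` (data.frame:
#'   `group_id`, `component`, `member_count`, `neighbourhood_count`,
#'   `is_query_family`).
#' @export
assign_groups <- function(components, graph) {
  stopifnot(inherits(graph, "hit_graph"))
  nodes <- graph$nodes
  stopifnot(all(nodes$node %in% names(components)))
  nodes$component <- unname(components[nodes$node])

  comp_ids <- sort(unique(nodes$component))
  stats <- do.call(rbind, lapply(comp_ids, function(cid) {
    sel <- nodes$component == cid
    data.frame(component = cid,
               member_count = sum(sel),
               neighbourhood_count = length(unique(nodes$nb[sel])),
               is_query_family = any(nodes$slot[sel] == 0L))
  }))
  # first occurrence: input (neighbourhood) order, then drawn slot order
  drawn_rank <- order(order(nodes$nb, nodes$slot))
  stats$first_seen <- vapply(stats$component, function(cid)
    min(drawn_rank[nodes$component == cid]), 0L)

  numbered <- stats$neighbourhood_count >= 2L | stats$is_query_family
  num <- stats[numbered, , drop = FALSE]
  ord <- order(-num$neighbourhood_count, -num$member_count, num$first_seen)
  num <- num[ord, , drop = FALSE]
  num$group_id <- seq_len(nrow(num))

  nodes$group_id <- num$group_id[match(nodes$component, num$component)]
  nodes$conserved <- stats$neighbourhood_count[match(nodes$component, stats$component)] >= 2L
  nodes$is_query_family <- stats$is_query_family[match(nodes$component, stats$component)]

  structure(list(nodes = nodes[, c("node", "nb", "slot", "protein_id", "component",
                                   "group_id", "conserved", "is_query_family")],
                 groups = num[, c("group_id", "component", "member_count",
                                  "neighbourhood_count", "is_query_family")]),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %d protein(s) in %d component(s); %d numbered group(s), %d conserved\n",
              nrow(x$nodes), length(unique(x$nodes$component)),
              nrow(x$groups), sum(x$nodes$conserved[!duplicated(x$nodes$component)])))
  invisible(x)
}

# Reserved style tokens (Fig-style semantics): the query family is a fixed
# red; non-conserved genes are unfilled with a grey border; pseudogenes are
# grey-filled with a blue border; non-coding genes use a hatch pattern.
STYLE_QUERY <- "#e41a1c"
STYLE_NONCONSERVED_FILL <- "none"
STYLE_NONCONSERVED_STROKE <- "#808080"
STYLE_PSEUDO_FILL <- "#c8c8c8"
STYLE_PSEUDO_STROKE <- "#1f77b4"
STYLE_NONCODING_FILL <- "url(#hatch)"
STYLE_NONCODING_STROKE <- "#555555"
STYLE_DEFAULT_STROKE <- "#000000"

reserved_styles <- function() {
  c(query = STYLE_QUERY, nonconserved = STYLE_NONCONSERVED_FILL,
    pseudo = STYLE_PSEUDO_FILL, noncoding = STYLE_NONCODING_FILL)
}

#' Deterministic colour palette for conservation groups
#'
#' Conserved groups get evenly spaced hues (HSV, fixed saturation and value
#' bands) in group-number order; the seed only rotates the hue phase, so the
#' same input and seed always yield the same palette. The query family keeps
#' a fixed reserved colour distinct from all palette hues.
#'
#' @param assignment A `group_assignment` from [assign_groups()].
#' @param seed Integer; perturbs the hue phase only.
#' @return Named character vector mapping `group_id` to a hex colour token.
#' @export
assign_colours <- function(assignment, seed = 0L) {
  stopifnot(inherits(assignment, "group_assignment"))
  g <- assignment$groups
  if (nrow(g) == 0L) return(setNames(character(0), character(0)))
  cols <- character(nrow(g))
  pal_idx <- which(!g$is_query_family)
  gp <- length(pal_idx)
  if (gp > 0L) {
    phase <- (as.integer(seed) * 47L) %% 360L
    hues <- (phase + (seq_len(gp) - 1L) * 360 / gp) %% 360
    cols[pal_idx] <- hsv(hues / 360, s = 0.55, v = 0.85)
  }
  cols[g$is_query_family] <- STYLE_QUERY
  setNames(cols, as.character(g$group_id))
}
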