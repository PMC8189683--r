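#' Search parameters for the homology stage
#'
#' @param evalue_cutoff Significance cut-off; pairs with E-value above this
#'   are not linked. Must be positive.
#' @param iterations Number of search iterations for the external profile
#'   backend (ignored, with a recorded warning, by the builtin backend).
#' @param backend `"builtin"` (self-contained Smith-Waterman scorer) or
#'   `"external_profile"` (an installed `jackhmmer` is invoked and its
#'   per-pair E-values are used).
#' @return A `search_params` list.
#' @export
search_params <- function(evalue_cutoff = 1e-3, iterations = 3L,
                          backend = c("builtin", "external_profile")) {
  backend <- match.arg(backend)
  stopifnot(is.numeric(evalue_cutoff), length(evalue_cutoff) == 1L, evalue_cutoff > 0,
            is.numeric(iterations), length(iterations) == 1L, iterations >= 1)
  structure(list(evalue_cutoff = evalue_cutoff,
                 iterations = as.integer(iterations),
                 backend = backend),
            class = "search_params")
}

#' Build the all-vs-all significant-similarity graph
#'
#' Every coding gene with an available protein sequence in every
#' neighbourhood (queries included) becomes a node, identified by
#' `(neighbourhood index, slot)`. All pairs are compared and undirected
#' edges are kept when the pair's E-value is at or below the cut-off. Since
#' the E-value scales with the first sequence's length, the symmetric edge
#' significance is the smaller of the two directed E-values. Pseudogene and
#' non-coding slots never enter the graph.
#'
#' @param neighbourhoods List of `neighbourhood` objects
#'   (from [extract_neighbourhood()]).
#' @param params A [search_params()] object.
#' @return A `hit_graph`: list with `nodes` (data.frame: `node`, `nb`,
#'   `slot`, `protein_id`, `seq_id`), `edges` (data.frame: `node_a`,
#'   `node_b`, `evalue`, `bitscore`), `db_residues`, `params` and
#'   `warnings`.
#' @export
build_hit_graph <- function(neighbourhoods, params = search_params()) {
  stopifnot(is.list(neighbourhoods), length(neighbourhoods) >= 1L,
            all(vapply(neighbourhoods, inherits, TRUE, "neighbourhood")),
            inherits(params, "search_params"))
  warnings <- character(0)

  nodes <- do.call(rbind, lapply(seq_along(neighbourhoods), function(i) {
    nb <- neighbourhoods[[i]]
    g <- nb$genes
    coding <- g$kind == "coding" & !is.na(g$protein_id) &
      g$protein_id %in% names(nb$proteins)
    if (!any(coding)) return(NULL)
    data.frame(node = sprintf("nb%d:s%d", i, g$slot[coding]),
               nb = i, slot = g$slot[coding],
               protein_id = g$protein_id[coding],
               seq = unname(nb$proteins[g$protein_id[coding]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes) || nrow(nodes) == 0L)
    stop("no coding proteins with sequences found in any neighbourhood", call. = FALSE)

  useqs <- unique(nodes$seq)
  names(useqs) <- sprintf("u%d", seq_along(useqs))
  nodes$seq_id <- names(useqs)[match(nodes$seq, useqs)]
  db_residues <- sum(nchar(nodes$seq))

  if (params$backend == "builtin") {
    if (params$iterations != 1L)
      warnings <- c(warnings,
        "builtin backend is non-iterative: the iterations parameter is ignored")
    ev <- builtin_evalue_matrix(useqs, db_residues)
    emat <- ev$evalue; bmat <- ev$bits
  } else {
    ev <- jackhmmer_evalue_matrix(useqs, params$iterations)
    emat <- ev$evalue; bmat <- ev$bits
  }

  # expand unique-sequence pairs to node pairs (duplicate sequences in
  # different slots are distinct nodes linked through their shared scores)
  n <- nrow(nodes)
  edges <- NULL
  if (n > 1L) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ia <- nodes$seq_id[pairs[, 1L]]
    ib <- nodes$seq_id[pairs[, 2L]]
    e <- emat[cbind(ia, ib)]
    keep <- is.finite(e) & e <= params$evalue_cutoff
    edges <- data.frame(node_a = nodes$node[pairs[keep, 1L]],
                        node_b = nodes$node[pairs[keep, 2L]],
                        evalue = e[keep],
                        bitscore = bmat[cbind(ia, ib)][keep],
                        stringsAsFactors = FALSE)
  }
  if (is.null(edges))
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        evalue = numeric(0), bitscore = numeric(0))

  structure(list(nodes = nodes[, c("node", "nb", "slot", "protein_id", "seq_id")],
                 sequences = useqs,
                 edges = edges, db_residues = db_residues,
                 params = params, warnings = warnings),
            class = "hit_graph")
}

#' @export
print.hit_graph <- function(x, ...) {
  cat(sprintf("<hit_graph> %d node(s), %d edge(s) at E <= %g (%s backend)\n",
              nrow(x$nodes), nrow(x$edges), x$params$evalue_cutoff,
              x$params$backend))
  invisible(x)
}

# symmetric E-value / bit-score matrices over unique sequences
builtin_evalue_matrix <- function(useqs, db_residues) {
  raw <- sw_score_matrix(useqs)
  bits <- bits_from_raw(raw)
  len <- nchar(useqs)
  # directed E = len(query) * db * 2^-bits; symmetrize with the minimum,
  # i.e. the shorter sequence as query
  lmin <- outer(len, len, pmin)
  list(evalue = lmin * db_residues * 2^(-bits), bits = bits)
}

jackhmmer_evalue_matrix <- function(useqs, iterations) {
  exe <- Sys.which("jackhmmer")
  if (exe == "")
    stop("external_profile backend requested but 'jackhmmer' is not on PATH; ",
         "use backend = \"builtin\" instead", call. = FALSE)
  td <- tempfile("jackhmmer"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fa <- file.path(td, "seqs.fa")
  writeLines(paste0(">", names(useqs), "\n", unname(useqs)), fa)
  tbl <- file.path(td, "hits.tbl")
  status <- system2(exe, c("-N", iterations, "--noali", "--tblout", shQuote(tbl),
                           "-E", "1000", shQuote(fa), shQuote(fa)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("jackhmmer run failed", call. = FALSE)
  lines <- readLines(tbl, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  u <- length(useqs)
  emat <- matrix(Inf, u, u, dimnames = list(names(useqs), names(useqs)))
  bmat <- matrix(0, u, u, dimnames = list(names(useqs), names(useqs)))
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 6L) next
    target <- f[1L]; query <- f[3L]
    e <- suppressWarnings(as.numeric(f[5L])); b <- suppressWarnings(as.numeric(f[6L]))
    if (is.na(e) || !target %in% names(useqs) || !query %in% names(useqs)) next
    if (e < emat[query, target]) {
      emat[query, target] <- emat[target, query] <- e
      bmat[query, target] <- bmat[target, query] <- b
    }
  }
  diag(emat) <- 0
  list(evalue = emat, bits = bmat)
}

#' Single-linkage clustering of the hit graph
#'
#' Homologous groups are the connected components of the significant-hit
#' graph: any chain of significant pairwise hits links proteins into one
#' group. Isolated nodes form singleton components.
#'
#' @param graph A `hit_graph` from [build_hit_graph()].
#' @return Integer vector of component ids (1-based, arbitrary order but
#'   deterministic for a given graph) named by node id, covering every node.
#' @export
cluster_components <- function(graph) {
  stopifnot(inherits(graph, "hit_graph"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(graph$nodes), name = graph$nodes$node)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$node_a, graph$edges$node_b))
  comp <- igraph::components(g)
  setNames(as.integer(comp$membership), igraph::V(g)$name)
}
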