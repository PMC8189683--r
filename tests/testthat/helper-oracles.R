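# Independent oracles, implemented with no shared code paths with the
# package internals they check.

# Exhaustive full-matrix Smith-Waterman with affine gaps (gap of length k
# costs open + k * extend); plain R, three explicit matrices.
sw_oracle <- function(a, b, open = 11, extend = 1,
                      sub = genecontext:::BLOSUM62) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in A (consumes B)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in B (consumes A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - extend, H[i, j - 1] - open - extend)
      F[i, j] <- max(F[i - 1, j] - extend, H[i - 1, j] - open - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Union-find with path compression; returns canonical partition labels.
union_find_oracle <- function(nodes, edge_a, edge_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edge_a)) {
    ra <- find(edge_a[k]); rb <- find(edge_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, "")
}

# Four-point-condition oracle: for 4 taxa, the generating unrooted topology
# pairs the two taxa whose within-pair distance sums are smallest.
four_point_split <- function(d) {
  stopifnot(nrow(d) == 4L)
  taxa <- rownames(d)
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                   list(c(1, 4), c(2, 3)))
  p <- pairings[[which.min(sums)]]
  lapply(p, function(ix) sort(taxa[ix]))
}

# does an unrooted 4-leaf tree contain the split {pair1}|{pair2}?
tree_has_split <- function(tree, pair) {
  ut <- ape::unroot(tree)
  parts <- ape::prop.part(ut)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  any(vapply(splits, identical, TRUE, sort(pair))) ||
    any(vapply(splits, function(s) identical(sort(setdiff(labs, s)), sort(pair)), TRUE))
}
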