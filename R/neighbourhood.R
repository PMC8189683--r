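#' Extract a gene neighbourhood around a query gene
#'
#' Collects the query gene plus up to `n` flanking genes on each side,
#' counted by gene index in the per-contig sorted feature table (pseudogenes
#' and non-coding genes occupy flank slots like coding genes). If fewer than
#' `n` genes exist toward a contig end the corresponding truncation flag is
#' set. When the query lies on the minus strand the whole neighbourhood is
#' mirrored (coordinates reflected through the contig, strands inverted,
#' sides swapped) so that the query always points right; `flipped` records
#' that this happened. Rare annotation artifacts wholly containing the query
#' are excluded from the flanks.
#'
#' @param assembly An `assembly` from [load_assembly()].
#' @param query Either a protein accession present in the assembly or a
#'   one-row record from `assembly$features`.
#' @param n Maximum number of flanking genes per side (>= 1).
#' @return An object of class `neighbourhood`: list with `genes` (data.frame
#'   in drawn left-to-right order with a `slot` column: negative = upstream,
#'   0 = query, positive = downstream; coordinates already mirrored if
#'   `flipped`), `query_protein_id`, `flipped`, `truncated_left`,
#'   `truncated_right`, `assembly_id`, `contig_id`, and `proteins` (named
#'   amino-acid sequences for the coding genes present in the FASTA).
#' @export
extract_neighbourhood <- function(assembly, query, n) {
  stopifnot(inherits(assembly, "assembly"), is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  feats <- assembly$features
  if (is.character(query)) {
    qi <- which(!is.na(feats$protein_id) & feats$protein_id == query)
    if (length(qi) == 0L)
      stop(sprintf("query %s not found in assembly %s", query, assembly$assembly_id),
           call. = FALSE)
    qi <- qi[1L]
  } else {
    qi <- which(feats$contig_id == query$contig_id & feats$start == query$start &
                  feats$end == query$end & feats$kind == query$kind)
    if (length(qi) == 0L)
      stop(sprintf("query record not found in assembly %s", assembly$assembly_id),
           call. = FALSE)
    qi <- qi[1L]
  }
  contig <- feats$contig_id[qi]
  on_contig <- which(feats$contig_id == contig)
  pos <- match(qi, on_contig)
  ctg <- feats[on_contig, , drop = FALSE]

  # drop features wholly containing the query (annotation artifacts)
  qs <- ctg$start[pos]; qe <- ctg$end[pos]
  contains <- ctg$start <= qs & ctg$end >= qe
  contains[pos] <- FALSE
  if (any(contains)) {
    keep <- !contains
    pos <- match(pos, which(keep))
    ctg <- ctg[keep, , drop = FALSE]
  }

  m <- nrow(ctg)
  left_idx <- rev(seq_len(m)[seq_len(m) < pos])           # nearest-first, genomic left
  right_idx <- seq_len(m)[seq_len(m) > pos]               # nearest-first, genomic right
  left_idx <- head(left_idx, n)
  right_idx <- head(right_idx, n)
  trunc_genomic_left <- length(left_idx) < n
  trunc_genomic_right <- length(right_idx) < n

  flipped <- ctg$strand[pos] == "-"
  if (!flipped) {
    up <- ctg[left_idx, , drop = FALSE]     # nearest-first
    down <- ctg[right_idx, , drop = FALSE]
    qrec <- ctg[pos, , drop = FALSE]
    trunc_left <- trunc_genomic_left; trunc_right <- trunc_genomic_right
  } else {
    # reflect through the contig: x -> C - x with C = contig length + 1
    L <- assembly$contigs[contig]
    if (is.na(L)) L <- max(feats$end[feats$contig_id == contig])
    reflect <- function(df) {
      s <- L + 1 - df$end; e <- L + 1 - df$start
      df$start <- s; df$end <- e
      df$strand <- ifelse(df$strand == "+", "-", ifelse(df$strand == "-", "+", df$strand))
      df
    }
    up <- reflect(ctg[right_idx, , drop = FALSE])   # genomic right becomes drawn upstream
    down <- reflect(ctg[left_idx, , drop = FALSE])
    qrec <- reflect(ctg[pos, , drop = FALSE])
    trunc_left <- trunc_genomic_right; trunc_right <- trunc_genomic_left
  }

  up$slot <- -seq_len(nrow(up))
  down$slot <- seq_len(nrow(down))
  qrec$slot <- 0L
  genes <- rbind(up[rev(seq_len(nrow(up))), , drop = FALSE], qrec, down)
  rownames(genes) <- NULL

  pids <- genes$protein_id[!is.na(genes$protein_id)]
  prots <- assembly$proteins[intersect(pids, names(assembly$proteins))]

  structure(list(genes = genes,
                 query_protein_id = qrec$protein_id,
                 flipped = flipped,
                 truncated_left = trunc_left,
                 truncated_right = trunc_right,
                 assembly_id = assembly$assembly_id,
                 contig_id = contig,
                 proteins = prots),
            class = "neighbourhood")
}

#' @export
print.neighbourhood <- function(x, ...) {
  cat(sprintf("<neighbourhood> query %s on %s/%s: %d upstream + %d downstream gene(s)%s%s\n",
              x$query_protein_id, x$assembly_id, x$contig_id,
              sum(x$genes$slot < 0), sum(x$genes$slot > 0),
              if (x$flipped) ", mirrored" else "",
              if (x$truncated_left || x$truncated_right) ", truncated at contig edge" else ""))
  invisible(x)
}
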