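#' Load a genome assembly from GFF3 annotation and protein FASTA
#'
#' Parses a RefSeq-dialect GFF3 file (CDS rows carry `protein_id` in their
#' attribute column) together with the matching amino-acid FASTA and builds
#' an indexed `assembly` object. Gene-level records are derived as follows:
#'
#' * CDS rows become `coding` records; multiple CDS segments sharing one
#'   `protein_id` on the same contig are merged into a single record
#'   spanning `min(start)..max(end)`.
#' * CDS or parent gene rows flagged `pseudo=true`, with
#'   `gene_biotype=pseudogene`, or of feature type `pseudogene` become
#'   `pseudogene` records (no protein).
#' * RNA feature types (tRNA, rRNA, ncRNA, tmRNA, ...) become `noncoding`
#'   records.
#'
#' Coordinates are kept 1-based inclusive as in GFF3. Both inputs may be
#' plain text, file paths, or gzip-compressed file paths.
#'
#' @param gff_source GFF3 input: path (optionally `.gz`), multi-line string,
#'   or character vector of lines.
#' @param faa_source Protein FASTA input, same accepted forms. Record IDs
#'   are the first whitespace-delimited token of each header.
#' @param assembly_id Identifier for this assembly (e.g. `"GCF_000001.1"`).
#' @return An object of class `assembly`: a list with `assembly_id`,
#'   `contigs` (named vector of contig lengths, `NA` when unknown),
#'   `features` (a data.frame of gene records sorted per contig by start,
#'   ties by end), `proteins` (named character vector of amino-acid
#'   sequences) and `warnings` (character vector of non-fatal issues, e.g.
#'   CDS proteins absent from the FASTA, which are flagged `missing` in
#'   `features`).
#' @seealso [locate_query()], [extract_neighbourhood()]
#' @export
load_assembly <- function(gff_source, faa_source, assembly_id) {
  stopifnot(is.character(assembly_id), length(assembly_id) == 1L, nzchar(assembly_id))
  gff <- parse_gff3(gff_source)
  proteins <- read_protein_fasta(faa_source)

  feats <- gff$features
  warnings <- character(0)
  missing <- rep(FALSE, nrow(feats))
  is_cds <- feats$kind == "coding"
  if (any(is_cds)) {
    absent <- is_cds & (is.na(feats$protein_id) | !(feats$protein_id %in% names(proteins)))
    if (any(absent)) {
      missing[absent] <- TRUE
      warnings <- c(warnings, sprintf(
        "protein %s (contig %s:%d-%d) has no sequence in the FASTA; flagged missing",
        ifelse(is.na(feats$protein_id[absent]), "<no protein_id>", feats$protein_id[absent]),
        feats$contig_id[absent], feats$start[absent], feats$end[absent]))
    }
  }
  feats$missing <- missing

  contigs <- gff$contigs
  extra <- setdiff(unique(feats$contig_id), names(contigs))
  if (length(extra)) contigs[extra] <- NA_real_
  known <- !is.na(contigs[feats$contig_id])
  if (any(known & feats$end > contigs[feats$contig_id])) {
    bad <- which(known & feats$end > contigs[feats$contig_id])[1L]
    stop(sprintf("feature at %s:%d-%d exceeds declared contig length %d",
                 feats$contig_id[bad], feats$start[bad], feats$end[bad],
                 contigs[feats$contig_id[bad]]), call. = FALSE)
  }

  ord <- order(match(feats$contig_id, names(contigs)), feats$start, feats$end)
  feats <- feats[ord, , drop = FALSE]
  rownames(feats) <- NULL

  structure(list(assembly_id = assembly_id, contigs = contigs,
                 features = feats, proteins = proteins,
                 warnings = warnings),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %s: %d contig(s), %d gene record(s) (%d coding, %d pseudo, %d noncoding)\n",
              x$assembly_id, length(x$contigs), nrow(x$features),
              sum(x$features$kind == "coding"), sum(x$features$kind == "pseudogene"),
              sum(x$features$kind == "noncoding")))
  if (length(x$warnings)) cat(sprintf("  %d warning(s) recorded\n", length(x$warnings)))
  invisible(x)
}

NONCODING_TYPES <- c("tRNA", "rRNA", "ncRNA", "tmRNA", "misc_RNA", "SRP_RNA",
                     "RNase_P_RNA", "antisense_RNA", "snRNA", "snoRNA",
                     "miRNA", "hammerhead_ribozyme")

parse_gff3 <- function(src) {
  lines <- read_text_lines(src)
  contigs <- numeric(0)
  n <- length(lines)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) {
      if (startsWith(ln, "##sequence-region")) {
        p <- strsplit(trimws(ln), "\\s+")[[1L]]
        if (length(p) >= 4L) contigs[p[2L]] <- suppressWarnings(as.numeric(p[4L]))
      }
      if (startsWith(ln, "##FASTA")) break
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)), call. = FALSE)
    st <- suppressWarnings(as.integer(f[4L])); en <- suppressWarnings(as.integer(f[5L]))
    if (is.na(st) || is.na(en) || st < 1L || en < st)
      stop(sprintf("GFF3 parse error at line %d: bad coordinates '%s'..'%s'",
                   i, f[4L], f[5L]), call. = FALSE)
    if (!f[7L] %in% c("+", "-", ".", "?"))
      stop(sprintf("GFF3 parse error at line %d: bad strand '%s'", i, f[7L]), call. = FALSE)
    rows[[i]] <- list(contig = f[1L], type = f[3L], start = st, end = en,
                      strand = f[7L], attrs = parse_gff_attrs(f[9L]))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]

  # index gene-level rows for pseudogene biotype and locus_tag lookup
  gene_info <- list()
  for (r in rows) {
    if (r$type %in% c("gene", "pseudogene")) {
      id <- r$attrs[["ID"]]
      if (!is.null(id)) gene_info[[id]] <- r
    }
  }
  gene_is_pseudo <- function(id) {
    g <- gene_info[[id %||% ""]]
    if (is.null(g)) return(FALSE)
    isTRUE(tolower(g$attrs[["pseudo"]] %||% "") == "true") ||
      identical(g$attrs[["gene_biotype"]], "pseudogene") ||
      g$type == "pseudogene"
  }
  gene_locus <- function(id) {
    g <- gene_info[[id %||% ""]]
    if (is.null(g)) NA_character_ else (g$attrs[["locus_tag"]] %||% NA_character_)
  }

  recs <- list()       # keyed records for CDS merging
  parent_used <- character(0)

  for (r in rows) {
    if (r$type == "CDS") {
      parent <- r$attrs[["Parent"]]
      if (!is.null(parent)) parent_used <- c(parent_used, parent)
      pid <- r$attrs[["protein_id"]]
      pseudo <- isTRUE(tolower(r$attrs[["pseudo"]] %||% "") == "true") ||
        gene_is_pseudo(parent)
      key <- paste(r$contig,
                   if (!is.null(pid)) paste0("p:", pid)
                   else paste0("g:", parent %||% r$attrs[["ID"]] %||% sprintf("anon%d:%d", r$start, r$end)))
      prev <- recs[[key]]
      if (is.null(prev)) {
        recs[[key]] <- list(
          contig_id = r$contig, start = r$start, end = r$end, strand = r$strand,
          kind = if (pseudo) "pseudogene" else "coding",
          protein_id = if (pseudo) NA_character_ else (pid %||% NA_character_),
          locus_tag = r$attrs[["locus_tag"]] %||% gene_locus(parent),
          product = r$attrs[["product"]] %||% "")
      } else {  # multi-segment CDS: merge span
        prev$start <- min(prev$start, r$start)
        prev$end <- max(prev$end, r$end)
        recs[[key]] <- prev
      }
    } else if (r$type %in% NONCODING_TYPES) {
      parent <- r$attrs[["Parent"]]
      if (!is.null(parent)) parent_used <- c(parent_used, parent)
      key <- paste(r$contig, "n:", r$attrs[["ID"]] %||% sprintf("rna%d:%d", r$start, r$end))
      recs[[key]] <- list(
        contig_id = r$contig, start = r$start, end = r$end, strand = r$strand,
        kind = "noncoding", protein_id = NA_character_,
        locus_tag = r$attrs[["locus_tag"]] %||% gene_locus(parent),
        product = r$attrs[["product"]] %||% "")
    }
  }

  # standalone pseudogene rows without any CDS/RNA child
  for (r in rows) {
    if ((r$type == "pseudogene" ||
         (r$type == "gene" && gene_is_pseudo(r$attrs[["ID"]] %||% ""))) &&
        !((r$attrs[["ID"]] %||% "") %in% parent_used)) {
      key <- paste(r$contig, "ps:", r$attrs[["ID"]] %||% sprintf("ps%d:%d", r$start, r$end))
      recs[[key]] <- list(
        contig_id = r$contig, start = r$start, end = r$end, strand = r$strand,
        kind = "pseudogene", protein_id = NA_character_,
        locus_tag = r$attrs[["locus_tag"]] %||% NA_character_,
        product = r$attrs[["product"]] %||% "")
    }
  }

  feats <- if (length(recs)) {
    do.call(rbind, lapply(recs, function(x)
      data.frame(contig_id = x$contig_id, start = x$start, end = x$end,
                 strand = x$strand, kind = x$kind, protein_id = x$protein_id,
                 locus_tag = x$locus_tag %||% NA_character_, product = x$product,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(contig_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), kind = character(0),
               protein_id = character(0), locus_tag = character(0),
               product = character(0), stringsAsFactors = FALSE)
  }
  rownames(feats) <- NULL
  list(contigs = contigs, features = feats)
}

parse_gff_attrs <- function(s) {
  if (is.na(s) || s == "" || s == ".") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) >= 2L)
      out[[trimws(p[1L])]] <- utils::URLdecode(paste(p[-1L], collapse = "="))
  }
  out
}

read_protein_fasta <- function(src) {
  lines <- read_text_lines(src)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) {
    if (all(!nzchar(lines))) return(setNames(character(0), character(0)))
    stop("protein FASTA input contains no '>' headers", call. = FALSE)
  }
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  seqs <- toupper(gsub("\\s", "", seqs))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA record id: %s", ids[duplicated(ids)][1L]), call. = FALSE)
  setNames(as.character(seqs), ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a query protein in one or more assemblies
#'
#' Finds the gene record encoding a query protein. When the query carries an
#' assembly identifier only that assembly is searched; otherwise all loaded
#' assemblies are searched and the match must be unique.
#'
#' @param provider A single `assembly` or a list of them.
#' @param protein_id Query protein accession.
#' @param assembly_id Optional assembly identifier restricting the search.
#' @return A list with elements `assembly` and `record` (a one-row
#'   data.frame from `assembly$features`), or `NULL` when the accession is
#'   not found (callers record a per-query "missing" outcome and continue).
#'   An accession present in several assemblies without a disambiguating
#'   `assembly_id` is an error naming the candidate assemblies.
#' @export
locate_query <- function(provider, protein_id, assembly_id = NA) {
  assemblies <- if (inherits(provider, "assembly")) list(provider) else provider
  stopifnot(length(assemblies) >= 1L,
            all(vapply(assemblies, inherits, TRUE, "assembly")))
  ids <- vapply(assemblies, function(a) a$assembly_id, "")
  if (!is.na(assembly_id) && !is.null(assembly_id)) {
    if (!assembly_id %in% ids) return(NULL)
    assemblies <- assemblies[ids == assembly_id]
    ids <- assembly_id
  }
  hits <- lapply(assemblies, function(a) {
    w <- which(!is.na(a$features$protein_id) & a$features$protein_id == protein_id)
    if (length(w)) a$features[w[1L], , drop = FALSE] else NULL
  })
  found <- !vapply(hits, is.null, TRUE)
  if (!any(found)) return(NULL)
  if (sum(found) > 1L)
    stop(sprintf("query %s is ambiguous: found in assemblies %s; add an assembly identifier to the query line",
                 protein_id, paste(ids[found], collapse = ", ")), call. = FALSE)
  i <- which(found)
  list(assembly = assemblies[[i]], record = hits[[i]])
}
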