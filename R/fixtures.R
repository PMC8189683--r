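AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# run code under a private RNG state so generation is deterministic without
# disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# substitution-only point mutation to an exact target identity fraction
mutate_to_identity <- function(seq, identity) {
  stopifnot(identity >= 0.3, identity <= 1)
  ch <- strsplit(seq, "")[[1L]]
  n_mut <- round((1 - identity) * length(ch))
  if (n_mut > 0L) {
    pos <- sample(length(ch), n_mut)
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Specification for a synthetic fixture
#'
#' Describes a set of synthetic assemblies with planted homologous families
#' around a planted query gene, plus pseudogenes, non-coding genes and
#' optional contig-edge queries. The same spec and seed always generate
#' identical files.
#'
#' Each assembly's first contig carries one query gene (all queries across
#' assemblies form one planted family) surrounded by one member of each
#' planted family at a fixed relative slot; remaining slots and further
#' contigs are filled with unrelated background genes, a fraction of which
#' are pseudogenes or non-coding genes.
#'
#' @param n_assemblies Number of assemblies (>= 1).
#' @param contigs_per_assembly Contigs per assembly.
#' @param genes_per_contig Genes per contig.
#' @param n_families Planted flanking-gene families (each with
#'   `members_per_assembly` copies per assembly).
#' @param members_per_assembly Copies of each family per assembly.
#' @param identity Fraction identity (0.6-1.0 realistic) of family members
#'   to their family ancestor.
#' @param pseudogene_rate,noncoding_rate Probability that a background gene
#'   is a pseudogene / non-coding gene.
#' @param edge_query If TRUE the query is the 2nd gene from the contig
#'   start, so extraction with `n >= 2` is truncated on one side.
#' @param query_strand `"+"`, `"-"` or `"random"`.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_assemblies = 6L, contigs_per_assembly = 2L,
                         genes_per_contig = 9L, n_families = 4L,
                         members_per_assembly = 1L, identity = 0.8,
                         pseudogene_rate = 0.1, noncoding_rate = 0.1,
                         edge_query = FALSE, query_strand = "+", seed = 1L) {
  stopifnot(n_assemblies >= 1, contigs_per_assembly >= 1, genes_per_contig >= 1,
            n_families >= 0, members_per_assembly >= 1,
            identity >= 0.3, identity <= 1,
            pseudogene_rate >= 0, pseudogene_rate <= 1,
            noncoding_rate >= 0, noncoding_rate <= 1,
            pseudogene_rate + noncoding_rate <= 1,
            query_strand %in% c("+", "-", "random"))
  if (genes_per_contig < n_families * members_per_assembly + 1L)
    stop(sprintf("infeasible packing: %d genes per contig cannot hold 1 query + %d family member(s)",
                 genes_per_contig, n_families * members_per_assembly), call. = FALSE)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' Produces GFF3 + protein FASTA text per assembly, a query list, and a
#' ground-truth table recording every gene's coordinates, kind, and planted
#' family (`QUERY`, `F1`..`Fk`, or `NA` for unrelated background genes).
#' The expected conservation partition is: one group per planted family
#' (including the query family), every background protein a singleton.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `<id>.gff`, `<id>.faa`,
#'   `queries.txt` and `truth.tsv` there.
#' @return A `fixture` list: `assemblies` (per assembly: `assembly_id`,
#'   `gff` and `faa` line vectors), `truth` (data.frame), `query_text`,
#'   `spec`, and `files` (paths, when `dir` was given).
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    # family ancestors (index 0 = query family)
    anc_len <- sample(90:150, spec$n_families + 1L, replace = TRUE)
    ancestors <- vapply(anc_len, random_protein, "")

    truth <- list(); assemblies <- list(); query_lines <- character(0)
    for (ai in seq_len(spec$n_assemblies)) {
      aid <- sprintf("GCF_%06d.1", ai)
      gff <- c("##gff-version 3")
      faa <- character(0)
      counter <- 0L

      for (ci in seq_len(spec$contigs_per_assembly)) {
        cid <- sprintf("NZ_CTG%d_%d", ai, ci)
        ng <- spec$genes_per_contig

        # per-gene plan: family id (0 = query, >0 planted, NA background)
        fam <- rep(NA_integer_, ng)
        if (ci == 1L) {
          q_idx <- if (spec$edge_query) min(2L, ng) else (ng + 1L) %/% 2L
          fam[q_idx] <- 0L
          # alternating offsets nearest-first: -1,+1,-2,+2,...
          offs <- as.vector(rbind(-seq_len(ng), seq_len(ng)))
          offs <- offs[q_idx + offs >= 1L & q_idx + offs <= ng]
          need <- rep(seq_len(spec$n_families), each = spec$members_per_assembly)
          if (length(need) > length(offs))
            stop("infeasible packing: not enough slots around the query", call. = FALSE)
          fam[q_idx + offs[seq_along(need)]] <- need
        }

        pos <- 101L
        rows <- list()
        for (gi in seq_len(ng)) {
          counter <- counter + 1L
          planted <- !is.na(fam[gi])
          kind <- if (planted) "coding" else
            sample(c("coding", "pseudogene", "noncoding"), 1L,
                   prob = c(1 - spec$pseudogene_rate - spec$noncoding_rate,
                            spec$pseudogene_rate, spec$noncoding_rate))
          seq <- NULL
          if (kind == "coding") {
            seq <- if (planted) {
              if (fam[gi] == 0L && spec$identity == 1) ancestors[1L]
              else mutate_to_identity(ancestors[fam[gi] + 1L], spec$identity)
            } else random_protein(sample(80:140, 1L))
            len_nt <- 3L * nchar(seq) + 3L
          } else {
            len_nt <- sample(seq(240L, 600L, by = 3L), 1L)
          }
          strand <- if (planted && fam[gi] == 0L) {
            if (spec$query_strand == "random") sample(c("+", "-"), 1L) else spec$query_strand
          } else sample(c("+", "-"), 1L)
          start <- pos; end <- pos + len_nt - 1L
          pos <- end + 1L + sample(20:150, 1L)
          pid <- if (kind == "coding") sprintf("WP_%03d%05d.1", ai, counter) else NA_character_
          locus <- sprintf("TST%d_%05d", ai, counter)
          product <- if (planted && fam[gi] == 0L) "planted query protein"
            else if (planted) sprintf("planted family %d protein", fam[gi])
            else switch(kind, coding = "hypothetical protein",
                        pseudogene = "degraded pseudogene", noncoding = "small RNA")
          rows[[gi]] <- data.frame(
            assembly_id = aid, contig_id = cid, gene_index = gi,
            start = start, end = end, strand = strand, kind = kind,
            protein_id = pid, locus_tag = locus, product = product,
            family = if (!planted) NA_character_
                     else if (fam[gi] == 0L) "QUERY" else sprintf("F%d", fam[gi]),
            is_query = planted && fam[gi] == 0L,
            stringsAsFactors = FALSE)
          if (kind == "coding") faa <- c(faa, paste0(">", pid, " ", product), seq)
        }
        ctg_rows <- do.call(rbind, rows)
        ctg_len <- max(ctg_rows$end) + 200L
        gff <- c(gff, sprintf("##sequence-region %s 1 %d", cid, ctg_len))
        for (k in seq_len(nrow(ctg_rows))) {
          r <- ctg_rows[k, ]
          gid <- sprintf("gene-%s", r$locus_tag)
          common <- sprintf("%s\tsynth\t%%s\t%d\t%d\t.\t%s\t%%s\t%%s", cid,
                            r$start, r$end, r$strand)
          if (r$kind == "coding") {
            gff <- c(gff,
              sprintf(common, "gene", ".", sprintf("ID=%s;locus_tag=%s;gene_biotype=protein_coding", gid, r$locus_tag)),
              sprintf(common, "CDS", "0", sprintf("ID=cds-%s;Parent=%s;protein_id=%s;product=%s;locus_tag=%s",
                                                  r$locus_tag, gid, r$protein_id, r$product, r$locus_tag)))
          } else if (r$kind == "pseudogene") {
            gff <- c(gff,
              sprintf(common, "gene", ".", sprintf("ID=%s;locus_tag=%s;gene_biotype=pseudogene;pseudo=true", gid, r$locus_tag)),
              sprintf(common, "CDS", "0", sprintf("ID=cds-%s;Parent=%s;pseudo=true;product=%s;locus_tag=%s",
                                                  r$locus_tag, gid, r$product, r$locus_tag)))
          } else {
            gff <- c(gff,
              sprintf(common, "gene", ".", sprintf("ID=%s;locus_tag=%s;gene_biotype=ncRNA", gid, r$locus_tag)),
              sprintf(common, "ncRNA", ".", sprintf("ID=rna-%s;Parent=%s;product=%s;locus_tag=%s",
                                                    r$locus_tag, gid, r$product, r$locus_tag)))
          }
        }
        truth[[length(truth) + 1L]] <- ctg_rows
      }
      assemblies[[ai]] <- list(assembly_id = aid, gff = gff, faa = faa)
      tr_a <- do.call(rbind, truth[(length(truth) - spec$contigs_per_assembly + 1L):length(truth)])
      qpid <- tr_a$protein_id[tr_a$is_query][1L]
      query_lines <- c(query_lines, paste(qpid, aid, sep = "\t"))
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(gff = character(0), faa = character(0))
      for (a in assemblies) {
        gf <- file.path(dir, paste0(a$assembly_id, ".gff"))
        ff <- file.path(dir, paste0(a$assembly_id, ".faa"))
        writeLines(a$gff, gf); writeLines(a$faa, ff)
        files$gff <- c(files$gff, gf); files$faa <- c(files$faa, ff)
      }
      files$queries <- file.path(dir, "queries.txt")
      writeLines(query_lines, files$queries)
      files$truth <- file.path(dir, "truth.tsv")
      write.table(truth, files$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    }

    structure(list(assemblies = assemblies, truth = truth,
                   query_text = paste(query_lines, collapse = "\n"),
                   spec = spec, files = files),
              class = "fixture")
  })
}

#' Expected conservation partition of a fixture
#'
#' Maps every coding protein of the truth table to its planted family
#' (query family included); background proteins are singletons. This is the
#' partition the clustering stage is expected to recover when family
#' identity is high enough for every pair to score significantly.
#'
#' @param fixture A `fixture` from [generate_fixture()].
#' @return Named character vector: `protein_id` -> partition label.
#' @export
truth_partition <- function(fixture) {
  tr <- fixture$truth[fixture$truth$kind == "coding", , drop = FALSE]
  lab <- ifelse(is.na(tr$family), paste0("bg:", tr$protein_id), tr$family)
  setNames(lab, tr$protein_id)
}
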