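# Tiny hand-built GFF3/FASTA inputs and convenience builders used across
# the suite. Everything is constructed in code; nothing is read from disk.

gff_header <- function(contig = "c1", len = 100000L) {
  c("##gff-version 3", sprintf("##sequence-region %s 1 %d", contig, len))
}

# one gene+CDS pair of GFF lines
gff_cds <- function(contig, start, end, strand, pid, locus = NULL,
                    product = "hypothetical protein", pseudo = FALSE,
                    parent_biotype = NULL) {
  locus <- locus %||% paste0("L", start)
  gid <- paste0("gene-", locus)
  bio <- parent_biotype %||% (if (pseudo) "pseudogene" else "protein_coding")
  gene_attrs <- sprintf("ID=%s;locus_tag=%s;gene_biotype=%s%s", gid, locus, bio,
                        if (pseudo) ";pseudo=true" else "")
  cds_attrs <- if (pseudo)
    sprintf("ID=cds-%s;Parent=%s;pseudo=true;product=%s", locus, gid, product)
  else
    sprintf("ID=cds-%s;Parent=%s;protein_id=%s;product=%s", locus, gid, pid, product)
  c(sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\t%s", contig, start, end, strand, gene_attrs),
    sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\t%s", contig, start, end, strand, cds_attrs))
}

gff_rna <- function(contig, start, end, strand, locus, type = "tRNA",
                    product = "tRNA-Xxx") {
  gid <- paste0("gene-", locus)
  c(sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s;gene_biotype=%s",
            contig, start, end, strand, gid, locus, type),
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=rna-%s;Parent=%s;product=%s",
            contig, type, start, end, strand, locus, gid, product))
}

fasta_of <- function(seqs) as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))

random_aa <- function(n, seed = NULL) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# a simple 7-gene one-contig assembly: g1..g7, 300 bp each, 100 bp gaps
seven_gene_assembly <- function(strands = rep("+", 7), id = "GCF_TEST.1") {
  starts <- 101 + (0:6) * 400
  gff <- gff_header("c1", 5000L)
  seqs <- character(0)
  withr::with_seed(99, {
    for (i in 1:7) {
      pid <- sprintf("WP_G%d.1", i)
      gff <- c(gff, gff_cds("c1", starts[i], starts[i] + 299, strands[i], pid,
                            locus = sprintf("g%d", i)))
      seqs[pid] <- random_aa(99)
    }
  })
  load_assembly(gff, fasta_of(seqs), id)
}

# load every assembly of a generated fixture
load_fixture_assemblies <- function(fx) {
  lapply(fx$assemblies, function(a) load_assembly(a$gff, a$faa, a$assembly_id))
}

# run the clustering stages of the pipeline on a generated fixture and
# return the assignment plus supporting objects
cluster_fixture <- function(fx, n_flank, cutoff = 1e-6) {
  asms <- load_fixture_assemblies(fx)
  q <- parse_query_list(fx$query_text)
  nbs <- lapply(seq_len(nrow(q)), function(i) {
    loc <- locate_query(asms, q$protein_id[i], q$assembly_id[i])
    extract_neighbourhood(loc$assembly, loc$record, n_flank)
  })
  graph <- build_hit_graph(nbs, search_params(cutoff))
  comps <- cluster_components(graph)
  list(nbs = nbs, graph = graph, components = comps,
       assignment = assign_groups(comps, graph))
}

# canonical form of a partition (set of sorted member groups) for equality
# comparisons independent of label values
canonical_partition <- function(labels) {
  unname(sort(vapply(split(names(labels), unname(labels)),
                     function(m) paste(sort(m), collapse = "|"), "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
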