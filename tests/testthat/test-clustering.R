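# one-contig assembly whose genes are exactly `seqs` (named protein_id ->
# sequence), in order; query is the gene named in `query`
linear_assembly <- function(seqs, id) {
  starts <- 101 + (seq_along(seqs) - 1) * 500
  gff <- gff_header("c1", max(starts) + 1000)
  for (i in seq_along(seqs))
    gff <- c(gff, gff_cds("c1", starts[i], starts[i] + 3 * nchar(seqs[i]),
                          "+", names(seqs)[i], locus = paste0(id, "g", i)))
  load_assembly(gff, fasta_of(seqs), id)
}

nb_of <- function(asm, query, n = 4) extract_neighbourhood(asm, query, n)

test_that("two identical proteins in different neighbourhoods give one edge", {
  withr::with_seed(10, {
    shared <- random_aa(90)
    qa <- random_aa(50); qb <- random_aa(50)
  })
  a <- linear_assembly(c(QA = qa, XA = shared), "A")
  b <- linear_assembly(c(QB = qb, XB = shared), "B")
  g <- build_hit_graph(list(nb_of(a, "QA"), nb_of(b, "QB")),
                       search_params(1e-3, iterations = 1))
  expect_equal(nrow(g$edges), 1L)
  linked <- g$nodes$protein_id[match(c(g$edges$node_a, g$edges$node_b), g$nodes$node)]
  expect_setequal(linked, c("XA", "XB"))
})

test_that("shuffled unrelated proteins produce no edges at 1e-6 (20 seeded shuffles)", {
  base <- withr::with_seed(11, random_aa(120))
  ch <- strsplit(base, "")[[1]]
  for (seed in 1:20) {
    withr::with_seed(seed, {
      s1 <- paste(sample(ch), collapse = "")
      s2 <- paste(sample(ch), collapse = "")
    })
    a <- linear_assembly(c(Q1 = s1), "A")
    b <- linear_assembly(c(Q2 = s2), "B")
    g <- build_hit_graph(list(nb_of(a, "Q1"), nb_of(b, "Q2")),
                         search_params(1e-6, iterations = 1))
    expect_equal(nrow(g$edges), 0L)
  }
})

test_that("tightening the cutoff never adds edges", {
  fx <- generate_fixture(fixture_spec(n_assemblies = 4, n_families = 3,
                                      identity = 0.7, seed = 21))
  run <- cluster_fixture(fx, n_flank = 3, cutoff = 1e-3)
  key <- function(g) paste(g$edges$node_a, g$edges$node_b)
  loose <- key(run$graph)
  tight <- key(build_hit_graph(run$nbs, search_params(1e-10)))
  expect_true(all(tight %in% loose))
})

test_that("edges respect the cutoff and carry symmetric significance", {
  fx <- generate_fixture(fixture_spec(n_assemblies = 3, n_families = 2, seed = 22))
  run <- cluster_fixture(fx, n_flank = 2, cutoff = 1e-6)
  expect_true(all(run$graph$edges$evalue <= 1e-6))
  expect_false(any(run$graph$edges$node_a == run$graph$edges$node_b))
})

test_that("the builtin backend records a warning when iterations > 1", {
  a <- linear_assembly(c(Q1 = withr::with_seed(1, random_aa(60))), "A")
  g <- build_hit_graph(list(nb_of(a, "Q1")), search_params(1e-3, iterations = 3))
  expect_match(g$warnings, "iterations", all = FALSE)
  g1 <- build_hit_graph(list(nb_of(a, "Q1")), search_params(1e-3, iterations = 1))
  expect_length(g1$warnings, 0L)
})

test_that("connected components follow transitive linkage with singletons", {
  mk_graph <- function(nodes, edges) {
    structure(list(
      nodes = data.frame(node = nodes, nb = seq_along(nodes), slot = 0L,
                         protein_id = nodes, seq_id = nodes,
                         stringsAsFactors = FALSE),
      edges = if (length(edges)) {
        data.frame(node_a = vapply(edges, `[`, "", 1),
                   node_b = vapply(edges, `[`, "", 2),
                   evalue = 1e-10, bitscore = 50, stringsAsFactors = FALSE)
      } else data.frame(node_a = character(0), node_b = character(0),
                        evalue = numeric(0), bitscore = numeric(0))),
      class = "hit_graph")
  }
  comp <- cluster_components(mk_graph(c("a", "b", "c", "d"),
                                      list(c("a", "b"), c("b", "c"))))
  expect_equal(canonical_partition(comp), c("a|b|c", "d"))
  comp0 <- cluster_components(mk_graph(c("a", "b", "c"), list()))
  expect_equal(canonical_partition(comp0), c("a", "b", "c"))

  # oracle equivalence on random graphs
  for (seed in 1:30) {
    withr::with_seed(seed, {
      nn <- sample(2:40, 1)
      nodes <- sprintf("n%d", seq_len(nn))
      ne <- sample(0:(2 * nn), 1)
      ea <- sample(nodes, ne, replace = TRUE)
      eb <- sample(nodes, ne, replace = TRUE)
    })
    keep <- ea != eb
    g <- mk_graph(nodes, Map(c, ea[keep], eb[keep]))
    got <- canonical_partition(cluster_components(g))
    want <- canonical_partition(union_find_oracle(nodes, ea[keep], eb[keep]))
    expect_equal(got, want)
  }
})

test_that("the external profile backend links identical proteins like the builtin", {
  skip_if(Sys.which("jackhmmer") == "", "jackhmmer not installed")
  withr::with_seed(12, {
    shared <- random_aa(90)
    qa <- random_aa(50); qb <- random_aa(50)
  })
  a <- linear_assembly(c(QA = qa, XA = shared), "A")
  b <- linear_assembly(c(QB = qb, XB = shared), "B")
  g <- build_hit_graph(list(nb_of(a, "QA"), nb_of(b, "QB")),
                       search_params(1e-3, iterations = 2,
                                     backend = "external_profile"))
  linked <- g$nodes$protein_id[match(c(g$edges$node_a, g$edges$node_b), g$nodes$node)]
  expect_true(all(c("XA", "XB") %in% linked))
})

test_that("a missing external tool is a clean error pointing at the builtin", {
  a <- linear_assembly(c(Q1 = withr::with_seed(1, random_aa(60))), "A")
  withr::local_envvar(PATH = tempdir())
  expect_error(build_hit_graph(list(nb_of(a, "Q1")),
                               search_params(1e-3, backend = "external_profile")),
               "builtin")
})
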