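# helper: assignment computed on a generated fixture
fixture_assignment <- function(seed = 31, n_assemblies = 6, n_families = 3,
                               n_flank = 3, ...) {
  fx <- generate_fixture(fixture_spec(n_assemblies = n_assemblies,
                                      n_families = n_families, seed = seed, ...))
  c(cluster_fixture(fx, n_flank = n_flank), list(fx = fx))
}

test_that("wider-spread families get smaller group numbers", {
  # family present in 5 of 6 neighbourhoods vs one in 3: build directly
  withr::with_seed(40, {
    f5 <- random_aa(90); f3 <- random_aa(90); qs <- replicate(6, random_aa(70))
  })
  nbs <- lapply(1:6, function(i) {
    seqs <- c(setNames(qs[i], sprintf("Q%d", i)))
    if (i <= 5) seqs <- c(seqs, setNames(f5, sprintf("A%d", i)))
    if (i <= 3) seqs <- c(seqs, setNames(f3, sprintf("B%d", i)))
    asm <- local({
      starts <- 101 + (seq_along(seqs) - 1) * 500
      gff <- gff_header("c1", 5000L)
      for (k in seq_along(seqs))
        gff <- c(gff, gff_cds("c1", starts[k], starts[k] + 200, "+",
                              names(seqs)[k], locus = sprintf("i%dg%d", i, k)))
      load_assembly(gff, fasta_of(seqs), sprintf("GCF_%d", i))
    })
    extract_neighbourhood(asm, sprintf("Q%d", i), 4)
  })
  g <- build_hit_graph(nbs, search_params(1e-6, iterations = 1))
  asg <- assign_groups(cluster_components(g), g)
  gid_of <- function(pid) {
    n <- asg$nodes
    unique(n$group_id[n$protein_id == pid])
  }
  expect_lt(gid_of("A1"), gid_of("B1"))
  # queries are unrelated random proteins: each its own non-conserved
  # component, but each still carries the reserved query numbering
  expect_true(all(asg$groups$neighbourhood_count[!asg$groups$is_query_family] >= 2))
})

test_that("a protein repeated inside one neighbourhood only is not conserved", {
  withr::with_seed(41, {
    dup <- random_aa(80)
    q <- random_aa(60)
  })
  seqs <- c(Q = q, D1 = dup, D2 = dup)
  starts <- c(101, 601, 1101)
  gff <- gff_header("c1", 3000L)
  for (k in seq_along(seqs))
    gff <- c(gff, gff_cds("c1", starts[k], starts[k] + 200, "+",
                          names(seqs)[k], locus = paste0("g", k)))
  asm <- load_assembly(gff, fasta_of(seqs), "GCF_1")
  nb <- extract_neighbourhood(asm, "Q", 2)
  g <- build_hit_graph(list(nb), search_params(1e-3, iterations = 1))
  asg <- assign_groups(cluster_components(g), g)
  dnodes <- asg$nodes[asg$nodes$protein_id %in% c("D1", "D2"), ]
  expect_true(all(!dnodes$conserved))
  expect_true(all(is.na(dnodes$group_id)))
})

test_that("group numbering is invariant to edge insertion order", {
  run <- fixture_assignment(seed = 42, n_assemblies = 5, n_families = 4,
                            n_flank = 3)
  ref <- run$assignment$nodes
  for (seed in 1:10) {
    g2 <- run$graph
    perm <- withr::with_seed(seed, sample(nrow(g2$edges)))
    g2$edges <- g2$edges[perm, , drop = FALSE]
    asg2 <- assign_groups(cluster_components(g2), g2)
    n2 <- asg2$nodes[match(ref$node, asg2$nodes$node), ]
    expect_equal(n2$group_id, ref$group_id)
    expect_equal(n2$conserved, ref$conserved)
  }
})

test_that("every coding gene is numbered+conserved or unnumbered; others never numbered", {
  run <- fixture_assignment(seed = 43, pseudogene_rate = 0.25,
                            noncoding_rate = 0.2, genes_per_contig = 11)
  nodes <- run$assignment$nodes
  # graph nodes are coding only
  kinds <- unlist(lapply(seq_along(run$nbs), function(i) {
    g <- run$nbs[[i]]$genes
    g$kind[match(nodes$slot[nodes$nb == i], g$slot)]
  }))
  expect_true(all(kinds == "coding"))
  # dichotomy: conserved <=> numbered, except the reserved query family
  plain <- nodes[!nodes$is_query_family, ]
  expect_equal(!is.na(plain$group_id), plain$conserved)
  # group ids are consecutive 1..G
  expect_equal(sort(run$assignment$groups$group_id),
               seq_len(nrow(run$assignment$groups)))
})

test_that("palettes are deterministic, injective and avoid reserved styles", {
  run <- fixture_assignment(seed = 44, n_assemblies = 6, n_families = 6,
                            n_flank = 4, genes_per_contig = 9)
  asg <- run$assignment
  p1 <- assign_colours(asg, seed = 5)
  p2 <- assign_colours(asg, seed = 5)
  expect_identical(p1, p2)
  expect_equal(length(unique(p1)), length(p1))
  reserved <- setdiff(unname(genecontext:::reserved_styles()),
                      genecontext:::STYLE_QUERY)
  expect_false(any(p1 %in% reserved))
  # different seed: same ids, possibly different hues
  p3 <- assign_colours(asg, seed = 6)
  expect_equal(names(p3), names(p1))
})

test_that("hue spacing stays at least 360/(G+1) degrees", {
  for (G in c(2, 5, 12, 24)) {
    asg <- structure(list(
      nodes = data.frame(),
      groups = data.frame(group_id = seq_len(G + 1),
                          component = seq_len(G + 1),
                          member_count = 2, neighbourhood_count = 2,
                          is_query_family = c(TRUE, rep(FALSE, G)))),
      class = "group_assignment")
    pal <- assign_colours(asg, seed = 3)
    hues <- grDevices::rgb2hsv(grDevices::col2rgb(pal[-1]))["h", ] * 360
    hs <- sort(hues)
    gaps <- c(diff(hs), 360 - (max(hs) - min(hs)))
    # 0.5 degree slack: hues survive an 8-bit hex round trip in this check
    expect_gte(min(gaps), 360 / (G + 1) - 0.5)
  }
})
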