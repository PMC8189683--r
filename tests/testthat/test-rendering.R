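# a small two-assembly fixture run rendered end-to-end, shared across tests
render_case <- function(seed = 51, n_assemblies = 3, n_families = 2, ...) {
  fx <- generate_fixture(fixture_spec(n_assemblies = n_assemblies,
                                      n_families = n_families,
                                      seed = seed, ...))
  run <- cluster_fixture(fx, n_flank = 3)
  pal <- assign_colours(run$assignment, seed = 1)
  model <- build_render_model(run$nbs, run$assignment, pal, bp_per_px = 20)
  c(run, list(palette = pal, model = model, fx = fx))
}

test_that("glyph widths are proportional to gene lengths within a pixel", {
  # two genes of 300 and 600 bp
  seqs <- withr::with_seed(50, c(Q = random_aa(99), L = random_aa(199)))
  gff <- c(gff_header("c1", 3000L),
           gff_cds("c1", 101, 400, "+", "Q", locus = "q"),     # 300 bp
           gff_cds("c1", 501, 1100, "+", "L", locus = "l"))    # 600 bp
  asm <- load_assembly(gff, fasta_of(seqs), "GCF_1")
  nb <- extract_neighbourhood(asm, "Q", 2)
  g <- build_hit_graph(list(nb), search_params(1e-3, iterations = 1))
  asg <- assign_groups(cluster_components(g), g)
  row <- layout_row(nb, 1, asg, assign_colours(asg), bp_per_px = 10)
  w <- setNames(row$width, row$protein_id)
  expect_lt(abs(w[["L"]] / w[["Q"]] - 600 / 300), 1 / min(w))
  # intergenic gap also to scale: gap 100 bp at 10 bp/px = 10 px
  expect_equal(row$x[2] - (row$x[1] + row$width[1]), 100 / 10)
})

test_that("style tokens encode conservation class", {
  rc <- render_case(seed = 52, pseudogene_rate = 0.35, noncoding_rate = 0.2,
                    genes_per_contig = 11)
  rows <- do.call(rbind, rc$model$rows)
  expect_true(any(rows$kind == "pseudogene"))
  ps <- rows[rows$kind == "pseudogene", ]
  expect_true(all(ps$fill == genecontext:::STYLE_PSEUDO_FILL))
  expect_true(all(ps$stroke == genecontext:::STYLE_PSEUDO_STROKE))
  nc <- rows[rows$kind == "coding" & is.na(rows$group_id), ]
  expect_true(all(nc$fill == "none"))
  expect_true(all(nc$stroke == genecontext:::STYLE_NONCONSERVED_STROKE))
  rna <- rows[rows$kind == "noncoding", ]
  if (nrow(rna)) expect_true(all(rna$fill == "url(#hatch)"))
  # conserved genes carry their palette colour and a printed number
  conserved <- rows[!is.na(rows$group_id), ]
  expect_true(all(conserved$label == as.character(conserved$group_id)))
  expect_true(all(conserved$fill == rc$palette[as.character(conserved$group_id)]))
})

test_that("queries align in one vertical column and rows stay to scale", {
  rc <- render_case(seed = 53)
  qx <- vapply(rc$model$rows, function(r) r$x[r$slot == 0], 0)
  expect_true(all(abs(qx - qx[1]) < 1e-9))
  # scale invariance: doubling bp/px halves widths
  m2 <- build_render_model(rc$nbs, rc$assignment, rc$palette, bp_per_px = 40)
  for (i in seq_along(rc$model$rows))
    expect_equal(m2$rows[[i]]$width, rc$model$rows[[i]]$width / 2)
})

test_that("truncated sides render no placeholder glyphs", {
  fx <- generate_fixture(fixture_spec(n_assemblies = 2, n_families = 1,
                                      edge_query = TRUE, seed = 54))
  run <- cluster_fixture(fx, n_flank = 4)
  expect_true(any(vapply(run$nbs, function(nb) nb$truncated_left ||
                           nb$truncated_right, TRUE)))
  pal <- assign_colours(run$assignment)
  model <- build_render_model(run$nbs, run$assignment, pal)
  for (i in seq_along(run$nbs)) {
    # one glyph per real gene, nothing more
    expect_equal(nrow(model$rows[[i]]), nrow(run$nbs[[i]]$genes))
    svg <- render_diagram_svg(model)
    expect_equal(length(gregexpr("<polygon", svg, fixed = TRUE)[[1]]),
                 sum(vapply(model$rows, nrow, 0L)))
  }
})

test_that("the description table has one row per slot plus truncation notes", {
  rc <- render_case(seed = 55)
  tsv <- write_description(rc$model)
  expect_match(tsv[1], "^#query_id\t")
  data_rows <- tsv[!startsWith(tsv, "#")]
  expect_equal(length(data_rows), sum(vapply(rc$model$rows, nrow, 0L)))
  # lone-gene neighbourhood: exactly 1 data row and a truncation note
  seqs <- c(Q = withr::with_seed(56, random_aa(80)))
  gff <- c(gff_header("c1", 1000L), gff_cds("c1", 101, 343, "+", "Q", locus = "q"))
  asm <- load_assembly(gff, fasta_of(seqs), "GCF_1")
  nb <- extract_neighbourhood(asm, "Q", 2)
  g <- build_hit_graph(list(nb), search_params(1e-3, iterations = 1))
  asg <- assign_groups(cluster_components(g), g)
  m <- build_render_model(list(nb), asg, assign_colours(asg))
  t2 <- write_description(m)
  expect_equal(sum(!startsWith(t2, "#")), 1L)
  expect_match(t2, "truncated", all = FALSE)
})

test_that("group numbers in the SVG and TSV agree exactly", {
  rc <- render_case(seed = 57, n_assemblies = 4, n_families = 3)
  svg <- render_diagram_svg(rc$model)
  tsv <- write_description(rc$model)
  svg_labels <- regmatches(svg, gregexpr(">[0-9]+</text>", svg))[[1]]
  svg_groups <- sort(unique(as.integer(gsub("\\D", "", svg_labels))))
  cells <- strsplit(tsv[!startsWith(tsv, "#")], "\t", fixed = TRUE)
  tsv_groups <- sort(unique(suppressWarnings(
    as.integer(vapply(cells, `[`, "", 6)))))
  tsv_groups <- tsv_groups[!is.na(tsv_groups)]
  expect_equal(svg_groups, tsv_groups)
  # and both match the legend
  expect_equal(tsv_groups, sort(rc$model$legend$group_id))
})

test_that("SVG output is valid XML and deterministic", {
  rc <- render_case(seed = 58)
  svg1 <- render_diagram_svg(rc$model)
  svg2 <- render_diagram_svg(rc$model)
  expect_identical(svg1, svg2)
  expect_no_error(xml2::read_xml(svg1))
})
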