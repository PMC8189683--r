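#' Configuration for an end-to-end run
#'
#' @param query_file Path to the query list (see [parse_query_list()]).
#' @param assemblies List of `list(gff=, faa=, assembly_id=)` sources, or a
#'   list of already-loaded `assembly` objects.
#' @param n_flank Flanking genes per side (default 4).
#' @param evalue_cutoff Significance cut-off (default 1e-3).
#' @param iterations Profile-search iterations, external backend only
#'   (default 3).
#' @param backend `"builtin"` or `"external_profile"`.
#' @param seed Integer seed (colour phase and any stochastic choices).
#' @param outdir Output directory (created if needed).
#' @param tree `"off"`, `"build"`, or a path to a user Newick whose leaves
#'   are the query accessions (takes precedence over building).
#' @param bp_per_px Diagram scale.
#' @return A `run_config` list with defaults applied.
#' @export
run_config <- function(query_file, assemblies, n_flank = 4L,
                       evalue_cutoff = 1e-3, iterations = 3L,
                       backend = "builtin", seed = 0L,
                       outdir = ".", tree = "build", bp_per_px = 20) {
  stopifnot(is.numeric(n_flank), n_flank >= 1)
  structure(list(query_file = query_file, assemblies = assemblies,
                 n_flank = as.integer(n_flank), evalue_cutoff = evalue_cutoff,
                 iterations = as.integer(iterations), backend = backend,
                 seed = as.integer(seed), outdir = outdir, tree = tree,
                 bp_per_px = bp_per_px),
            class = "run_config")
}

#' Run the full neighbourhood-conservation pipeline
#'
#' Executes parse -> load -> locate -> extract -> cluster -> assign ->
#' render. Per-query failures (accessions not found) are recorded in the
#' report and skipped; the run fails only if no query succeeds. Outputs
#' (`neighbourhoods.svg`, `description.tsv`, and with a tree also
#' `tree.svg` + `tree.nwk`) are written to a temporary directory and moved
#' into `outdir` atomically on success, so a failed run leaves no partial
#' outputs.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `queries` (data.frame of per-query
#'   status), `groups` (legend table), `params`, `seed`, `output_files`,
#'   `log` (recorded warnings), `model`, and `ok` (TRUE iff >= 1 query
#'   succeeded).
#' @export
run_neighbourhood_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)

  queries <- parse_query_list(config$query_file)

  assemblies <- lapply(config$assemblies, function(a) {
    if (inherits(a, "assembly")) return(a)
    if (is.null(a$gff) || is.null(a$faa) || is.null(a$assembly_id))
      stop("each assembly source needs gff, faa and assembly_id", call. = FALSE)
    load_assembly(a$gff, a$faa, a$assembly_id)
  })
  for (a in assemblies) log <- c(log, a$warnings)

  status <- character(nrow(queries))
  nbs <- list()
  for (i in seq_len(nrow(queries))) {
    loc <- locate_query(assemblies, queries$protein_id[i], queries$assembly_id[i])
    if (is.null(loc)) {
      status[i] <- "missing"
      log <- c(log, sprintf("query %s: not found in any assembly", queries$protein_id[i]))
      next
    }
    nbs[[length(nbs) + 1L]] <- extract_neighbourhood(loc$assembly, loc$record,
                                                     config$n_flank)
    status[i] <- "ok"
  }
  report_queries <- data.frame(protein_id = queries$protein_id,
                               assembly_id = queries$assembly_id,
                               status = status, stringsAsFactors = FALSE)
  if (!any(status == "ok")) {
    return(structure(list(queries = report_queries, groups = NULL,
                          params = config, seed = config$seed,
                          output_files = character(0), log = log,
                          model = NULL, ok = FALSE),
                     class = "run_report"))
  }

  params <- search_params(config$evalue_cutoff, config$iterations, config$backend)
  graph <- build_hit_graph(nbs, params)
  log <- c(log, graph$warnings)
  comps <- cluster_components(graph)
  assignment <- assign_groups(comps, graph)
  palette <- assign_colours(assignment, config$seed)
  model <- build_render_model(nbs, assignment, palette, config$bp_per_px)

  # tree handling
  tr <- NULL
  if (!identical(config$tree, "off")) {
    qids <- vapply(nbs, function(nb) nb$query_protein_id, "")
    if (identical(config$tree, "build")) {
      seqs <- vapply(nbs, function(nb) {
        s <- nb$proteins[nb$query_protein_id]
        if (length(s) == 1L && !is.na(s)) unname(s) else NA_character_
      }, "")
      names(seqs) <- qids
      seqs <- seqs[!is.na(seqs)]
      if (length(seqs) >= 2L) {
        tr <- withCallingHandlers(build_guide_tree(seqs), warning = function(w) {
          log <<- c(log, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      } else {
        log <- c(log, "tree requested but < 2 queries succeeded; skipped")
      }
    } else {
      tr <- ape::read.tree(config$tree)
    }
  }

  # render everything into a temp dir, then move atomically
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("gcx_out", tmpdir = config$outdir)
  dir.create(tmp)
  files <- character(0)
  writeLines(render_diagram_svg(model), file.path(tmp, "neighbourhoods.svg"))
  files <- c(files, "neighbourhoods.svg")
  writeLines(write_description(model), file.path(tmp, "description.tsv"))
  files <- c(files, "description.tsv")
  if (!is.null(tr)) {
    writeLines(render_newick(tr), file.path(tmp, "tree.nwk"))
    writeLines(annotate_tree(tr, model), file.path(tmp, "tree.svg"))
    files <- c(files, "tree.nwk", "tree.svg")
  }
  dest <- file.path(config$outdir, files)
  ok_move <- file.rename(file.path(tmp, files), dest)
  if (!all(ok_move)) {  # cross-device fallback
    file.copy(file.path(tmp, files)[!ok_move], dest[!ok_move], overwrite = TRUE)
  }
  unlink(tmp, recursive = TRUE)

  structure(list(queries = report_queries, groups = model$legend,
                 params = config, seed = config$seed,
                 output_files = dest, log = log, model = model, ok = TRUE),
            class = "run_report")
}

render_newick <- function(tr) ape::write.tree(tr)

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d/%d quer%s ok; %s numbered group(s)\n",
              sum(x$queries$status == "ok"), nrow(x$queries),
              if (nrow(x$queries) == 1L) "y" else "ies",
              if (is.null(x$groups)) "0" else nrow(x$groups)))
  if (length(x$output_files))
    cat("  outputs:", paste(basename(x$output_files), collapse = ", "), "\n")
  if (length(x$log)) cat(sprintf("  %d log message(s)\n", length(x$log)))
  invisible(x)
}

# flat "key: value" config-file parser; command-line flags override
read_config_file <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*?)\\s*$", ln))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("bad config line (expected 'key: value'): %s", ln), call. = FALSE)
    out[[m[2L]]] <- m[3L]
  }
  out
}

#' Command-line entry point
#'
#' Flags: `--queries FILE`, `--assembly GFF,FAA,ID` (repeatable),
#' `--flank N`, `--evalue X`, `--iterations K`,
#' `--backend builtin|external`, `--tree off|build|PATH.nwk`, `--seed S`,
#' `--outdir D`, `--config FILE` (flat `key: value`; flags override),
#' `--verbose`. Installed as `inst/cli/genecontext.R`, runnable with
#' `Rscript $(Rscript -e 'cat(system.file("cli/genecontext.R", package="genecontext"))') ...`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status: 0 if at least one query succeeded, 1 otherwise.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- list(queries = NULL, flank = "4", evalue = "1e-3", iterations = "3",
               backend = "builtin", tree = "build", seed = "0", outdir = ".",
               verbose = FALSE)
  asm <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; if (i > length(args)) stop(sprintf("flag %s needs a value", a), call. = FALSE); args[i] }
    switch(a,
      "--queries" = { opts$queries <- take() },
      "--assembly" = { asm <- c(asm, take()) },
      "--flank" = { opts$flank <- take() },
      "--evalue" = { opts$evalue <- take() },
      "--iterations" = { opts$iterations <- take() },
      "--backend" = { opts$backend <- take() },
      "--tree" = { opts$tree <- take() },
      "--seed" = { opts$seed <- take() },
      "--outdir" = { opts$outdir <- take() },
      "--verbose" = { opts$verbose <- TRUE },
      "--config" = {
        cf <- read_config_file(take())
        for (k in names(cf)) {
          if (k == "assembly") asm <- c(asm, strsplit(cf[[k]], ";", fixed = TRUE)[[1L]])
          else opts[[k]] <- cf[[k]]
        }
      },
      stop(sprintf("unknown flag: %s", a), call. = FALSE))
    i <- i + 1L
  }
  if (is.null(opts$queries)) stop("--queries is required", call. = FALSE)
  if (length(asm) == 0L) stop("at least one --assembly GFF,FAA,ID is required", call. = FALSE)
  sources <- lapply(strsplit(asm, ",", fixed = TRUE), function(p) {
    if (length(p) != 3L) stop("--assembly expects GFF,FAA,ID", call. = FALSE)
    list(gff = p[1L], faa = p[2L], assembly_id = p[3L])
  })
  backend <- if (opts$backend == "external") "external_profile" else opts$backend
  cfg <- run_config(opts$queries, sources,
                    n_flank = as.integer(opts$flank),
                    evalue_cutoff = as.numeric(opts$evalue),
                    iterations = as.integer(opts$iterations),
                    backend = backend, seed = as.integer(opts$seed),
                    outdir = opts$outdir, tree = opts$tree)
  report <- run_neighbourhood_analysis(cfg)
  if (opts$verbose) {
    print(report)
    for (msg in report$log) message("note: ", msg)
  }
  if (report$ok) 0L else 1L
}
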