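#' Parse a query list
#'
#' Reads the plain-text query format: one protein accession per line,
#' optionally followed by a genome assembly identifier (tab- or
#' whitespace-separated). Blank lines and lines starting with `#` are
#' skipped.
#'
#' @param text A single multi-line string, a character vector of lines, or a
#'   path to an existing file.
#' @return A data.frame with columns `protein_id` and `assembly_id`
#'   (`NA` when no assembly was given), one row per query, in input order.
#' @examples
#' parse_query_list("WP_0001.1\nWP_0002.1\tGCF_9\n")
#' @export
parse_query_list <- function(text) {
  lines <- read_text_lines(text)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no queries found in query list", call. = FALSE)
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(parts)
  if (any(nf > 2L)) {
    bad <- idx[which(nf > 2L)[1L]]
    stop(sprintf("malformed query line %d: expected 'protein_id' or 'protein_id<TAB>assembly_id', got %d fields",
                 bad, nf[which(nf > 2L)[1L]]), call. = FALSE)
  }
  out <- data.frame(
    protein_id  = vapply(parts, `[`, "", 1L),
    assembly_id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  if (any(out$protein_id == "")) stop("empty protein identifier in query list", call. = FALSE)
  key <- paste(out$protein_id, out$assembly_id)
  if (anyDuplicated(key)) {
    d <- out$protein_id[duplicated(key)][1L]
    stop(sprintf("duplicate query entry: %s", d), call. = FALSE)
  }
  class(out) <- c("query_list", "data.frame")
  out
}

# Accept a file path, a single string with embedded newlines, or a vector of
# lines; gzip-compressed paths are handled transparently.
read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    con <- if (grepl("\\.gz$", x)) gzfile(x, "rt") else file(x, "rt")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}
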