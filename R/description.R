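#' Write the description (legend) table
#'
#' One row per (query, slot) in input order, then drawn slot order. The
#' `group` column carries the group number for numbered genes, `NC` for
#' coding genes not conserved in the dataset, `PSEUDO` for pseudogenes and
#' `RNA` for non-coding genes. The header line is `#`-prefixed;
#' `#note` comment lines record contig-edge truncation.
#'
#' @param model A `render_model`.
#' @return Character vector of tab-separated lines (header first).
#' @export
write_description <- function(model) {
  stopifnot(inherits(model, "render_model"))
  header <- paste0("#", paste(
    c("query_id", "assembly_id", "contig", "slot", "protein_id", "group",
      "colour", "product", "strand", "start", "end", "flipped"),
    collapse = "\t"))
  lines <- character(0)
  for (i in seq_along(model$rows)) {
    r <- model$rows[[i]]
    nb <- model$neighbourhoods[[i]]
    for (j in seq_len(nrow(r))) {
      grp <- if (!is.na(r$group_id[j])) as.character(r$group_id[j])
             else if (r$kind[j] == "pseudogene") "PSEUDO"
             else if (r$kind[j] == "noncoding") "RNA"
             else "NC"
      colour <- if (!is.na(r$group_id[j])) r$fill[j]
                else if (r$kind[j] == "pseudogene") STYLE_PSEUDO_FILL
                else if (r$kind[j] == "noncoding") "hatch"
                else "none"
      lines <- c(lines, paste(
        nb$query_protein_id, nb$assembly_id, nb$contig_id, r$slot[j],
        ifelse(is.na(r$protein_id[j]), "-", r$protein_id[j]),
        grp, colour, r$product[j], r$strand[j], r$start[j], r$end[j],
        tolower(nb$flipped), sep = "\t"))
    }
    if (nb$truncated_left)
      lines <- c(lines, sprintf("#note\t%s\ttruncated_left", nb$query_protein_id))
    if (nb$truncated_right)
      lines <- c(lines, sprintf("#note\t%s\ttruncated_right", nb$query_protein_id))
  }
  c(header, lines)
}
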