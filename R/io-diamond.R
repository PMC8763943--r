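#' Read DIAMOND/BLAST 12-column tabular hits against KEGG orthologs
#'
#' Reads the standard 12-column BLAST tabular dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`). The
#' format carries no query-coverage column, so coverage is computed from the
#' aligned query span and a caller-supplied query-length table:
#' `query_coverage = (|qend - qstart| + 1) / query_length * 100`.
#'
#' @param path Path to the tabular hit file.
#' @param query_lengths Named numeric vector (or two-column data frame
#'   `query_id`, `length`) giving each query's length in the same unit as
#'   the alignment coordinates.
#' @return A tibble (class `ko_hit_tbl`) with columns `read_id`, `ko_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_openings`,
#'   `qstart`, `qend`, `sstart`, `send`, `e_value`, `bit_score`,
#'   `query_coverage`.
#' @export
read_diamond_hits <- function(path, query_lengths) {
  if (is.data.frame(query_lengths)) {
    query_lengths <- setNames(query_lengths[[2]], query_lengths[[1]])
  }
  cols <- c(
    "read_id", "ko_id", "percent_identity", "align_length", "mismatches",
    "gap_openings", "qstart", "qend", "sstart", "send", "e_value", "bit_score"
  )
  raw_lines <- readLines(path)
  if (!any(nzchar(raw_lines) & !startsWith(raw_lines, "#"))) {
    empty <- as_tibble(setNames(
      c(list(character(0), character(0)), rep(list(double(0)), 10)), cols
    ))
    return(ko_hit_tbl(mutate(empty, query_coverage = double(0))))
  }
  tab <- tryCatch(
    readr::read_tsv(
      path,
      col_names = cols,
      col_types = "ccnnnnnnnnnn",
      comment = "#", progress = FALSE
    ),
    warning = function(w) abort(paste0("parse error in ", path, ": ", conditionMessage(w)))
  )
  if (!nrow(tab)) {
    return(ko_hit_tbl(mutate(tab, query_coverage = double(0))))
  }
  num_cols <- cols[-(1:2)]
  bad <- vapply(tab[num_cols], anyNA, logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric value in column ", num_cols[bad][1], " of ", path))
  }
  if (any(tab$e_value < 0)) abort(paste0("negative e-value in ", path))
  unknown <- setdiff(unique(tab$read_id), names(query_lengths))
  if (length(unknown)) {
    abort(paste0("query id missing from length table: ", unknown[1]))
  }
  qlen <- unname(query_lengths[tab$read_id])
  hits <- tab |>
    mutate(query_coverage = (abs(.data$qend - .data$qstart) + 1) / qlen * 100)
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    abort(paste0("percent identity outside [0, 100] in ", path))
  }
  ko_hit_tbl(hits)
}

ko_hit_tbl <- function(x) {
  structure(as_tibble(x), class = c("ko_hit_tbl", class(as_tibble(x))))
}
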