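#' Taxonomic ranks used for clade profiles
#'
#' @return Character vector of the six ranks, highest to lowest.
#' @export
taxon_ranks <- function() {
  c("phylum", "class", "order", "family", "genus", "species")
}

rank_prefixes <- c(
  k = "kingdom", p = "phylum", c = "class", o = "order",
  f = "family", g = "genus", s = "species", t = "strain"
)

#' Read a MetaPhlAn-style clade abundance profile
#'
#' Parses a two-column TSV of pipe-delimited clade strings
#' (`k__Bacteria|p__Firmicutes|...`) and relative abundances (percent).
#' Only bacterial lineages are retained; each line contributes one entry at
#' its terminal rank (the deepest rank named on the line). Kingdom-only and
#' strain-level lines carry no entry at the six ranks used downstream and
#' are skipped. Comment lines (`#`) are ignored.
#'
#' Per rank, abundances are expected to sum to at most 100 (within 1%
#' relative tolerance, since profiler output is rounded); a larger sum
#' triggers a warning, not an error.
#'
#' @param path Path to the profile TSV.
#' @param sample_id Sample identifier to attach; defaults to the file name
#'   without extension.
#' @return A tibble (class `taxon_profile`) with columns `sample_id`,
#'   `rank`, `clade`, `proportion`.
#' @export
read_metaphlan_profile <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) {
    warn(paste0("empty profile: ", path))
    return(taxon_profile(tibble(
      sample_id = character(), rank = character(),
      clade = character(), proportion = double()
    )))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    abort(sprintf("line %d of %s: expected two tab-separated columns", line_no[bad][1], path))
  }
  clade_str <- vapply(parts, `[`, character(1), 1L)
  prop <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(prop)) {
    abort(sprintf("line %d of %s: non-numeric abundance", line_no[which(is.na(prop))[1]], path))
  }
  if (any(prop < 0)) {
    abort(sprintf("line %d of %s: negative abundance", line_no[which(prop < 0)[1]], path))
  }

  entries <- vector("list", length(clade_str))
  for (i in seq_along(clade_str)) {
    segs <- strsplit(clade_str[i], "|", fixed = TRUE)[[1]]
    pref <- sub("__.*$", "", segs)
    name <- sub("^[a-z]__", "", segs)
    if (any(!pref %in% names(rank_prefixes)) || any(!grepl("^[a-z]__", segs))) {
      abort(sprintf("line %d of %s: malformed clade string '%s'", line_no[i], path, clade_str[i]))
    }
    ranks <- unname(rank_prefixes[pref])
    if (anyDuplicated(ranks)) {
      abort(sprintf("line %d of %s: repeated rank in clade string", line_no[i], path))
    }
    if (ranks[1] != "kingdom" || name[1] != "Bacteria") next  # non-bacterial or rootless
    terminal <- ranks[length(ranks)]
    if (!terminal %in% taxon_ranks()) next  # kingdom-only or strain line
    if (!nzchar(name[length(name)])) {
      abort(sprintf("line %d of %s: empty clade name", line_no[i], path))
    }
    entries[[i]] <- tibble(
      sample_id = sample_id, rank = terminal,
      clade = name[length(name)], proportion = prop[i]
    )
  }
  out <- bind_rows(entries)
  if (nrow(out)) {
    dup <- out |>
      dplyr::count(.data$rank, .data$clade) |>
      filter(n > 1)
    if (nrow(dup)) {
      abort(sprintf(
        "%s: clade '%s' repeated at rank %s", path, dup$clade[1], dup$rank[1]
      ))
    }
    sums <- out |>
      group_by(.data$rank) |>
      summarise(total = sum(.data$proportion), .groups = "drop")
    if (any(sums$total > 100 * 1.01)) {
      r <- sums$rank[sums$total > 100 * 1.01][1]
      warn(sprintf(
        "%s: %s abundances sum to %.2f (> 100)", path, r,
        sums$total[sums$rank == r]
      ))
    }
  }
  taxon_profile(out)
}

taxon_profile <- function(x) {
  structure(as_tibble(x), class = c("taxon_profile", class(as_tibble(x))))
}
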