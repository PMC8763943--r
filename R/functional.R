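#' Filter KO hits by identity, query coverage and e-value
#'
#' Keeps hits with `percent_identity >= min_identity`,
#' `query_coverage >= min_qcov` and `e_value <= max_evalue`. All three
#' cutoffs are inclusive.
#'
#' @param hits A KO-hit tibble ([read_diamond_hits()]).
#' @param min_identity Percent-identity cutoff (default 50).
#' @param min_qcov Query-coverage cutoff in percent (default 50).
#' @param max_evalue E-value cutoff (default `1e-10`).
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, min_identity = 50, min_qcov = 50,
                        max_evalue = 1e-10) {
  keep <- hits$percent_identity >= min_identity &
    hits$query_coverage >= min_qcov &
    hits$e_value <= max_evalue
  ko_hit_tbl(hits[keep, , drop = FALSE])
}

#' Assign each read its best KO hit
#'
#' Reads with multiple passing hits keep the hit with the highest bit
#' score; ties break to the lowest e-value, then to the lexicographically
#' smallest `ko_id`.
#'
#' @param hits A filtered KO-hit tibble.
#' @return A hit tibble with one row per read.
#' @export
assign_best_hit <- function(hits) {
  out <- hits |>
    group_by(.data$read_id) |>
    arrange(desc(.data$bit_score), .data$e_value, .data$ko_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  ko_hit_tbl(out)
}

#' Read a KO gene-length table
#'
#' @param path Two-column TSV (`ko_id`, `gene_length`); lines starting with
#'   `#` are ignored.
#' @return Named numeric vector of gene lengths.
#' @export
read_ko_lengths <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("ko_id", "gene_length"), col_types = "cn",
    comment = "#", progress = FALSE
  )
  if (any(tab$gene_length < 1)) abort("KO gene lengths must be >= 1")
  setNames(tab$gene_length, tab$ko_id)
}

#' Assemble the KO functional abundance feature matrix
#'
#' Counts each sample's reads assigned per KO, converts the counts to
#' gene-length-normalised RPKM
#' (`count * 1e3 * 1e6 / (total_reads * gene_length)`), and log-transforms.
#' Columns are the KOs matched by at least one read in any sample.
#'
#' @param assigned A tibble with columns `sample_id`, `read_id`, `ko_id` —
#'   per-sample best-hit assignments ([assign_best_hit()] with a
#'   `sample_id` column added, or their row-bound combination).
#' @param gene_lengths Named numeric vector of KO gene lengths
#'   ([read_ko_lengths()]).
#' @param total_reads Named numeric vector: reads per sample (RPKM
#'   denominator). Samples with zero assigned reads must still appear here
#'   to get a row of zeros.
#' @param pseudocount Passed to [log_transform()].
#' @param log Apply the log transform (default `TRUE`).
#' @return A `feature_matrix` (modality `"functional"`).
#' @export
build_functional_matrix <- function(assigned, gene_lengths, total_reads,
                                    pseudocount = 1e-6, log = TRUE) {
  if (is.data.frame(total_reads)) {
    total_reads <- setNames(total_reads[[2]], total_reads[[1]])
  }
  samples <- names(total_reads)
  if (any(total_reads <= 0)) abort("total_reads must be positive")
  extra <- setdiff(unique(assigned$sample_id), samples)
  if (length(extra)) {
    abort(paste0("assigned hits for sample missing from total_reads: ", extra[1]))
  }
  kos <- sort(unique(assigned$ko_id))
  missing_ko <- setdiff(kos, names(gene_lengths))
  if (length(missing_ko)) {
    abort(paste0(
      "KO(s) missing from the gene-length table: ",
      paste(missing_ko, collapse = ", ")
    ))
  }
  if (!length(kos)) {
    m <- feature_matrix(tibble(sample_id = samples), modality = "functional")
    return(if (log) log_transform(m, pseudocount) else m)
  }
  counts <- assigned |>
    group_by(.data$sample_id, .data$ko_id) |>
    summarise(count = n_distinct(.data$read_id), .groups = "drop")
  grid <- tidyr::expand_grid(sample_id = samples, ko_id = kos) |>
    left_join(counts, by = c("sample_id", "ko_id")) |>
    mutate(
      count = replace_na(.data$count, 0L),
      value = .data$count * 1e3 * 1e6 /
        (unname(total_reads[.data$sample_id]) * unname(gene_lengths[.data$ko_id]))
    )
  wide <- grid |>
    select("sample_id", "ko_id", "value") |>
    pivot_wider(names_from = "ko_id", values_from = "value")
  wide <- wide[match(samples, wide$sample_id), , drop = FALSE]
  m <- feature_matrix(wide, modality = "functional", transform = "raw")
  if (log) log_transform(m, pseudocount) else m
}
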