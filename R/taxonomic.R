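#' Build a per-rank abundance table from clade profiles
#'
#' Assembles the union of clade names observed at one taxonomic rank across
#' samples into a samples x clades `feature_matrix` of proportions; clades
#' absent from a sample are filled with 0.
#'
#' @param profiles A single profile tibble ([read_metaphlan_profile()]), a
#'   list of them, or their row-bound combination.
#' @param rank One of [taxon_ranks()].
#' @return A `feature_matrix` (modality `"taxonomic"`, transform `"raw"`).
#' @export
build_rank_table <- function(profiles, rank) {
  rank <- match.arg(rank, taxon_ranks())
  if (is.data.frame(profiles)) profiles <- list(profiles)
  per_profile_ids <- unlist(map(profiles, function(p) unique(p$sample_id)))
  if (anyDuplicated(per_profile_ids)) {
    abort(paste0(
      "duplicate sample_id across profiles: ",
      per_profile_ids[duplicated(per_profile_ids)][1]
    ))
  }
  prof <- bind_rows(profiles)
  if (nrow(prof) && anyDuplicated(prof[c("sample_id", "rank", "clade")])) {
    abort("duplicate (sample, rank, clade) entry across profiles")
  }
  samples <- unique(prof$sample_id)
  if (length(samples) < 2L) {
    abort("build_rank_table() needs profiles from at least two samples")
  }
  at_rank <- prof[prof$rank == rank, , drop = FALSE]
  clades <- sort(unique(at_rank$clade))
  wide <- tibble(sample_id = samples)
  if (length(clades)) {
    filled <- at_rank |>
      select("sample_id", "clade", "proportion") |>
      pivot_wider(
        names_from = "clade", values_from = "proportion", values_fill = 0
      )
    wide <- left_join(wide, filled, by = "sample_id")
    wide[clades] <- lapply(wide[clades], function(v) replace(v, is.na(v), 0))
    wide <- wide[, c("sample_id", clades)]
  }
  feature_matrix(wide, modality = "taxonomic", transform = "raw")
}

#' Remove taxa observed in at most one sample
#'
#' Drops feature columns whose abundance is nonzero in one sample or none:
#' such taxa are likely sample-specific and uninformative for
#' classification. Column order is otherwise preserved.
#'
#' @param m A raw taxonomic `feature_matrix`.
#' @param min_samples Minimum number of samples with nonzero abundance a
#'   taxon must reach to be kept (default 2).
#' @return A `feature_matrix` with the filtered column set.
#' @export
filter_single_sample_taxa <- function(m, min_samples = 2L) {
  stopifnot(inherits(m, "feature_matrix"))
  if (fm_transform(m) != "raw") {
    abort("filter_single_sample_taxa() expects a raw feature_matrix")
  }
  vals <- fm_values(m)
  keep <- colSums(vals != 0) >= min_samples
  out <- as_tibble(m)[, c("sample_id", fm_feature_ids(m)[keep]), drop = FALSE]
  feature_matrix(out, modality = fm_modality(m), transform = "raw")
}

#' Log-transform a feature matrix
#'
#' Applies `log10(value + pseudocount)` elementwise; the pseudocount keeps
#' zero abundances finite. Neural-network inputs are log-transformed
#' throughout the pipeline.
#'
#' @param m A raw `feature_matrix` (all values >= 0).
#' @param pseudocount Additive constant before the log (default `1e-6`).
#' @return A `feature_matrix` with transform `"log"`.
#' @export
log_transform <- function(m, pseudocount = 1e-6) {
  stopifnot(inherits(m, "feature_matrix"))
  if (fm_transform(m) != "raw") abort("feature_matrix is already log-transformed")
  vals <- fm_values(m)
  if (any(vals < 0)) abort("log_transform() requires non-negative values")
  if (any(vals + pseudocount <= 0)) {
    abort("zero values need a positive pseudocount")
  }
  out <- as_tibble(m)
  out[fm_feature_ids(m)] <- as_tibble(log10(vals + pseudocount), .name_repair = "minimal")
  feature_matrix(out, modality = fm_modality(m), transform = "log")
}
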