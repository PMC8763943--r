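#' Feature matrices
#'
#' A `feature_matrix` is the universal currency between pipeline stages: a
#' tibble whose first column is `sample_id` and whose remaining columns are
#' numeric feature abundances, tagged with a `modality` (which of the three
#' feature families it holds, or an embedding/fused representation) and a
#' `transform` state (`"raw"` non-negative abundances or `"log"` values).
#'
#' @param x A data frame with a `sample_id` character column followed by
#'   numeric feature columns, or a numeric matrix with sample-id rownames.
#' @param modality One of `"taxonomic"`, `"genomic"`, `"functional"`,
#'   `"embedding"`, `"fused"`.
#' @param transform `"raw"` or `"log"`.
#' @return A tibble of class `feature_matrix`.
#' @examples
#' fm <- feature_matrix(
#'   tibble::tibble(sample_id = c("s1", "s2"), fA = c(1, 0), fB = c(2.5, 4)),
#'   modality = "taxonomic"
#' )
#' fm_modality(fm)
#' @export
feature_matrix <- function(x, modality, transform = "raw") {
  modality <- match.arg(modality, fm_modalities())
  transform <- match.arg(transform, c("raw", "log"))
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort("matrix input to feature_matrix() needs sample-id rownames")
    }
    x <- tibble(sample_id = rownames(x), as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!identical(names(x)[1], "sample_id")) {
    abort("first column of a feature_matrix must be 'sample_id'")
  }
  x$sample_id <- as.character(x$sample_id)
  validate_feature_matrix(x, modality, transform)
  structure(
    x,
    modality = modality,
    transform = transform,
    class = c("feature_matrix", class(as_tibble(x)))
  )
}

fm_modalities <- function() {
  c("taxonomic", "genomic", "functional", "embedding", "fused")
}

validate_feature_matrix <- function(x, modality, transform) {
  if (anyDuplicated(x$sample_id)) {
    abort(paste0(
      "duplicated sample_id: ",
      paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")
    ))
  }
  feats <- names(x)[-1]
  if (anyDuplicated(feats)) {
    abort("duplicated feature ids in feature_matrix")
  }
  if (length(feats)) {
    ok <- vapply(x[feats], is.numeric, logical(1))
    if (!all(ok)) {
      abort(paste0("non-numeric feature columns: ", paste(feats[!ok], collapse = ", ")))
    }
    vals <- as.matrix(x[feats])
    if (transform == "raw" && any(vals < 0, na.rm = TRUE)) {
      abort("raw feature_matrix values must be >= 0")
    }
    if (transform == "log" && any(!is.finite(vals))) {
      abort("log-transformed feature_matrix values must be finite")
    }
  }
  invisible(x)
}

#' @rdname feature_matrix
#' @export
fm_modality <- function(x) attr(x, "modality")

#' @rdname feature_matrix
#' @export
fm_transform <- function(x) attr(x, "transform")

#' @rdname feature_matrix
#' @export
fm_sample_ids <- function(x) x$sample_id

#' @rdname feature_matrix
#' @export
fm_feature_ids <- function(x) setdiff(names(x), "sample_id")

#' Extract the dense value matrix of a feature_matrix
#'
#' @param x A `feature_matrix`.
#' @return A numeric matrix, samples in rows (rownames = sample ids).
#' @export
fm_values <- function(x) {
  m <- as.matrix(as_tibble(x)[fm_feature_ids(x)])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "# feature_matrix: %d samples x %d features [%s, %s]\n",
    nrow(x), length(fm_feature_ids(x)), fm_modality(x), fm_transform(x)
  ))
  NextMethod()
}

#' Write / read a feature_matrix as annotated TSV
#'
#' The on-disk format is a TSV with a header row of feature ids, a leading
#' `sample_id` column, and `#key=value` metadata lines (`modality`,
#' `transform`) before the header. Values round-trip exactly.
#'
#' @param x A `feature_matrix`.
#' @param path File path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  feats <- fm_feature_ids(x)
  vals <- fm_values(x)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$sample_id[i], sprintf("%.17g", vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(
    c(
      paste0("#modality=", fm_modality(x)),
      paste0("#transform=", fm_transform(x)),
      paste(c("sample_id", feats), collapse = "\t"),
      body
    ),
    path
  )
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  header <- readLines(path, n = 50L)
  meta_lines <- grep("^#", header, value = TRUE)
  meta <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(
    vapply(meta, `[`, character(1), 2L),
    vapply(meta, `[`, character(1), 1L)
  )
  for (key in c("modality", "transform")) {
    if (is.na(meta[key])) abort(paste0("missing #", key, "= header in ", path))
  }
  tab <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(
      sample_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  feature_matrix(tab, modality = meta[["modality"]], transform = meta[["transform"]])
}
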