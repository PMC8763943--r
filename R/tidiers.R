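#' Tidy evaluation results
#'
#' `tidy()` on an `eval_result` returns the per-fold prediction table;
#' `glance()` returns a one-row summary of the aggregate metrics.
#'
#' @param x An `eval_result` or `eval_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eval_result <- function(x, ...) {
  x$folds
}

#' @rdname tidy.eval_result
#' @export
glance.eval_result <- function(x, ...) {
  bind_cols(
    x$metrics,
    tibble(auc = x$auc, n_folds = nrow(x$folds), positive = x$positive)
  )
}

#' @rdname tidy.eval_result
#' @export
tidy.eval_summary <- function(x, ...) {
  x$per_run
}

#' @rdname tidy.eval_result
#' @export
glance.eval_summary <- function(x, ...) {
  bind_cols(x$mean_metrics, tibble(n_runs = nrow(x$per_run)))
}

#' Tidy a trained multimodal model
#'
#' One row per network layer with its dimensions, for a quick structural
#' overview.
#'
#' @param x A `multimodal_model`.
#' @param ... Unused.
#' @return A tibble with `network`, `layer`, `from`, `to`.
#' @export
tidy.multimodal_model <- function(x, ...) {
  nets <- c(x$encoders, list(fusion = x$fusion))
  imap(nets, function(net, name) {
    sizes <- net$params$sizes
    tibble(
      network = name,
      layer = seq_len(length(sizes) - 1L),
      from = sizes[-length(sizes)],
      to = sizes[-1]
    )
  }) |> list_rbind()
}

#' @rdname tidy.multimodal_model
#' @export
glance.multimodal_model <- function(x, ...) {
  tibble(
    n_modalities = length(x$modalities),
    n_classes = length(x$classes),
    embedding_dim = sum(map_int(x$encoders, function(e) {
      tail(e$config$hidden_sizes, 1L)
    }))
  )
}
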