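#' Encoder / classifier network configuration
#'
#' Hyperparameters for one feedforward network: ReLU hidden layers, softmax
#' output, Adam optimiser with the canonical moment decays, categorical
#' cross-entropy loss.
#'
#' @param hidden_sizes Hidden-layer node counts (default `c(200, 100, 50)`;
#'   the last entry is the embedding width).
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam step size (default 0.001).
#' @param beta1,beta2 Adam moment decays (defaults 0.9, 0.999).
#' @param seed Integer seed controlling weight initialisation and batch
#'   order.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(hidden_sizes = c(200, 100, 50), epochs = 100,
                           batch_size = 16, learning_rate = 0.001,
                           beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  if (!length(hidden_sizes) || any(hidden_sizes < 1)) {
    abort("hidden_sizes must be a non-empty vector of counts >= 1")
  }
  structure(
    list(
      hidden_sizes = as.integer(hidden_sizes), epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      beta1 = beta1, beta2 = beta2, seed = as.integer(seed)
    ),
    class = "encoder_config"
  )
}

#' Default per-modality encoder configurations
#'
#' Taxonomic and genomic encoders use 200-100-50 hidden layers; the
#' functional encoder, built for larger feature sets, uses 500-100-50; the
#' fusion classifier uses 50-25.
#'
#' @param seed Base seed; each network gets a distinct derived seed.
#' @inheritParams encoder_config
#' @return Named list of `encoder_config`s
#'   (`taxonomic`, `genomic`, `functional`, `fusion`).
#' @export
default_model_configs <- function(seed = 1L, epochs = 100, batch_size = 16) {
  list(
    taxonomic = encoder_config(c(200, 100, 50), epochs, batch_size, seed = seed + 101L),
    genomic = encoder_config(c(200, 100, 50), epochs, batch_size, seed = seed + 202L),
    functional = encoder_config(c(500, 100, 50), epochs, batch_size, seed = seed + 303L),
    fusion = encoder_config(c(50, 25), epochs, batch_size, seed = seed + 404L)
  )
}

check_labels <- function(labels, n) {
  labels <- as.factor(labels)
  if (length(labels) != n) abort("labels length must equal the sample count")
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) abort("training needs at least two classes")
  labels
}

one_hot <- function(labels) {
  Y <- matrix(0, nrow = length(labels), ncol = nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Train a per-modality encoder network
#'
#' Fits a supervised feedforward classifier on one modality's
#' log-transformed feature matrix. The last hidden layer doubles as the
#' modality's embedded representation.
#'
#' @param m A `feature_matrix` with transform `"log"`.
#' @param labels Class labels, one per sample (factor or coercible).
#' @param config An [encoder_config()].
#' @return An `encoder_model` object.
#' @export
train_encoder <- function(m, labels, config = encoder_config()) {
  stopifnot(inherits(m, "feature_matrix"))
  if (fm_transform(m) != "log") {
    abort("train_encoder() expects a log-transformed feature_matrix")
  }
  X <- fm_values(m)
  if (anyNA(X) || any(!is.finite(X))) abort("non-finite values in features")
  labels <- check_labels(labels, nrow(X))
  params <- mlp_train(
    X, one_hot(labels),
    hidden = config$hidden_sizes, epochs = config$epochs,
    batch_size = config$batch_size, learning_rate = config$learning_rate,
    beta1 = config$beta1, beta2 = config$beta2, seed = config$seed
  )
  structure(
    list(
      params = params, classes = levels(labels), config = config,
      feature_ids = fm_feature_ids(m), modality = fm_modality(m)
    ),
    class = "encoder_model"
  )
}

encoder_check_input <- function(object, m) {
  if (length(fm_feature_ids(m)) != length(object$feature_ids)) {
    abort(sprintf(
      "feature count %d does not match encoder input size %d",
      length(fm_feature_ids(m)), length(object$feature_ids)
    ))
  }
  if (!identical(fm_feature_ids(m), object$feature_ids)) {
    abort("feature ids do not match the encoder's training features")
  }
  fm_values(m)
}

#' Embed samples with a trained encoder
#'
#' Returns the activations of the encoder's last hidden layer — the
#' modality's embedded representation.
#'
#' @param object A trained `encoder_model`.
#' @param m A `feature_matrix` with the encoder's feature columns.
#' @return A `feature_matrix` (modality `"embedding"`) whose width is the
#'   last hidden size.
#' @export
embed_samples <- function(object, m) {
  X <- encoder_check_input(object, m)
  E <- mlp_embedding(object$params, X)
  k <- ncol(E)
  colnames(E) <- sprintf("%s_dim%03d", object$modality, seq_len(k))
  rownames(E) <- fm_sample_ids(m)
  feature_matrix(E, modality = "embedding", transform = "log")
}

#' Concatenate per-modality embeddings into a shared representation
#'
#' Column-binds embedding matrices in the given order; samples must agree
#' in identity and order (no silent reordering).
#'
#' @param parts List of embedding `feature_matrix` objects.
#' @return A `feature_matrix` (modality `"fused"`).
#' @export
concat_embeddings <- function(parts) {
  stopifnot(length(parts) >= 1L)
  ids <- fm_sample_ids(parts[[1]])
  for (p in parts[-1]) {
    if (!identical(fm_sample_ids(p), ids)) {
      abort("sample ids/order differ between embedding parts")
    }
  }
  cols <- unlist(map(parts, fm_feature_ids))
  if (anyDuplicated(cols)) abort("duplicate feature ids across embedding parts")
  out <- bind_cols(
    c(list(tibble(sample_id = ids)),
      map(parts, function(p) as_tibble(p)[fm_feature_ids(p)]))
  )
  feature_matrix(out, modality = "fused", transform = "log")
}

#' Train the fusion classifier on the shared representation
#'
#' Fits the final-stage network (50-25 hidden layers by default) on the
#' concatenated embeddings. Encoders are left untouched: two-stage training
#' with frozen encoders.
#'
#' @param fused The `feature_matrix` from [concat_embeddings()].
#' @param labels Class labels.
#' @param config An [encoder_config()] for the fusion network.
#' @return An `encoder_model` acting as the fusion classifier.
#' @export
train_fusion <- function(fused, labels, config = encoder_config(c(50, 25))) {
  if (!fm_modality(fused) %in% c("fused", "embedding")) {
    abort("train_fusion() expects a fused/embedding feature_matrix")
  }
  train_encoder(fused, labels, config)
}

#' Fit the full multimodal model
#'
#' Stage one trains one encoder per modality; stage two freezes them,
#' concatenates their last-hidden-layer embeddings and trains the fusion
#' classifier on the shared representation.
#'
#' @param mats Named list of log-transformed `feature_matrix` objects (same
#'   samples, same order).
#' @param labels Class labels, one per sample.
#' @param configs Named list of [encoder_config()]s: one per modality plus
#'   `fusion` ([default_model_configs()]).
#' @return A `multimodal_model` object.
#' @export
fit_multimodal <- function(mats, labels, configs = default_model_configs()) {
  stopifnot(is.list(mats), length(mats) >= 1L, !is.null(names(mats)))
  ids <- fm_sample_ids(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(fm_sample_ids(m), ids)) {
      abort("sample ids/order differ between modalities")
    }
  }
  encoders <- imap(mats, function(m, name) {
    cfg <- configs[[name]] %||% abort(paste0("no config for modality ", name))
    enc <- train_encoder(m, labels, cfg)
    enc$modality <- name  # embedding columns are named by the list slot
    enc
  })
  embeddings <- map2(encoders, mats, embed_samples)
  fused <- concat_embeddings(unname(embeddings))
  fusion <- train_fusion(fused, labels, configs$fusion %||% encoder_config(c(50, 25)))
  structure(
    list(
      encoders = encoders, fusion = fusion,
      modalities = names(mats), classes = fusion$classes
    ),
    class = "multimodal_model"
  )
}

#' @export
predict.encoder_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- encoder_check_input(object, newdata)
  P <- mlp_predict_proba(object$params, X)
  colnames(P) <- object$classes
  finish_prediction(P, fm_sample_ids(newdata), object$classes, type)
}

#' @export
predict.multimodal_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(is.list(newdata))
  missing_mod <- setdiff(object$modalities, names(newdata))
  if (length(missing_mod)) {
    abort(paste0("missing modality in newdata: ", missing_mod[1]))
  }
  embeddings <- map(object$modalities, function(mod) {
    embed_samples(object$encoders[[mod]], newdata[[mod]])
  })
  fused <- concat_embeddings(embeddings)
  X <- encoder_check_input(object$fusion, fused)
  P <- mlp_predict_proba(object$fusion$params, X)
  colnames(P) <- object$classes
  finish_prediction(P, fm_sample_ids(fused), object$classes, type)
}

# probabilities -> tidy prediction tibble; argmax ties break to the first
# class in label order
finish_prediction <- function(P, sample_ids, classes, type) {
  pred <- classes[apply(P, 1L, which.max)]
  out <- tibble(sample_id = sample_ids)
  probs <- as_tibble(P, .name_repair = "minimal")
  names(probs) <- paste0(".pred_", classes)
  out <- bind_cols(out, probs)
  out$.pred_class <- factor(pred, levels = classes)
  if (type == "class") out[c("sample_id", ".pred_class")] else out
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf(
    "<encoder_model> %s: %d -> %s -> %d classes\n",
    x$modality, length(x$feature_ids),
    paste(x$config$hidden_sizes, collapse = "-"), length(x$classes)
  ))
  invisible(x)
}

#' @export
print.multimodal_model <- function(x, ...) {
  cat(sprintf(
    "<multimodal_model> modalities: %s; classes: %s\n",
    paste(x$modalities, collapse = ", "), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}
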