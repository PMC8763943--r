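test_that("training is deterministic under a fixed seed", {
  d <- tiny_model_data()
  e1 <- train_encoder(d$m, d$labels, fast_cfg(seed = 5))
  e2 <- train_encoder(d$m, d$labels, fast_cfg(seed = 5))
  expect_identical(e1$params$W, e2$params$W)
  expect_identical(e1$params$b, e2$params$b)
  e3 <- train_encoder(d$m, d$labels, fast_cfg(seed = 6))
  expect_false(identical(e1$params$W, e3$params$W))
})

test_that("well-separated classes are fit to training accuracy 1", {
  d <- tiny_model_data(shift = 5)
  enc <- train_encoder(d$m, d$labels, fast_cfg(epochs = 60))
  pred <- predict(enc, d$m)
  expect_equal(mean(pred$.pred_class == d$labels), 1)
})

test_that("encoder input contracts are enforced", {
  d <- tiny_model_data()
  raw <- make_fm(10^fm_values(d$m), modality = "taxonomic", transform = "raw")
  expect_error(train_encoder(raw, d$labels, fast_cfg()), "log-transformed")
  expect_error(
    train_encoder(d$m, rep("one_class", nrow(d$m)), fast_cfg()),
    "two classes"
  )
  bad <- fm_values(d$m)
  bad[1, 1] <- NA
  expect_error(
    train_encoder(make_fm(bad, transform = "log"), d$labels, fast_cfg()),
    "labels length|finite|non-finite"
  )
})

test_that("embeddings tap the last hidden layer", {
  d <- tiny_model_data()
  enc <- train_encoder(d$m, d$labels, fast_cfg(hidden = c(16, 8), epochs = 10))
  emb <- embed_samples(enc, d$m)
  expect_equal(length(fm_feature_ids(emb)), 8L)
  expect_equal(fm_modality(emb), "embedding")
  expect_true(all(fm_values(emb) >= 0))  # ReLU output

  one <- subset_one <- feature_matrix(
    tibble::as_tibble(d$m)[1, ], modality = "taxonomic", transform = "log"
  )
  expect_equal(nrow(embed_samples(enc, one)), 1L)

  wrong <- make_fm(matrix(0, 2, 5), transform = "log")
  expect_error(embed_samples(enc, wrong), "feature count")
})

test_that("concatenation preserves order and rejects misaligned samples", {
  a <- make_fm(matrix(1, 3, 2, dimnames = list(NULL, c("x1", "x2"))),
               modality = "embedding", transform = "log")
  b <- make_fm(matrix(2, 3, 3, dimnames = list(NULL, c("y1", "y2", "y3"))),
               modality = "embedding", transform = "log")
  fused <- concat_embeddings(list(a, b))
  expect_equal(length(fm_feature_ids(fused)), 5L)
  expect_equal(fm_modality(fused), "fused")
  expect_identical(fm_values(concat_embeddings(list(a)))[, c("x1", "x2")],
                   fm_values(a))

  shuffled <- feature_matrix(
    tibble::as_tibble(b)[c(2, 1, 3), ], modality = "embedding",
    transform = "log"
  )
  expect_error(concat_embeddings(list(a, shuffled)), "order")
})

test_that("softmax probabilities row-normalise for arbitrary inputs", {
  d <- tiny_model_data()
  enc <- train_encoder(d$m, d$labels, fast_cfg(epochs = 5))
  withr::with_seed(8, {
    X <- matrix(rnorm(40 * 20, sd = 10), 40, 20)
    probs <- predict(enc, make_fm(X, transform = "log"))
    sums <- rowSums(as.matrix(probs[paste0(".pred_", enc$classes)]))
    expect_true(all(abs(sums - 1) < 1e-6))
  })
})

test_that("fusion training leaves encoder weights untouched", {
  d <- tiny_model_data()
  mats <- list(taxonomic = d$m, genomic = d$m)
  cfgs <- list(
    taxonomic = fast_cfg(seed = 1), genomic = fast_cfg(seed = 2),
    fusion = fast_cfg(hidden = c(8, 4), seed = 3)
  )
  mm <- fit_multimodal(mats, d$labels, cfgs)
  before <- lapply(mm$encoders, function(e) e$params$W)
  fused <- concat_embeddings(lapply(mm$encoders, function(e) {
    embed_samples(e, d$m)
  }))
  train_fusion(fused, d$labels, fast_cfg(hidden = c(8, 4), seed = 99))
  after <- lapply(mm$encoders, function(e) e$params$W)
  expect_identical(before, after)
})

test_that("a memorising model predicts its own training labels", {
  d <- tiny_model_data(shift = 5)
  mats <- list(taxonomic = d$m)
  cfgs <- list(taxonomic = fast_cfg(epochs = 60),
               fusion = fast_cfg(hidden = c(8, 4)))
  mm <- fit_multimodal(mats, d$labels, cfgs)
  pred <- predict(mm, mats)
  expect_equal(as.character(pred$.pred_class), as.character(d$labels))
  expect_equal(nrow(pred), nrow(d$m))
})

test_that("compiled training reproduces one reference Adam step", {
  withr::with_seed(17, {
    X <- matrix(rnorm(8 * 6), 8, 6)
    labels <- factor(rep(c("a", "b"), 4))
    Y <- matrix(0, 8, 2)
    Y[cbind(1:8, as.integer(labels))] <- 1
  })
  seed <- 123L
  # full-batch, one epoch = exactly one Adam step
  fit <- micromodal:::mlp_train(X, Y, c(5, 3), epochs = 1, batch_size = 8,
                                learning_rate = 0.001, beta1 = 0.9,
                                beta2 = 0.999, seed = seed)
  ref <- withr::with_seed(seed, {
    params <- micromodal:::mlp_init(6, c(5, 3), 2)
    ord <- sample.int(8)  # same permutation draw as the training path
    g <- micromodal:::mlp_grad(params, X[ord, ], Y[ord, ])
    st <- micromodal:::adam_init(params)
    micromodal:::adam_step(params, g, st, 0.001, 0.9, 0.999)$params
  })
  for (l in 1:3) {
    expect_equal(fit$W[[l]], ref$W[[l]], tolerance = 1e-5)
    expect_equal(fit$b[[l]], ref$b[[l]], tolerance = 1e-5)
  }
})

test_that("the reference gradient matches finite differences", {
  withr::with_seed(29, {
    X <- matrix(rnorm(5 * 4), 5, 4)
    Y <- matrix(0, 5, 2)
    Y[cbind(1:5, sample(1:2, 5, TRUE))] <- 1
    params <- micromodal:::mlp_init(4, c(3), 2)
    g <- micromodal:::mlp_grad(params, X, Y)
    loss_at <- function(p) {
      fw <- micromodal:::mlp_forward(p, X)
      -mean(rowSums(Y * log(pmax(fw$probs, 1e-12))))
    }
    h <- 1e-6
    for (l in 1:2) {
      for (k in 1:3) {
        idx <- sample(length(params$W[[l]]), 1)
        p2 <- params
        p2$W[[l]][idx] <- p2$W[[l]][idx] + h
        num <- (loss_at(p2) - loss_at(params)) / h
        expect_equal(g$W[[l]][idx], num, tolerance = 1e-3)
      }
    }
  })
})
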