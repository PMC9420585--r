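test_that("model building is seeded and shape contracts hold", {
  cfg <- model_config(hidden_size = 8L, seed = 5L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)

  r <- generate_record("normal", noise = no_noise(), seed = 3)
  rec <- pulse_record(r$record$samples)
  out <- predict_segmenter(m1, rec)
  expect_identical(dim(out$probs), c(2160L, 3L))
  expect_length(out$classes, 2160L)
  expect_true(all(abs(rowSums(out$probs) - 1) < 1e-5))

  # length-agnostic: a 500-sample record yields a 500 x 3 output
  short <- pulse_record(r$record$samples[1:500])
  out5 <- predict_segmenter(m1, short)
  expect_identical(dim(out5$probs), c(500L, 3L))

  bad <- pulse_record(r$record$samples)
  bad$samples[7] <- NaN
  expect_error(predict_segmenter(m1, bad), "finite")
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(hidden_size = 3L, seed = 13L, dropout = 0)
  m <- build_model(cfg)
  set.seed(13)
  X <- matrix(rnorm(24), 12, 2)
  Y <- matrix(sample(0:2, 24, TRUE), 12, 2)
  r <- pulseseg:::cpp_bilstm_loss_grad(m$params, X, Y, matrix(0, 0, 0), TRUE)
  eps <- 1e-5
  set.seed(14)
  for (k in names(m$params)) {
    for (i in sample(length(m$params[[k]]), min(4, length(m$params[[k]])))) {
      up <- m$params; up[[k]][i] <- up[[k]][i] + eps
      dn <- m$params; dn[[k]][i] <- dn[[k]][i] - eps
      num <- (pulseseg:::cpp_bilstm_loss_grad(up, X, Y, matrix(0, 0, 0), FALSE)$loss -
                pulseseg:::cpp_bilstm_loss_grad(dn, X, Y, matrix(0, 0, 0), FALSE)$loss) /
        (2 * eps)
      expect_equal(r$grads[[k]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("a zero epoch budget returns the initial model untouched", {
  cfg <- model_config(hidden_size = 4L, max_epochs = 0L, seed = 2L)
  recs <- clean_records(3)
  fit <- train_segmenter(build_model(cfg), signals_of(recs), labels_of(recs),
                         signals_of(recs), labels_of(recs))
  expect_identical(fit$model$params, build_model(cfg)$params)
  expect_identical(nrow(fit$history), 0L)
})

test_that("training reduces the loss on a tiny noiseless set", {
  recs <- clean_records(5, seed0 = 300)
  sigs <- signals_of(recs); labs <- labels_of(recs)
  run <- function(ep) {
    cfg <- model_config(hidden_size = 16L, max_epochs = ep,
                        early_stop_patience = 100L, seed = 17L)
    train_segmenter(build_model(cfg), sigs, labs, sigs, labs)
  }
  f1 <- run(1L); f10 <- run(10L)
  expect_lt(f10$history$train_loss[10], f1$history$train_loss[1])
  # identical seeds give identical first epochs
  expect_equal(f1$history$train_loss[1], f10$history$train_loss[1],
               tolerance = 1e-12)
})

test_that("label/signal mismatches are rejected before training", {
  recs <- clean_records(3)
  labs <- labels_of(recs)
  labs[[2]] <- labs[[2]][-1]
  expect_error(
    train_segmenter(model_config(hidden_size = 4L), signals_of(recs), labs,
                    signals_of(recs), labels_of(recs)),
    "mismatch")
})

test_that("postprocessing removes islands and keeps clean sequences fixed", {
  clean <- c(rep(0L, 50), rep(1L, 250), rep(2L, 400), rep(1L, 250),
             rep(2L, 400), rep(0L, 50))
  expect_identical(postprocess_classes(clean, 720), clean)

  # a 5-sample spurious island inside a systolic run is absorbed
  dirty <- clean
  dirty[151:155] <- 2L
  expect_identical(postprocess_classes(dirty, 720), clean)

  expect_identical(postprocess_classes(integer(100), 720), integer(100))

  # same-phase runs split by background are bridged (alternation enforced)
  split_run <- c(rep(1L, 100), rep(0L, 60), rep(1L, 100), rep(2L, 200))
  out <- postprocess_classes(split_run, 720)
  runs <- rle(out[out != 0L])$values
  expect_identical(runs, c(1L, 2L))
})

test_that("checkpoints round-trip to bit-identical predictions", {
  recs <- clean_records(4, seed0 = 500)
  cfg <- model_config(hidden_size = 8L, max_epochs = 2L, seed = 23L)
  fit <- train_segmenter(build_model(cfg), signals_of(recs), labels_of(recs),
                         signals_of(recs), labels_of(recs))
  rec <- pulse_record(recs[[1]]$record$samples)
  before <- predict_segmenter(fit$model, rec)
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, tmp, preprocess_config())
  m2 <- load_checkpoint(tmp)
  after <- predict_segmenter(m2, rec)
  expect_identical(before$classes, after$classes)
  expect_identical(before$probs, after$probs)
  sidecar <- jsonlite::fromJSON(paste0(tmp, ".json"))
  expect_identical(sidecar$config$hidden_size, 8L)
  expect_identical(sidecar$preprocess$wavelet_name, "sym8")
})
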