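# Property predictor: architecture, determinism, dropout gating, gradients.

test_that("predictor widths trace the configured architecture", {
  expect_identical(predictor_architecture(predictor_config()),
                   c(8192L, 10240L, 10240L, 10240L, 1024L, 1L))
  expect_identical(predictor_architecture(predictor_config(rep_dim = 64L, output_dim = 3L)),
                   c(256L, 320L, 320L, 320L, 32L, 3L))
})

test_that("evaluation mode is deterministic; dropout is active only in training", {
  pp <- init_predictor(predictor_config(rep_dim = 32L, seed = 6L))
  set.seed(2)
  reps <- matrix(rnorm(4 * 32), 4, 32)
  p1 <- predict_property(pp, reps)
  p2 <- predict_property(pp, reps)
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(4L, 1L))
  # training-mode forwards differ because of the dropout mask
  fw <- function() {
    tape <- latentmol:::ad_tape()
    latentmol:::predictor_forward(pp, latentmol:::ad_const(tape, reps), tape,
                                  training = TRUE)$val
  }
  set.seed(10); a <- fw()
  set.seed(11); b <- fw()
  expect_false(isTRUE(all.equal(a, b)))
  # different representations map to different outputs
  expect_false(isTRUE(all.equal(predict_property(pp, reps[1, ]),
                                predict_property(pp, reps[2, ]))))
  expect_error(predict_property(pp, reps[, 1:8]), "ncol")
})

test_that("gradients w.r.t. the representation match closed forms and finite differences", {
  pp <- init_predictor(predictor_config(rep_dim = 16L, seed = 3L))
  set.seed(4)
  r <- rnorm(16)
  g0 <- gradient_wrt_representation(pp, r, function(pred, rep, tape) {
    latentmol:::ad_const(tape, matrix(5, 1, 1))      # constant objective
  })
  expect_true(all(g0 == 0))
  g1 <- gradient_wrt_representation(pp, r, function(pred, rep, tape) {
    latentmol:::v_sum(latentmol:::v_square(rep))     # bypasses the network
  })
  expect_equal(g1, 2 * r, tolerance = 1e-10)
  gn <- gradient_wrt_representation(pp, r, function(pred, rep, tape) {
    latentmol:::v_sum(pred)
  })
  f <- function(x) sum(predict_property(pp, x))
  h <- 1e-5
  num <- vapply(seq_along(r), function(i) {
    x1 <- r; x2 <- r; x1[i] <- x1[i] + h; x2[i] <- x2[i] - h
    (f(x1) - f(x2)) / (2 * h)
  }, numeric(1))
  denom <- pmax(abs(num), 1e-4)
  expect_lt(max(abs(gn - num) / denom), 1e-3)
})

test_that("projection-mode training improves held-out correlation on the mini fixture", {
  fx <- mini_fixture()
  enc <- init_encoder(encoder_config(rep_dim = 32L, seed = 11L))
  reps <- encode(enc, fx$molecules$smiles)
  labs <- fx$properties$label
  tri <- which(fx$molecules$split == "train")
  vi <- which(fx$molecules$split == "valid")
  pp <- init_predictor(predictor_config(rep_dim = 32L, seed = 4L))
  res <- train_predictor(pp, reps, labs, tri, vi,
                         schedule = schedule_config(base_lr = 1e-3, warmup_steps = 20,
                                                    cosine_period = 300),
                         steps = 200L, eval_every = 40L, patience = 30L,
                         batch_size = 16L, seed = 2L)
  expect_gt(res$best_metric, 0.3)
  expect_lt(tail(res$history$loss, 1), res$history$loss[1])
})

test_that("fine-tuning updates a clone and leaves the shared encoder untouched", {
  fx <- mini_fixture()
  enc <- init_encoder(encoder_config(rep_dim = 16L, seed = 8L))
  graphs <- featurize_molecules(fx$molecules$smiles)
  labs <- fx$properties$label
  tri <- which(fx$molecules$split == "train")
  vi <- which(fx$molecules$split == "valid")
  before <- lapply(latentmol:::collect_params(enc$params), function(p) p$val)
  pp <- init_predictor(predictor_config(rep_dim = 16L, seed = 5L))
  res <- train_predictor(pp, reps = NULL, labs, tri, vi,
                         schedule = schedule_config(base_lr = 1e-3, warmup_steps = 5,
                                                    cosine_period = 100),
                         steps = 12L, eval_every = 6L, patience = 50L,
                         encoder = enc, graphs = graphs, finetune = TRUE,
                         batch_size = 8L, seed = 3L)
  after <- lapply(latentmol:::collect_params(enc$params), function(p) p$val)
  for (k in seq_along(before)) expect_identical(after[[k]], before[[k]])
  # the returned clone did move
  clone_vals <- lapply(latentmol:::collect_params(res$encoder$params), function(p) p$val)
  moved <- any(vapply(seq_along(before), function(k) {
    !isTRUE(all.equal(clone_vals[[k]], before[[k]]))
  }, logical(1)))
  expect_true(moved)
})
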