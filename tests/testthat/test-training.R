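# Schedules, batch-size rule, split guard, checkpoint round-trips, and the
# two training loops at toy scale.

test_that("learning-rate schedule ramps, oscillates, and is junction-continuous", {
  cfg <- schedule_config()
  expect_equal(lr_at(0, cfg), 0.10 * cfg$base_lr)
  expect_equal(lr_at(cfg$warmup_steps, cfg), cfg$base_lr)
  trough <- cfg$warmup_steps + cfg$cosine_period / 2
  expect_equal(lr_at(trough, cfg), 0.50 * cfg$base_lr)
  # continuity at the warmup/cosine junction
  eps <- 1
  expect_lt(abs(lr_at(cfg$warmup_steps - eps, cfg) - lr_at(cfg$warmup_steps + eps, cfg)),
            1e-2 * cfg$base_lr)
  # full period returns to base
  expect_equal(lr_at(cfg$warmup_steps + cfg$cosine_period, cfg), cfg$base_lr)
})

test_that("batch size follows the dataset-size rule", {
  expect_identical(batch_size_rule(6000), 96L)
  expect_identical(batch_size_rule(5001), 96L)
  expect_identical(batch_size_rule(5000), 64L)
  expect_identical(batch_size_rule(2000), 64L)
  expect_identical(batch_size_rule(1001), 64L)
  expect_identical(batch_size_rule(1000), 48L)
  expect_identical(batch_size_rule(500), 48L)
  expect_error(batch_size_rule(0))
})

test_that("split guard rejects homologous splits and passes disjoint ones", {
  expect_error(split_guard("CCO", "CCO", "c1ccccc1"), "split error")
  rep_identical <- split_guard("CCO", "CCO", "c1ccccc1", assert = FALSE)
  expect_false(rep_identical$pass)
  expect_identical(rep_identical$violations$smiles_a[1], "CCO")
  expect_error(split_guard("CCO", "CCN", character(0)), "non-empty")
  fx <- mini_fixture()
  sp <- split(fx$molecules$smiles, fx$molecules$split)
  rep_ok <- split_guard(sp$train, sp$valid, sp$test)
  expect_true(rep_ok$pass)
  expect_lt(rep_ok$max_similarity, 0.3)
})

test_that("checkpoints round-trip models, optimizer state and vocabulary", {
  dec <- tiny_decoder()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(dec, path, extra = list(step = 17L))
  ck <- load_checkpoint(path)
  expect_identical(ck$extra$step, 17L)
  expect_identical(ck$model$vocab$index, dec$vocab$index)
  set.seed(1); r <- rnorm(16)
  s <- tokenize_smiles("CCO", tiny_vocab())[[1]]
  expect_equal(teacher_forced_logits(ck$model, r, s),
               teacher_forced_logits(dec, r, s))
})

test_that("checkpointed training resumes bit-identically", {
  v <- tiny_vocab()
  smiles <- c("CCO", "CCN", "CCCO", "c1ccccc1")
  cfg <- decoder_config(vocab_size = vocab_size(v), model_dim = 32L, layers = 1L,
                        heads = 4L, rep_dim = 8L, max_len = 30L, seed = 6L)
  set.seed(2); reps <- matrix(rnorm(4 * 8), 4, 8)
  sched <- schedule_config(base_lr = 1e-3, warmup_steps = 5, cosine_period = 50)
  run <- function(model, epochs, seed) {
    train_reconstruction(model, reps, smiles, epochs = epochs, chunk = 4L,
                         schedule = sched, eval_every = 1000L, patience = 10L,
                         seed = seed)
  }
  m1 <- init_decoder(cfg, v)
  run(m1, 3L, seed = 9L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m1, path)
  run(m1, 2L, seed = 10L)
  after_direct <- latentmol:::decoder_snapshot(m1)
  m2 <- load_checkpoint(path)$model
  run(m2, 2L, seed = 10L)
  after_resumed <- latentmol:::decoder_snapshot(m2)
  for (k in seq_along(after_direct$params)) {
    expect_equal(after_resumed$params[[k]]$val, after_direct$params[[k]]$val,
                 tolerance = 1e-12)
  }
})

test_that("similarity training freezes graph parameters during the freeze window", {
  fx <- mini_fixture()
  enc <- init_encoder(encoder_config(rep_dim = 16L, seed = 21L))
  before <- lapply(latentmol:::collect_params(enc$params[c("atom_in", "contact", "gate_self")]),
                   function(p) p$val)
  res <- train_similarity(enc, fx$matrices$train, valid_matrix = NULL,
                          steps = 10L, block_q = 6L, block_r = 3L,
                          schedule = schedule_config(base_lr = 1e-3, warmup_steps = 2,
                                                     cosine_period = 50),
                          freeze_steps = 10L, eval_every = 5L, patience = 50L, seed = 3L)
  after <- lapply(latentmol:::collect_params(res$model$params[c("atom_in", "contact", "gate_self")]),
                  function(p) p$val)
  for (k in seq_along(before)) expect_identical(after[[k]], before[[k]])
})

test_that("similarity training reduces loss on the mini fixture", {
  fx <- mini_fixture()
  enc <- init_encoder(encoder_config(rep_dim = 24L, seed = 31L))
  res <- train_similarity(enc, fx$matrices$train, valid_matrix = NULL,
                          steps = 120L, block_q = 8L, block_r = 4L,
                          schedule = schedule_config(base_lr = 1e-3, warmup_steps = 10,
                                                     cosine_period = 200),
                          freeze_steps = 0L, eval_every = 20L, patience = 50L, seed = 13L)
  h <- res$history
  expect_gt(nrow(h), 2)
  expect_lt(tail(h$loss, 1), h$loss[1])
})

test_that("reconstruction training memorizes a toy corpus; shuffled pairing fails", {
  v <- tiny_vocab()
  smiles <- tiny_smiles()[1:6]
  cfg <- decoder_config(vocab_size = vocab_size(v), model_dim = 48L, layers = 2L,
                        heads = 4L, rep_dim = 24L, max_len = 40L, seed = 2L)
  set.seed(14); reps <- matrix(rnorm(6 * 24), 6, 24)
  sched <- schedule_config(base_lr = 2e-3, warmup_steps = 20, cosine_period = 200)
  dec <- init_decoder(cfg, v)
  res <- train_reconstruction(dec, reps, smiles, epochs = 70L, chunk = 6L,
                              schedule = sched, eval_every = 30L, patience = 100L,
                              seed = 3L)
  exact <- sum(vapply(1:6, function(i) {
    identical(decode_representation(res$model, reps[i, ], temperature = 0.01,
                                    seed = 5L)$smiles, smiles[i])
  }, logical(1)))
  expect_gte(exact, 5L)
  # epoch-over-epoch improvement on the fixture
  expect_lt(tail(res$history$eval_loss, 1), res$history$eval_loss[1])
  # negative control: train under a permuted representation/SMILES pairing,
  # then evaluate under the true pairing -- reconstruction must fail
  dec2 <- init_decoder(cfg, v)
  perm <- c(2, 3, 4, 5, 6, 1)
  res2 <- train_reconstruction(dec2, reps[perm, ], smiles, epochs = 70L, chunk = 6L,
                               schedule = sched, eval_every = 30L, patience = 100L,
                               seed = 3L)
  exact2 <- sum(vapply(1:6, function(i) {
    identical(decode_representation(res2$model, reps[i, ], temperature = 0.01,
                                    seed = 5L)$smiles, smiles[i])
  }, logical(1)))
  expect_lt(exact2, exact)
})
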