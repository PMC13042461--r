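# Transformer decoder: causality, weighted loss, Gumbel sampling,
# perturbation, decoding and reconstruction assessment.

test_that("teacher-forced logits are causal and depend on the memory", {
  dec <- tiny_decoder()
  v <- tiny_vocab()
  set.seed(8)
  rep1 <- rnorm(16); rep2 <- rnorm(16)
  seqs <- tokenize_smiles(c("CC(=O)O", "c1ccncc1", "CCCO"), v)
  for (s in seqs) {
    lg <- teacher_forced_logits(dec, rep1, s)
    expect_identical(dim(lg), c(length(s) - 1L, vocab_size(v)))
    # mutate token j: logits strictly before j unchanged
    for (j in c(3L, length(s) - 1L)) {
      s2 <- s
      s2[j] <- (s2[j] + 1L) %% vocab_size(v)
      lg2 <- teacher_forced_logits(dec, rep1, s2)
      expect_equal(lg2[seq_len(j - 1L), , drop = FALSE],
                   lg[seq_len(j - 1L), , drop = FALSE], tolerance = 1e-12)
      expect_false(isTRUE(all.equal(lg2[j, ], lg[j, ])))
    }
  }
  lg_a <- teacher_forced_logits(dec, rep1, seqs[[1]])
  lg_b <- teacher_forced_logits(dec, rep2, seqs[[1]])
  expect_false(isTRUE(all.equal(lg_a, lg_b)))     # memory conditioning matters
  long <- rep(2L, dec$config$max_len + 2L)
  expect_error(teacher_forced_logits(dec, rep1, c(1L, long)), "max_len")
})

test_that("token weights cap at 100 and reset to 1 for absent tokens", {
  expect_equal(token_weight(1, 1e6), 100)
  expect_equal(token_weight(0, 1e6), 1)
  expect_equal(token_weight(10, 50), 5)
})

test_that("weighted cross-entropy matches hand-computed values", {
  # uniform frequencies -> every weight = n/f = V equal, loss = mean CE * w
  set.seed(3)
  V <- 4L
  logits <- matrix(rnorm(4 * V), 4, V)
  targets <- c(1L, 2L, 3L, 1L)      # each frequency: 1 appears twice etc.
  got <- weighted_ce_loss(logits, targets)
  # independent arithmetic
  softmax_ce <- function(z, t) {
    p <- exp(z - max(z)); p <- p / sum(p); -log(p[t + 1L])
  }
  freq <- tabulate(targets + 1L, nbins = V)
  w <- ifelse(freq == 0, 1, pmin(4 / freq, 100))
  manual <- sum(vapply(1:4, function(i) softmax_ce(logits[i, ], targets[i]) * w[targets[i] + 1L],
                       numeric(1))) / 4
  expect_equal(got, manual, tolerance = 1e-12)
  # pad targets are excluded from count and loss
  logits2 <- rbind(logits, rnorm(V))
  targets2 <- c(targets, 0L)
  expect_equal(weighted_ce_loss(logits2, targets2), manual, tolerance = 1e-12)
  expect_error(weighted_ce_loss(logits[1, , drop = FALSE], 0L), "no valid")
})

test_that("uniform-frequency batch reduces to plain mean cross-entropy times vocab-count weight", {
  set.seed(9)
  V <- 5L
  logits <- matrix(rnorm(4 * V), 4, V)
  targets <- c(1L, 2L, 3L, 4L)  # all frequencies equal (1 each), weight = 4
  plain <- mean(vapply(1:4, function(i) {
    z <- logits[i, ]; p <- exp(z - max(z)); p <- p / sum(p); -log(p[targets[i] + 1L])
  }, numeric(1)))
  expect_equal(weighted_ce_loss(logits, targets), plain * 4, tolerance = 1e-12)
})

test_that("Gumbel sampling approaches argmax at low temperature and is shift invariant", {
  y <- c(0.3, 2.5, -1, 0.9)
  set.seed(1)
  draws <- replicate(200, gumbel_sample(y, temperature = 1e-4))
  expect_true(all(draws == 2L))
  set.seed(42); a <- replicate(50, gumbel_sample(y, 1))
  set.seed(42); b <- replicate(50, gumbel_sample(y + 7, 1))
  expect_identical(a, b)                    # softmax shift invariance
})

test_that("Gumbel empirical distribution tracks softmax(y/T)", {
  set.seed(11)
  y <- rnorm(4); temp <- 0.7
  n <- 2e4
  z <- y / temp
  p <- exp(z - max(z)); p <- p / sum(p)
  draws <- vapply(seq_len(n), function(i) gumbel_sample(y, temp), integer(1))
  emp <- tabulate(draws, nbins = 4) / n
  expect_lt(sum(abs(emp - p)) / 2, 0.02)    # total-variation distance
})

test_that("representation perturbation matches its contract", {
  set.seed(2)
  e <- rnorm(200)
  expect_identical(perturb_representation(e, 0), e)
  v <- perturb_representation(e, 0.1, seed = 3)
  frac <- mean(v != e)
  expect_gt(frac, 0.35); expect_lt(frac, 0.65)
  # per-coordinate variance of changed entries ~ N^2
  ch <- replicate(400, {
    vv <- perturb_representation(e, 0.1)
    d <- vv - e; d[d != 0][1]
  })
  expect_equal(var(ch), 0.01, tolerance = 0.25)
})

test_that("decoding stops at max_len, is seed-deterministic, flags validity", {
  dec <- tiny_decoder()
  set.seed(5)
  r <- rnorm(16)
  d1 <- decode_representation(dec, r, temperature = 1, max_len = 12, seed = 4)
  d2 <- decode_representation(dec, r, temperature = 1, max_len = 12, seed = 4)
  expect_identical(d1$smiles, d2$smiles)
  expect_lte(length(d1$ids), 12L)
  expect_type(d1$valid, "logical")
})

test_that("validity check accepts real molecules and rejects garbage", {
  expect_true(smiles_valid("CC(=O)Oc1ccccc1C(=O)O"))
  expect_true(smiles_valid("c1cc[nH]c1"))
  expect_false(smiles_valid(""))
  expect_false(smiles_valid("C(("))
  expect_false(smiles_valid("FF(F)F"))   # halogen over-valence
})

test_that("reconstruction similarity is 1 for identity, 0 for invalid, set arithmetic otherwise", {
  expect_equal(assess_reconstruction("CCO", "OCC"), 1)
  expect_equal(assess_reconstruction("CCO", "xyz"), 0)
  # ethanol vs ethylamine: brute-force atom-pair multiset Tanimoto
  sdf <- ChemmineR::smiles2sdf(c(a = "CCO", b = "CCN"))
  aps <- ChemmineR::ap(suppressWarnings(ChemmineR::sdf2ap(sdf)))
  a <- sort(as.numeric(aps[[1]])); b <- sort(as.numeric(aps[[2]]))
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  c0 <- if (length(common)) sum(pmin(ta[common], tb[common])) else 0
  manual <- c0 / (length(a) + length(b) - c0)
  expect_equal(assess_reconstruction("CCO", "CCN"), manual)
})
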