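# Graph encoder: equivalence with a dense loop-based oracle, pooling
# properties, projection-head contracts.

test_that("every encoder stage matches the dense oracle on small random graphs", {
  model <- init_encoder(encoder_config(rep_dim = 16L, mp_rounds = 2L, seed = 5L))
  for (s in 1:6) {
    g <- random_graph(n = sample(1:6, 1L), seed = 100L + s)
    oracle <- dense_encoder_oracle(model, g)
    batch <- latentmol:::batch_graphs(list(g))
    tape <- latentmol:::ad_tape()
    fw <- latentmol:::encoder_forward(model, batch, tape, training = FALSE)
    expect_lt(max(abs(fw$hf$val - oracle$hf)), 1e-8)
    expect_lt(max(abs(as.numeric(fw$attn$val) - oracle$weights)), 1e-8)
    expect_lt(max(abs(as.numeric(fw$rep$val) - oracle$rep)), 1e-8)
  }
})

test_that("atom embedding is the clamped input projection", {
  model <- init_encoder(encoder_config(rep_dim = 22L, seed = 1L))
  g <- featurize_molecule("CCO")
  # identity weights, zero bias, non-negative inputs -> identity map
  model$params$atom_in$W$val <- diag(22)
  model$params$atom_in$b$val <- matrix(0, 1, 22)
  expect_equal(embed_atoms(model, g), g$atom_features)
  # zero weights -> all-zero embeddings
  model$params$atom_in$W$val <- matrix(0, 22, 22)
  expect_true(all(embed_atoms(model, g) == 0))
})

test_that("message passing updates a 2-node path as computed by hand", {
  model <- init_encoder(encoder_config(rep_dim = 8L, mp_rounds = 1L, seed = 3L))
  g <- random_graph(2L, seed = 77L)
  oracle <- dense_encoder_oracle(model, g)
  got <- propagate_messages(model, g)
  # independent loop recomputation of one round
  p <- model$params
  lin <- function(l, x) sweep(x %*% l$W$val, 2L, as.numeric(l$b$val), "+")
  h0 <- pmax(lin(p$atom_in, g$atom_features), 0)
  e0 <- pmax(lin(p$bond_in, g$bond_features), 0)
  m1 <- pmax(lin(p$contact, cbind(h0[g$edges[, 1], ], e0)), 0)
  agg <- rbind(m1[2, ], m1[1, ])  # edge 1->2 lands on node 2, 2->1 on node 1
  h1 <- pmax(lin(p$aggregate, cbind(h0, agg)), 0)
  expect_equal(got$atoms, h1, tolerance = 1e-10)
  expect_equal(got$bonds, m1, tolerance = 1e-10)
})

test_that("gated readout zeroes isolated nodes and scales linearly in the self gate", {
  model <- init_encoder(encoder_config(rep_dim = 16L, seed = 9L))
  g1 <- suppressWarnings(featurize_molecule("C"))
  expect_true(all(gated_readout(model, g1) == 0))
  g2 <- featurize_molecule("CCO")
  base <- gated_readout(model, g2)
  model$params$gate_self$val <- 2 * model$params$gate_self$val
  expect_equal(gated_readout(model, g2), 2 * base, tolerance = 1e-12)
})

test_that("pooling weights are a probability vector; symmetric atoms share weight", {
  model <- tiny_encoder()
  for (smi in c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O")) {
    pw <- attention_pool(model, featurize_molecule(smi))
    expect_equal(sum(pw$weights), 1, tolerance = 1e-12)
    expect_true(all(pw$weights > 0))
  }
  benz <- attention_pool(model, featurize_molecule("c1ccccc1"))
  expect_equal(benz$weights, rep(1 / 6, 6), tolerance = 1e-10)  # identical atoms
  g1 <- suppressWarnings(featurize_molecule("C"))
  expect_equal(attention_pool(model, g1)$weights, 1)
})

test_that("encoding is deterministic and invariant to the input SMILES form", {
  model <- tiny_encoder()
  r1 <- encode(model, "CC(=O)Oc1ccccc1C(=O)O")
  r2 <- encode(model, "O=C(O)c1ccccc1OC(C)=O")  # same molecule, different writing
  expect_equal(unname(r1), unname(r2))
  expect_identical(ncol(r1), 32L)
  expect_true(all(is.finite(r1)))
  at <- attr(r1, "attention")
  expect_equal(sum(at[[1]]), 1, tolerance = 1e-12)
})

test_that("projection heads emit (0,1) values with 3 + 5 outputs", {
  model <- tiny_encoder()
  set.seed(4)
  eq <- matrix(rnorm(5 * 32), 5); er <- matrix(rnorm(5 * 32), 5)
  out <- project_pair(model, eq, er)
  expect_identical(dim(out), c(5L, 8L))
  expect_true(all(out > 0 & out < 1))
  expect_identical(colnames(out)[1:5], paste0("csps_", c("w1", "w2", "w3", "w4", "diff")))
  expect_identical(colnames(out)[6:8], c("ecfp4", "maccs", "atompairs"))
  # zeroed final layer -> sigmoid(0) = 0.5 everywhere
  z <- init_encoder(encoder_config(rep_dim = 32L, seed = 2L))
  z$params$head_fp$out$W$val[] <- 0
  z$params$head_fp$out$b$val[] <- 0
  out2 <- project_pair(z, eq, er)
  expect_true(all(out2[, 6:8] == 0.5))
  expect_error(project_pair(model, eq[, 1:10], er), "rep_dim|ncol")
})

test_that("architecture width traces match the configured defaults", {
  arch <- encoder_architecture(encoder_config())
  expect_identical(arch$attention_mlp, c(6144L, 1024L, 128L, 128L, 128L, 1L))
  expect_identical(arch$head_input, 24576L)
  expect_identical(arch$head_reduction, c(2048L, 512L, 512L, 512L))
  expect_identical(c(arch$fingerprint_out, arch$csps_out), c(3L, 5L))
})
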