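# Shared lazy fixtures; built once per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.cache[[name]])) .cache[[name]] <- build()
  .cache[[name]]
}

tiny_smiles <- function() {
  c("CCO", "CCN", "c1ccccc1", "c1ccncc1", "CC(=O)O", "CCCO",
    "CC(=O)Oc1ccccc1C(=O)O", "C1CCNCC1", "c1ccc(F)cc1", "OCCN")
}

tiny_vocab <- function() cached("vocab", function() build_vocabulary(tiny_smiles(), merge_budget = 6L))

tiny_encoder <- function() cached("encoder", function() init_encoder(encoder_config(rep_dim = 32L, seed = 11L)))

tiny_decoder <- function() cached("decoder", function() {
  v <- tiny_vocab()
  init_decoder(decoder_config(vocab_size = vocab_size(v), model_dim = 32L,
                              layers = 2L, heads = 4L, rep_dim = 16L,
                              max_len = 40L, seed = 2L), v)
})

tiny_library <- function() cached("library", function() sample_library(50L, seed = 3L))

mini_fixture <- function() cached("mini_fixture", function() {
  build_tiny_fixture(fixture_config(n_train = 24L, n_valid = 6L, n_test = 6L,
                                    n_ref = 4L, seed = 7L))
})

# Random abstract molecular graph (for architecture oracles): a connected
# graph on n atoms with random extra edges and random feature values.
random_graph <- function(n, seed) {
  set.seed(seed)
  edges <- NULL
  if (n > 1L) {
    for (v in 2:n) edges <- rbind(edges, c(sample.int(v - 1L, 1L), v))
    n_extra <- sample(0:2, 1L)
    for (k in seq_len(n_extra)) {
      uv <- sort(sample.int(n, 2L))
      edges <- rbind(edges, uv)
    }
    edges <- unique(edges)
  }
  m <- if (is.null(edges)) 0L else nrow(edges)
  af <- matrix(runif(n * 22), n, 22)
  bf1 <- matrix(runif(max(m, 0) * 4), max(m, 0), 4)
  structure(list(smiles = sprintf("random-%d", seed), n_atoms = n, n_bonds = m,
                 atom_features = af,
                 edges = if (m) rbind(edges, edges[, 2:1, drop = FALSE]) else matrix(0L, 0L, 2L),
                 bond_features = rbind(bf1, bf1)),
            class = "mol_graph")
}

# Dense, loop-based recomputation of the full encoder forward pass
# (atom embedding, message passing, gated readout, attention pooling) --
# independent of the autodiff path.
dense_encoder_oracle <- function(model, graph) {
  p <- model$params
  relu <- function(x) pmax(x, 0)
  sigm <- function(x) 1 / (1 + exp(-x))
  lin <- function(l, x) sweep(x %*% l$W$val, 2L, as.numeric(l$b$val), "+")
  n <- graph$n_atoms
  h <- relu(lin(p$atom_in, graph$atom_features))
  src <- graph$edges[, 1L]; dst <- graph$edges[, 2L]
  ne <- nrow(graph$edges)
  if (ne > 0L) {
    e <- relu(lin(p$bond_in, graph$bond_features))
    for (t in seq_len(model$config$mp_rounds)) {
      msg <- matrix(NA_real_, ne, ncol(e))
      for (k in seq_len(ne)) {
        msg[k, ] <- relu(as.numeric(lin(p$contact, matrix(c(h[src[k], ], e[k, ]), 1L))))
      }
      e <- msg
      hn <- matrix(NA_real_, n, ncol(h))
      for (v in seq_len(n)) {
        s <- rep(0, ncol(e))
        for (k in which(dst == v)) s <- s + e[k, ]
        hn[v, ] <- relu(as.numeric(lin(p$aggregate, matrix(c(h[v, ], s), 1L))))
      }
      h <- hn
    }
    hf <- matrix(NA_real_, n, ncol(h))
    for (v in seq_len(n)) {
      s <- rep(0, ncol(h))
      for (k in which(dst == v)) {
        s <- s + (e[k, ] %*% p$gate_bond$val) * (h[src[k], ] %*% p$gate_atom$val)
      }
      hf[v, ] <- (h[v, ] %*% p$gate_self$val) * s
    }
  } else {
    hf <- matrix(0, n, ncol(h))
  }
  # attention MLP (evaluation-mode batch norm)
  at <- p$attention
  x <- hf
  bn_eval <- function(bn, x) {
    xh <- sweep(sweep(x, 2L, bn$state$running_mean), 2L,
                sqrt(bn$state$running_var + 1e-5), "/")
    sweep(sweep(xh, 2L, as.numeric(bn$gamma$val), "*"), 2L, as.numeric(bn$beta$val), "+")
  }
  for (i in seq_along(at$layers)) {
    x <- lin(at$layers[[i]], x)
    if (i == 1L) x <- bn_eval(at$bn1, x)
    if (i == 2L) x <- bn_eval(at$bn2, x)
    x <- sigm(x)
  }
  a <- as.numeric(x)
  w <- exp(a - max(a)); w <- w / sum(w)
  rep_vec <- as.numeric(t(hf) %*% w)
  list(h0 = NULL, hf = hf, weights = w, rep = rep_vec)
}
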