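## Graph-neural encoder: Weisfeiler-Lehman style message passing over
## atom/bond features, a gated readout, global attention pooling into a 1D
## molecular representation, and the two similarity projection heads
## (fingerprint: 3 outputs, CSPS: 5 outputs).

#' Encoder configuration
#'
#' Full-scale defaults: 2048-dimensional representation, 4 message-passing
#' rounds, attention MLP widths 6144/1024/128/128/128/1.  All internal
#' widths scale proportionally with `rep_dim`, so a desk-scale profile is
#' obtained by lowering `rep_dim` alone.
#'
#' @param rep_dim representation length (>= 8).
#' @param mp_rounds message-passing rounds (>= 1).
#' @param expansion_factor projection-head rectifier expansion.
#' @param seed parameter-initialization seed.
#' @export
encoder_config <- function(rep_dim = 2048L, mp_rounds = 4L,
                           expansion_factor = 5L, seed = 1L) {
  stopifnot(rep_dim >= 8L, mp_rounds >= 1L)
  structure(list(rep_dim = as.integer(rep_dim), mp_rounds = as.integer(mp_rounds),
                 expansion_factor = as.integer(expansion_factor),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Architecture width traces for a configuration
#'
#' Returns the layer width sequences implied by a configuration: the
#' attention-pooling MLP, and the projection-head reduction stack from the
#' paired input down to each head's output.
#' @param cfg an [encoder_config()].
#' @export
encoder_architecture <- function(cfg) {
  d <- cfg$rep_dim
  list(attention_mlp = c(3L * d, d %/% 2L, rep(d %/% 16L, 3L), 1L),
       head_input = 2L * d * (1L + cfg$expansion_factor),
       head_reduction = c(d, rep(d %/% 4L, 3L)),
       fingerprint_out = 3L, csps_out = 5L)
}

#' Initialize an encoder
#'
#' Kaiming-uniform fan-in initialization for rectifier layers, Xavier for
#' sigmoid layers and the bias-free readout gates; seed-controlled.
#' @param cfg an [encoder_config()].
#' @return `mol_encoder` model object.
#' @export
init_encoder <- function(cfg = encoder_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  d <- cfg$rep_dim
  arch <- encoder_architecture(cfg)
  params <- list(
    atom_in = new_linear(ATOM_FEATURE_WIDTH, d, "kaiming", name = "atom_in"),
    bond_in = new_linear(BOND_FEATURE_WIDTH, d, "kaiming", name = "bond_in"),
    contact = new_linear(2L * d, d, "kaiming", name = "contact"),
    aggregate = new_linear(2L * d, d, "kaiming", name = "aggregate"),
    gate_self = new_param(init_xavier(d, d), "gate_self"),
    gate_bond = new_param(init_xavier(d, d), "gate_bond"),
    gate_atom = new_param(init_xavier(d, d), "gate_atom"),
    attention = init_attention_mlp(arch$attention_mlp, d),
    head_fp = init_projection_head(cfg, 3L, "fp"),
    head_csps = init_projection_head(cfg, 5L, "csps")
  )
  structure(list(config = cfg, params = params), class = "mol_encoder")
}

init_attention_mlp <- function(widths, d) {
  dims <- c(d, widths)
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    new_linear(dims[i], dims[i + 1L], "xavier", name = paste0("attn", i))
  })
  list(layers = layers,
       bn1 = new_batchnorm(dims[2L], "attn_bn1"),
       bn2 = new_batchnorm(dims[3L], "attn_bn2"))
}

init_projection_head <- function(cfg, n_out, name) {
  d <- cfg$rep_dim
  ex <- cfg$expansion_factor * d
  red <- encoder_architecture(cfg)$head_reduction
  inw <- 2L * d * (1L + cfg$expansion_factor)
  list(
    rectifier = new_linear(d, ex, "kaiming", name = paste0(name, "_rect")),
    rect_bn = new_batchnorm(ex, paste0(name, "_rect_bn")),
    red1 = new_linear(inw, red[1L], "kaiming", name = paste0(name, "_red1")),
    bn1 = new_batchnorm(red[1L], paste0(name, "_bn1")),
    red2 = new_linear(red[1L], red[2L], "kaiming", name = paste0(name, "_red2")),
    bn2 = new_batchnorm(red[2L], paste0(name, "_bn2")),
    red3 = new_linear(red[2L], red[3L], "kaiming", name = paste0(name, "_red3")),
    red4 = new_linear(red[3L], red[4L], "kaiming", name = paste0(name, "_red4")),
    out = new_linear(red[4L], n_out, "xavier", name = paste0(name, "_out"))
  )
}

## ---- graph batching --------------------------------------------------------

# Merge mol_graph objects into one disjoint-union batch.
batch_graphs <- function(graphs) {
  offs <- cumsum(c(0L, vapply(graphs, `[[`, integer(1), "n_atoms")))
  af <- do.call(rbind, lapply(graphs, `[[`, "atom_features"))
  bf <- do.call(rbind, lapply(graphs, `[[`, "bond_features"))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e) == 0L) return(matrix(0L, 0L, 2L))
    e + offs[i]
  }))
  mol <- rep(seq_along(graphs), vapply(graphs, `[[`, integer(1), "n_atoms"))
  list(af = af, bf = bf, src = edges[, 1L], dst = edges[, 2L], mol = mol,
       n_nodes = nrow(af), n_mols = length(graphs))
}

## ---- forward passes --------------------------------------------------------

# Full encoder forward on a tape; returns node/graph-level nodes.
encoder_forward <- function(model, batch, tape, training = FALSE) {
  p <- model$params
  af <- ad_const(tape, batch$af)
  h <- v_relu(ap_linear(tape, p$atom_in, af))                     # atom embedding
  has_edges <- length(batch$src) > 0L
  if (has_edges) {
    bf <- ad_const(tape, batch$bf)
    e <- v_relu(ap_linear(tape, p$bond_in, bf))                   # bond embedding
    for (t in seq_len(model$config$mp_rounds)) {
      msg <- v_relu(ap_linear(tape, p$contact, v_concat_cols(v_rows(h, batch$src), e)))
      e <- msg                                                    # bond update
      agg <- v_rowsum_by(e, batch$dst, batch$n_nodes)
      h <- v_relu(ap_linear(tape, p$aggregate, v_concat_cols(h, agg)))
    }
    gated <- v_mul(v_mm(e, use_param(tape, p$gate_bond)),
                   v_mm(v_rows(h, batch$src), use_param(tape, p$gate_atom)))
    hf <- v_mul(v_mm(h, use_param(tape, p$gate_self)),
                v_rowsum_by(gated, batch$dst, batch$n_nodes))
  } else {
    zero <- ad_const(tape, matrix(0, batch$n_nodes, model$config$rep_dim))
    hf <- v_mul(v_mm(h, use_param(tape, p$gate_self)), zero)
  }
  pool <- attention_pool_forward(model, hf, batch, tape, training)
  list(h0 = h, hf = hf, attn = pool$attn, rep = pool$rep)
}

attention_pool_forward <- function(model, hf, batch, tape, training) {
  at <- model$params$attention
  x <- hf
  nl <- length(at$layers)
  for (i in seq_len(nl)) {
    x <- ap_linear(tape, at$layers[[i]], x)
    if (i == 1L) x <- ap_batchnorm(tape, at$bn1, x, training)
    if (i == 2L) x <- ap_batchnorm(tape, at$bn2, x, training)
    x <- v_sigmoid(x)
  }
  w <- v_softmax_groups(x, batch$mol, batch$n_mols)
  rep <- v_rowsum_by(v_mul(hf, v_mm(w, ad_const(tape, matrix(1, 1L, ncol(hf$val))))),
                     batch$mol, batch$n_mols)
  list(attn = w, rep = rep)
}

# Projection head on paired representation rows.
head_forward <- function(head, eq, er, tape, training = FALSE) {
  expand <- function(x) {
    r <- ap_batchnorm(tape, head$rect_bn,
                      v_leakyrelu(ap_linear(tape, head$rectifier, x)), training)
    v_concat_cols(r, x)
  }
  z <- v_concat_cols(expand(eq), expand(er))
  z <- v_silu(ap_batchnorm(tape, head$bn1, ap_linear(tape, head$red1, z), training))
  z <- v_silu(ap_batchnorm(tape, head$bn2, ap_linear(tape, head$red2, z), training))
  z <- v_silu(ap_linear(tape, head$red3, z))
  z <- v_silu(ap_linear(tape, head$red4, z))
  v_sigmoid(ap_linear(tape, head$out, z))
}

## ---- user-facing operations ------------------------------------------------

#' Encode molecules into representation vectors
#'
#' Runs the full graph encoder in evaluation mode (batch normalization uses
#' running statistics, so the output is batch-independent and
#' deterministic).
#'
#' @param model `mol_encoder`.
#' @param x SMILES character vector or list of `mol_graph` objects.
#' @return numeric matrix n x rep_dim; attribute `"attention"` holds the
#'   per-atom pooling weights (list of vectors, each summing to 1).
#' @export
encode <- function(model, x) {
  graphs <- if (is.character(x)) featurize_molecules(x) else x
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  batch <- batch_graphs(graphs)
  tape <- ad_tape()
  fw <- encoder_forward(model, batch, tape, training = FALSE)
  reps <- fw$rep$val
  attn <- split(as.numeric(fw$attn$val), batch$mol)
  attr(reps, "attention") <- attn
  reps
}

#' Low-level encoder stages
#'
#' These expose the intermediate stages of the encoder on a single graph
#' for inspection and testing: `embed_atoms` (input projection + ReLU),
#' `propagate_messages` (bond/atom updates after the configured rounds),
#' `gated_readout` (bias-free gating), `attention_pool` (softmax-weighted
#' aggregation).
#'
#' @param model `mol_encoder`.
#' @param graph a `mol_graph`.
#' @return numeric matrices (per-node vectors), or for `attention_pool` a
#'   list with `rep` and `weights`.
#' @export
embed_atoms <- function(model, graph) {
  tape <- ad_tape()
  h <- v_relu(ap_linear(tape, model$params$atom_in, ad_const(tape, graph$atom_features)))
  h$val
}

#' @rdname embed_atoms
#' @export
propagate_messages <- function(model, graph) {
  batch <- batch_graphs(list(graph))
  tape <- ad_tape()
  p <- model$params
  h <- v_relu(ap_linear(tape, p$atom_in, ad_const(tape, batch$af)))
  if (length(batch$src) == 0L) return(list(atoms = h$val, bonds = matrix(0, 0, model$config$rep_dim)))
  e <- v_relu(ap_linear(tape, p$bond_in, ad_const(tape, batch$bf)))
  for (t in seq_len(model$config$mp_rounds)) {
    msg <- v_relu(ap_linear(tape, p$contact, v_concat_cols(v_rows(h, batch$src), e)))
    e <- msg
    agg <- v_rowsum_by(e, batch$dst, batch$n_nodes)
    h <- v_relu(ap_linear(tape, p$aggregate, v_concat_cols(h, agg)))
  }
  list(atoms = h$val, bonds = e$val)
}

#' @rdname embed_atoms
#' @export
gated_readout <- function(model, graph) {
  batch <- batch_graphs(list(graph))
  tape <- ad_tape()
  fw <- encoder_forward(model, batch, tape, training = FALSE)
  fw$hf$val
}

#' @rdname embed_atoms
#' @export
attention_pool <- function(model, graph) {
  batch <- batch_graphs(list(graph))
  if (batch$n_nodes < 1L) stop("empty graph cannot be pooled")
  tape <- ad_tape()
  fw <- encoder_forward(model, batch, tape, training = FALSE)
  list(rep = as.numeric(fw$rep$val), weights = as.numeric(fw$attn$val))
}

#' Predict the 8-component similarity record for representation pairs
#'
#' Applies both projection heads in evaluation mode.  Rows of `eq`/`er`
#' are paired positionally.
#'
#' @param model `mol_encoder`.
#' @param eq,er representation matrices (n x rep_dim) or single vectors.
#' @return n x 8 matrix, columns `csps_w1..csps_w4, csps_diff, ecfp4,
#'   maccs, atompairs`, all values in (0, 1).
#' @export
project_pair <- function(model, eq, er) {
  if (is.null(dim(eq))) eq <- matrix(eq, nrow = 1L)
  if (is.null(dim(er))) er <- matrix(er, nrow = 1L)
  stopifnot(ncol(eq) == model$config$rep_dim, ncol(er) == model$config$rep_dim,
            nrow(eq) == nrow(er))
  tape <- ad_tape()
  qn <- ad_const(tape, eq); rn <- ad_const(tape, er)
  fp <- head_forward(model$params$head_fp, qn, rn, tape, training = FALSE)
  cs <- head_forward(model$params$head_csps, qn, rn, tape, training = FALSE)
  out <- cbind(cs$val, fp$val)
  colnames(out) <- c("csps_w1", "csps_w2", "csps_w3", "csps_w4", "csps_diff",
                     "ecfp4", "maccs", "atompairs")
  out
}

#' @export
print.mol_encoder <- function(x, ...) {
  cat("mol_encoder: rep_dim", x$config$rep_dim, "-", x$config$mp_rounds,
      "message-passing rounds\n")
  invisible(x)
}
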