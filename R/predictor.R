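## Property predictor: an MLP with a sigmoid expansion, a residual
## double-linear block and staged reductions, mapping representation
## vectors to numeric molecular properties.  Projection mode trains the
## head on frozen representations; fine-tuning mode clones the encoder so
## the shared reconstruction-compatible encoder is never mutated.

#' Predictor configuration
#'
#' Full-scale widths for a 2048 representation: dropout(0.5) + expansion
#' to 8192 (sigmoid), concatenation with the input to 10240, two 10240
#' linears (LeakyReLU + batch norm) with a residual addition, reduction to
#' 1024, then the output dimension.  All widths scale with `rep_dim`.
#'
#' @param rep_dim representation length.
#' @param output_dim number of predicted properties (>= 1).
#' @param dropout input dropout rate.
#' @param seed initialization seed.
#' @export
predictor_config <- function(rep_dim = 2048L, output_dim = 1L, dropout = 0.5,
                             seed = 1L) {
  stopifnot(output_dim >= 1L)
  structure(list(rep_dim = as.integer(rep_dim), output_dim = as.integer(output_dim),
                 dropout = dropout, seed = as.integer(seed)),
            class = "predictor_config")
}

#' Width trace of the predictor architecture
#' @param cfg a [predictor_config()].
#' @return integer vector (expansion, concat, linear1, linear2, reduction,
#'   output).
#' @export
predictor_architecture <- function(cfg) {
  d <- cfg$rep_dim
  c(4L * d, 5L * d, 5L * d, 5L * d, d %/% 2L, cfg$output_dim)
}

#' Initialize a property predictor
#' @param cfg a [predictor_config()].
#' @export
init_predictor <- function(cfg = predictor_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  d <- cfg$rep_dim
  w <- predictor_architecture(cfg)
  params <- list(
    expand = new_linear(d, w[1L], "xavier", name = "pp_expand"),
    lin1 = new_linear(w[2L], w[3L], "kaiming", name = "pp_lin1"),
    bn1 = new_batchnorm(w[3L], "pp_bn1"),
    lin2 = new_linear(w[3L], w[4L], "kaiming", name = "pp_lin2"),
    lin3 = new_linear(w[4L], w[5L], "kaiming", name = "pp_lin3"),
    bn3 = new_batchnorm(w[5L], "pp_bn3"),
    bn4 = new_batchnorm(w[5L], "pp_bn4"),
    out = new_linear(w[5L], cfg$output_dim, "kaiming", name = "pp_out")
  )
  structure(list(config = cfg, params = params), class = "property_predictor")
}

predictor_forward <- function(model, rep_node, tape, training = FALSE) {
  p <- model$params
  rep_node <- apply_input_scaler(model$scaler, rep_node, tape)
  x <- v_dropout(rep_node, model$config$dropout, training)
  e <- v_sigmoid(ap_linear(tape, p$expand, x))
  z <- v_concat_cols(e, rep_node)
  h <- ap_batchnorm(tape, p$bn1, v_leakyrelu(ap_linear(tape, p$lin1, z)), training)
  h <- ap_linear(tape, p$lin2, h)
  r <- v_add(z, h)                                  # residual over the block
  r <- v_silu(ap_batchnorm(tape, p$bn3, ap_linear(tape, p$lin3, r), training))
  r <- v_silu(ap_batchnorm(tape, p$bn4, r, training))
  ap_linear(tape, p$out, r)   # SiLU precedes the final linear; output unbounded
}

#' Predict properties from representation vectors
#'
#' Evaluation-mode forward pass (dropout inactive, batch norm on running
#' statistics): deterministic and batch-independent.
#'
#' @param model `property_predictor`.
#' @param reps representation matrix (n x rep_dim) or single vector.
#' @return n x output_dim numeric matrix.
#' @export
predict_property <- function(model, reps) {
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1L)
  stopifnot(ncol(reps) == model$config$rep_dim)
  tape <- ad_tape()
  predictor_forward(model, ad_const(tape, reps), tape, training = FALSE)$val
}

#' Gradient of an objective with respect to a representation
#'
#' Builds the computation `objective(prediction, rep)` on a fresh tape and
#' backpropagates to the representation vector.  The `objective` callback
#' receives the prediction node, the representation node and the tape, and
#' must return a scalar node (use the `v_*` op helpers).
#'
#' @param model `property_predictor`.
#' @param rep representation vector.
#' @param objective function(pred_node, rep_node, tape) -> scalar node.
#' @return gradient vector of length rep_dim.
#' @export
gradient_wrt_representation <- function(model, rep, objective) {
  tape <- ad_tape()
  rep_node <- ad_node(tape, matrix(rep, nrow = 1L))
  pred <- predictor_forward(model, rep_node, tape, training = FALSE)
  loss <- objective(pred, rep_node, tape)
  ad_backward(loss)
  g <- rep_node$grad
  if (is.null(g)) g <- matrix(0, 1L, length(rep))
  if (any(!is.finite(g))) stop("optimization error: non-finite gradient")
  as.numeric(g)
}

#' Train a property predictor
#'
#' Projection mode (default) fits the head on frozen representations with
#' MSE loss, AdamW, the shared warmup/cosine schedule, the dataset-size
#' batch rule, and early stopping on validation Spearman.  Fine-tuning
#' mode additionally updates a *clone* of the supplied encoder (the
#' original is never mutated) and re-encodes each batch through it.
#'
#' @param model `property_predictor`.
#' @param reps n x rep_dim representations (projection mode input).
#' @param labels numeric vector or n x output_dim matrix.
#' @param train_idx,valid_idx row indices of the two splits.
#' @param schedule a [schedule_config()].
#' @param steps maximum steps.
#' @param eval_every,patience early-stopping cadence.
#' @param encoder optional `mol_encoder` for fine-tuning mode.
#' @param graphs `mol_graph` list (aligned with `labels`) for fine-tuning.
#' @param finetune enable fine-tuning mode.
#' @param batch_size override; defaults to [batch_size_rule()].
#' @param seed sampling seed.
#' @param verbose print progress.
#' @param log_file optional JSON-lines training log path.
#' @return list: `model`, `encoder` (clone if fine-tuned, else NULL),
#'   `history`, `best_metric`.
#' @export
train_predictor <- function(model, reps, labels, train_idx, valid_idx,
                            schedule = schedule_config(cosine_period = 1000L),
                            steps = 1000L, eval_every = 50L, patience = 60L,
                            encoder = NULL, graphs = NULL, finetune = FALSE,
                            batch_size = NULL, seed = 1L, verbose = FALSE,
                            log_file = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1L)
  if (finetune) {
    stopifnot(!is.null(encoder), !is.null(graphs))
    encoder <- clone_model(encoder)
  }
  if (is.null(batch_size)) batch_size <- batch_size_rule(length(train_idx))
  batch_size <- min(batch_size, length(train_idx))
  if (is.null(model$scaler)) {
    model$scaler <- if (finetune) {
      fit_input_scaler(encode(encoder, graphs[train_idx]))  # pre-training scale
    } else {
      fit_input_scaler(reps[train_idx, , drop = FALSE])
    }
  }
  best <- list(metric = -Inf, params = NULL, enc_params = NULL)
  hist <- list(); stall <- 0L
  for (step in seq_len(steps)) {
    bi <- sample(train_idx, batch_size)
    tape <- ad_tape()
    if (finetune) {
      batch <- batch_graphs(graphs[bi])
      fw <- encoder_forward(encoder, batch, tape, training = TRUE)
      rep_node <- fw$rep
    } else {
      rep_node <- ad_const(tape, reps[bi, , drop = FALSE])
    }
    pred <- predictor_forward(model, rep_node, tape, training = TRUE)
    loss <- v_mean(v_square(v_sub(pred, ad_const(tape, labels[bi, , drop = FALSE]))))
    if (!is.finite(loss$val[1L])) stop("divergence: non-finite predictor loss")
    ad_backward(loss)
    adamw_step(tape_param_grads(tape), lr = lr_at(step - 1L, schedule),
               weight_decay = schedule$weight_decay, t = step, grad_clip = 5)
    if (step %% eval_every == 0L) {
      vr <- if (finetune) encode(encoder, graphs[valid_idx]) else reps[valid_idx, , drop = FALSE]
      pv <- predict_property(model, vr)
      metric <- mean(vapply(seq_len(ncol(labels)), function(j) {
        if (sd(pv[, j]) == 0 || sd(labels[valid_idx, j]) == 0) return(0)
        cor(pv[, j], labels[valid_idx, j], method = "spearman")
      }, numeric(1)))
      hist[[length(hist) + 1L]] <- data.frame(step = step, loss = loss$val[1L],
                                              metric = metric)
      append_train_log(log_file, list(step = step, lr = lr_at(step - 1L, schedule),
                                      loss = loss$val[1L], metric = metric))
      if (verbose) message(sprintf("step %d loss %.4f spearman %.3f",
                                   step, loss$val[1L], metric))
      if (metric > best$metric) {
        best <- list(metric = metric, params = decoder_snapshot(model),
                     enc_params = if (finetune) snapshot_params(encoder) else NULL)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (!is.null(best$params)) decoder_restore(model, best$params)
  if (finetune && !is.null(best$enc_params)) restore_params(encoder, best$enc_params)
  list(model = model, encoder = if (finetune) encoder else NULL,
       history = do.call(rbind, hist), best_metric = best$metric)
}

#' @export
print.property_predictor <- function(x, ...) {
  cat("property_predictor: widths",
      paste(predictor_architecture(x$config), collapse = " -> "), "\n")
  invisible(x)
}
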