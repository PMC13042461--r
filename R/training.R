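## Training loops: similarity learning for the encoder + projection heads,
## teacher-forced reconstruction for the decoder, schedules, early stopping
## and checkpointing.

#' Learning-rate schedule configuration
#'
#' Warmup ramps linearly from 10% of the base rate to the base rate, then a
#' cosine oscillates between the base rate and 50% of it with the given
#' period (continuous at the junction).
#'
#' @param base_lr base learning rate.
#' @param weight_decay decoupled AdamW weight decay.
#' @param warmup_steps linear warmup length.
#' @param warmup_start_fraction starting fraction of `base_lr`.
#' @param cosine_min_fraction trough fraction of `base_lr`.
#' @param cosine_period full oscillation period in steps.
#' @export
schedule_config <- function(base_lr = 5e-5, weight_decay = 0.01,
                            warmup_steps = 10000L, warmup_start_fraction = 0.10,
                            cosine_min_fraction = 0.50, cosine_period = 10000L) {
  stopifnot(warmup_start_fraction > 0, warmup_start_fraction <= 1,
            cosine_min_fraction > 0, cosine_min_fraction <= 1, cosine_period >= 1)
  structure(list(base_lr = base_lr, weight_decay = weight_decay,
                 warmup_steps = as.integer(warmup_steps),
                 warmup_start_fraction = warmup_start_fraction,
                 cosine_min_fraction = cosine_min_fraction,
                 cosine_period = as.integer(cosine_period)),
            class = "schedule_config")
}

#' Learning rate at a step
#'
#' @param step 0-based training step.
#' @param cfg a [schedule_config()].
#' @export
lr_at <- function(step, cfg = schedule_config()) {
  stopifnot(step >= 0)
  base <- cfg$base_lr
  if (step < cfg$warmup_steps) {
    f <- cfg$warmup_start_fraction
    return(base * (f + (1 - f) * step / cfg$warmup_steps))
  }
  s <- step - cfg$warmup_steps
  lo <- base * cfg$cosine_min_fraction
  lo + (base - lo) * (1 + cos(2 * pi * s / cfg$cosine_period)) / 2
}

#' Batch size rule for property training
#'
#' 96 for training sets above 5000 samples, 64 for 1001..5000, 48 at or
#' below 1000.
#' @param n_train training-set size.
#' @export
batch_size_rule <- function(n_train) {
  stopifnot(n_train >= 1)
  if (n_train > 5000) 96L else if (n_train > 1000) 64L else 48L
}

#' Guard non-homologous data splits
#'
#' Checks that no cross-split molecule pair exceeds the ECFP4 Tanimoto
#' cutoff.
#'
#' @param train,valid,test character vectors of SMILES.
#' @param cutoff similarity cutoff (default 0.3).
#' @param assert error on violation (default TRUE).
#' @return invisibly, a report list: `pass`, `max_similarity`, `violations`
#'   (data.frame of offending pairs).
#' @export
split_guard <- function(train, valid, test, cutoff = 0.3, assert = TRUE) {
  if (length(train) == 0L || length(valid) == 0L || length(test) == 0L) {
    stop("configuration error: every split must be non-empty")
  }
  pairs <- list(c("train", "valid"), c("train", "test"), c("valid", "test"))
  sets <- list(train = train, valid = valid, test = test)
  viol <- NULL
  max_sim <- 0
  for (p in pairs) {
    ct <- ecfp4_cross_tanimoto(sets[[p[1]]], sets[[p[2]]])
    max_sim <- max(max_sim, ct)
    bad <- which(ct >= cutoff, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      viol <- rbind(viol, data.frame(
        split_a = p[1], split_b = p[2],
        smiles_a = sets[[p[1]]][bad[, 1]], smiles_b = sets[[p[2]]][bad[, 2]],
        tanimoto = ct[bad], stringsAsFactors = FALSE))
    }
  }
  report <- list(pass = is.null(viol), max_similarity = max_sim,
                 violations = if (is.null(viol)) data.frame() else viol)
  if (assert && !report$pass) {
    stop("split error: ", nrow(report$violations),
         " cross-split pair(s) at or above Tanimoto ", cutoff, "; worst ",
         signif(report$max_similarity, 3))
  }
  invisible(report)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint stores the model (configuration, vocabulary where present,
#' parameter tensors and batch-norm running statistics, and AdamW optimizer
#' state) plus the training step, so that training resumes bit-identically.
#'
#' @param model a `mol_encoder`, `smiles_decoder` or `property_predictor`
#'   (optionally wrapped in a training result).
#' @param path file path.
#' @param extra optional list stored alongside (e.g. step, metric history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(format = "latentmol-checkpoint-1", model = model, extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "latentmol-checkpoint-1")) stop("unrecognized checkpoint")
  ck
}

# Deep-copy all parameter stores of a model (values + optimizer state).
clone_model <- function(model) {
  copy_env <- function(x) {
    if (is.environment(x)) {
      e <- new.env(parent = emptyenv())
      for (nm in ls(x, all.names = TRUE)) assign(nm, get(nm, envir = x), envir = e)
      e
    } else if (is.list(x)) {
      out <- lapply(x, copy_env)
      attributes(out) <- attributes(x)
      out
    } else x
  }
  copy_env(model)
}

graph_param_names <- c("atom_in", "bond_in", "contact", "aggregate",
                       "gate_self", "gate_bond", "gate_atom")

# One JSON object per line; the structured training log.
append_train_log <- function(log_file, rec) {
  if (is.null(log_file)) return(invisible(NULL))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), "\n",
      file = log_file, append = TRUE, sep = "")
}

## ---- similarity learning ---------------------------------------------------

#' Pre-train the encoder by similarity projection
#'
#' Each step samples a query x reference block from the similarity matrix,
#' encodes the block's molecules, projects every pair through both heads,
#' and minimizes the mean squared error against the 8-component labels.
#' Graph-network parameters stay frozen for the first `freeze_steps`.
#' Validation (mean per-component Spearman of the predicted vs actual
#' labels) runs every `eval_every` steps with early stopping after
#' `patience` evaluations without improvement; the best-validation
#' parameters are restored before returning.
#'
#' @param model `mol_encoder`.
#' @param train_matrix,valid_matrix `similarity_matrix` objects sharing the
#'   reference set.
#' @param steps maximum optimization steps.
#' @param block_q,block_r sampled block size (full-scale 512 x 48;
#'   desk-scale default 16 x 8).
#' @param schedule a [schedule_config()].
#' @param freeze_steps graph-parameter freeze window.
#' @param eval_every,patience early-stopping cadence.
#' @param seed sampling seed.
#' @param verbose print progress.
#' @param log_file optional path receiving one JSON line per evaluation
#'   (step, lr, loss, metric).
#' @return list: `model` (best), `history` (data.frame), `best_metric`,
#'   `steps_run`.
#' @export
train_similarity <- function(model, train_matrix, valid_matrix = NULL,
                             steps = 2000L, block_q = 16L, block_r = 8L,
                             schedule = schedule_config(),
                             freeze_steps = 2000L, eval_every = 200L,
                             patience = 60L, seed = 1L, verbose = FALSE,
                             log_file = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  q_graphs <- featurize_molecules(train_matrix$queries)
  r_graphs <- featurize_molecules(train_matrix$refs)
  nq <- length(q_graphs); nr <- length(r_graphs)
  block_q <- min(block_q, nq); block_r <- min(block_r, nr)

  best <- list(metric = -Inf, params = NULL, step = 0L)
  hist <- list()
  stall <- 0L
  for (step in seq_len(steps)) {
    qi <- sample.int(nq, block_q)
    ri <- sample.int(nr, block_r)
    graphs <- c(q_graphs[qi], r_graphs[ri])
    batch <- batch_graphs(graphs)
    tape <- ad_tape()
    fw <- encoder_forward(model, batch, tape, training = TRUE)
    pair_q <- rep(seq_len(block_q), each = block_r)
    pair_r <- block_q + rep(seq_len(block_r), block_q)
    eq <- v_rows(fw$rep, pair_q)
    er <- v_rows(fw$rep, pair_r)
    pred_cs <- head_forward(model$params$head_csps, eq, er, tape, training = TRUE)
    pred_fp <- head_forward(model$params$head_fp, eq, er, tape, training = TRUE)
    lab <- train_matrix$labels[qi, ri, , drop = FALSE]
    lab_flat <- matrix(NA_real_, block_q * block_r, 8L)
    for (c0 in 1:8) lab_flat[, c0] <- as.numeric(t(lab[, , c0]))
    pred <- v_concat_cols(pred_cs, pred_fp)
    loss <- v_mean(v_square(v_sub(pred, ad_const(tape, lab_flat))))
    if (!is.finite(loss$val[1L])) stop("divergence: non-finite similarity loss at step ", step)
    ad_backward(loss)
    pairs <- tape_param_grads(tape)
    if (step <= freeze_steps) {
      pairs <- Filter(function(pg) !pg$param$name %in%
                        c(graph_param_names, paste0(graph_param_names, ".W"),
                          paste0(graph_param_names, ".b")), pairs)
    }
    adamw_step(pairs, lr = lr_at(step - 1L, schedule),
               weight_decay = schedule$weight_decay, t = step, grad_clip = 5)

    if (step %% eval_every == 0L) {
      metric <- if (!is.null(valid_matrix)) {
        similarity_validation_metric(model, valid_matrix)
      } else -loss$val[1L]
      hist[[length(hist) + 1L]] <- data.frame(step = step, loss = loss$val[1L],
                                              metric = metric)
      append_train_log(log_file, list(step = step, lr = lr_at(step - 1L, schedule),
                                      loss = loss$val[1L], metric = metric))
      if (verbose) message(sprintf("step %d loss %.4f metric %.3f", step,
                                   loss$val[1L], metric))
      if (metric > best$metric) {
        best <- list(metric = metric, params = snapshot_params(model), step = step)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (!is.null(best$params)) restore_params(model, best$params)
  list(model = model, history = do.call(rbind, hist),
       best_metric = best$metric, steps_run = step)
}

# Mean per-component Spearman between projected and actual labels.
similarity_validation_metric <- function(model, mat) {
  pred <- predict_similarity_matrix(model, mat)
  comps <- dim(mat$labels)[3]
  rho <- vapply(seq_len(comps), function(c0) {
    x <- as.numeric(pred[, , c0]); y <- as.numeric(mat$labels[, , c0])
    if (sd(y) == 0 || sd(x) == 0) return(0)
    cor(x, y, method = "spearman")
  }, numeric(1))
  mean(rho)
}

#' Predict all labels of a similarity matrix with the current encoder
#'
#' @param model `mol_encoder`.
#' @param mat `similarity_matrix` (labels used only for shape).
#' @return Q x R x 8 array of head predictions (evaluation mode).
#' @export
predict_similarity_matrix <- function(model, mat) {
  reps_q <- encode(model, mat$queries)
  reps_r <- encode(model, mat$refs)
  nq <- nrow(reps_q); nr <- nrow(reps_r)
  pq <- rep(seq_len(nq), each = nr)
  pr <- rep(seq_len(nr), nq)
  out <- project_pair(model, reps_q[pq, , drop = FALSE], reps_r[pr, , drop = FALSE])
  arr <- array(NA_real_, c(nq, nr, 8L), dimnames = list(NULL, NULL, colnames(out)))
  for (c0 in 1:8) arr[, , c0] <- matrix(out[, c0], nq, nr, byrow = TRUE)
  arr
}

# Batch-norm running-statistic environments of a parameter structure.
collect_bn_states <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$running_mean)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_bn_states)))
  list()
}

# A best-validation snapshot must capture the batch-norm running
# statistics together with the parameters: restoring one without the
# other pairs weights with normalization constants they never saw.
snapshot_params <- function(model) {
  list(params = lapply(collect_params(model$params),
                       function(p) list(name = p$name, val = p$val)),
       bn = lapply(collect_bn_states(model$params),
                   function(st) list(mean = st$running_mean, var = st$running_var)))
}

restore_params <- function(model, snap) {
  ps <- collect_params(model$params)
  names(ps) <- vapply(ps, function(p) p$name, character(1))
  for (s in snap$params) ps[[s$name]]$val <- s$val
  sts <- collect_bn_states(model$params)
  stopifnot(length(sts) == length(snap$bn))
  for (k in seq_along(sts)) {
    sts[[k]]$running_mean <- snap$bn[[k]]$mean
    sts[[k]]$running_var <- snap$bn[[k]]$var
  }
  invisible(model)
}

## ---- reconstruction learning -----------------------------------------------

#' Train the decoder to reconstruct SMILES from fixed representations
#'
#' Teacher-forced training with the frequency-weighted cross-entropy loss;
#' the encoder is frozen (representations are precomputed inputs).  The
#' validation metric is the weighted loss on a held-out slice (or the
#' training slice when none is given); the best-validation parameters are
#' restored on return.
#'
#' @param model `smiles_decoder`.
#' @param reps n x rep_dim matrix of representations.
#' @param smiles character vector of n target SMILES.
#' @param epochs passes over the corpus.
#' @param chunk sequences per optimization step.
#' @param schedule a [schedule_config()] (reconstruction default period
#'   4000 at full scale).
#' @param eval_every evaluations cadence in steps; `patience` as in
#'   [train_similarity()].
#' @param valid_idx indices of `smiles` held out for validation (excluded
#'   from training batches).
#' @param seed shuffling seed.
#' @param verbose print progress.
#' @param log_file optional JSON-lines training log path.
#' @return list: `model`, `history`, `best_loss`, `steps_run`.
#' @export
train_reconstruction <- function(model, reps, smiles, epochs = 30L, chunk = 10L,
                                 schedule = schedule_config(cosine_period = 4000L),
                                 eval_every = 50L, patience = 60L,
                                 valid_idx = NULL, seed = 1L, verbose = FALSE,
                                 log_file = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seqs <- tokenize_smiles(smiles, model$vocab)
  too_long <- vapply(seqs, length, integer(1)) > model$config$max_len
  if (any(too_long)) {
    warning(sum(too_long), " molecule(s) exceed max_len and were dropped")
    seqs <- seqs[!too_long]; reps <- reps[!too_long, , drop = FALSE]
  }
  n <- length(seqs)
  train_set <- setdiff(seq_len(n), valid_idx)
  eval_set <- if (is.null(valid_idx)) train_set else valid_idx
  # standardize the incoming representation space once, from training data
  if (is.null(model$scaler)) {
    model$scaler <- fit_input_scaler(reps[train_set, , drop = FALSE])
  }

  best <- list(loss = Inf, params = NULL)
  hist <- list(); stall <- 0L; step <- 0L
  done <- FALSE
  for (ep in seq_len(epochs)) {
    idx <- sample(train_set)
    chunks <- split(idx, ceiling(seq_along(idx) / chunk))
    for (ch in chunks) {
      step <- step + 1L
      tape <- ad_tape()
      fw <- decoder_forward(model, reps[ch, , drop = FALSE], seqs[ch], tape,
                            training = TRUE)
      tv <- fw$targets
      valid <- tv != 0L
      n_total <- sum(valid)
      freq <- tabulate(tv[valid] + 1L, nbins = model$config$vocab_size)
      w <- token_weight(freq, n_total)
      loss <- v_scale(v_crossentropy_sum(fw$logits, tv + 1L, w[tv + 1L] * valid),
                      1 / n_total)
      if (!is.finite(loss$val[1L])) stop("divergence: non-finite reconstruction loss")
      ad_backward(loss)
      adamw_step(tape_param_grads(tape), lr = lr_at(step - 1L, schedule),
                 weight_decay = schedule$weight_decay, t = step, grad_clip = 5)
      if (step %% eval_every == 0L) {
        ev <- reconstruction_loss(model, reps[eval_set, , drop = FALSE], seqs[eval_set])
        hist[[length(hist) + 1L]] <- data.frame(step = step, epoch = ep,
                                                train_loss = loss$val[1L],
                                                eval_loss = ev)
        append_train_log(log_file, list(step = step, lr = lr_at(step - 1L, schedule),
                                        loss = loss$val[1L], metric = ev))
        if (verbose) message(sprintf("step %d eval loss %.4f", step, ev))
        if (ev < best$loss) {
          best <- list(loss = ev, params = decoder_snapshot(model)); stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) { done <- TRUE; break }
        }
      }
    }
    if (done) break
  }
  ev <- reconstruction_loss(model, reps[eval_set, , drop = FALSE], seqs[eval_set])
  if (ev < best$loss) best <- list(loss = ev, params = decoder_snapshot(model))
  if (!is.null(best$params)) decoder_restore(model, best$params)
  list(model = model, history = do.call(rbind, hist), best_loss = best$loss,
       steps_run = step)
}

#' Weighted reconstruction loss of a decoder on a corpus (no training)
#' @param model `smiles_decoder`.
#' @param reps representation matrix.
#' @param seqs list of token sequences (as from [tokenize_smiles()]).
#' @export
reconstruction_loss <- function(model, reps, seqs) {
  tape <- ad_tape()
  fw <- decoder_forward(model, reps, seqs, tape, training = FALSE)
  weighted_ce_loss(fw$logits$val, fw$targets)
}

decoder_snapshot <- snapshot_params
decoder_restore <- restore_params
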