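## Autoregressive Transformer reconstruction of SMILES from representation
## vectors.  The 1D representation, projected to model width, serves as a
## single-position cross-attention memory: with one key the attention
## softmax is identically 1, so the cross-attention block reduces exactly
## to adding the (value- and output-projected) memory at every position.
## Target embeddings carry rotary position encoding; self-attention is
## causally masked.

#' Decoder configuration
#'
#' Full-scale defaults: 4 layers, 32 heads, model width equal to the
#' 2048-dimensional representation, output MLP 4096 -> 1024 -> vocabulary.
#' The output-head widths scale with `model_dim` (2x and 1/2x).
#'
#' @param vocab_size token count of the attached vocabulary.
#' @param model_dim transformer width (heads must divide it).
#' @param layers decoder layers.
#' @param heads attention heads.
#' @param rep_dim incoming representation length (defaults to `model_dim`).
#' @param ffn_mult feed-forward hidden width multiplier.
#' @param max_len maximum token-sequence length.
#' @param temperature default sampling temperature.
#' @param seed initialization seed.
#' @export
decoder_config <- function(vocab_size, model_dim = 2048L, layers = 4L,
                           heads = 32L, rep_dim = model_dim, ffn_mult = 1L,
                           max_len = 128L, temperature = 1.0, seed = 1L) {
  stopifnot(model_dim %% heads == 0L, temperature > 0, vocab_size >= 4L)
  structure(list(vocab_size = as.integer(vocab_size),
                 model_dim = as.integer(model_dim), layers = as.integer(layers),
                 heads = as.integer(heads), rep_dim = as.integer(rep_dim),
                 ffn_mult = as.integer(ffn_mult), max_len = as.integer(max_len),
                 temperature = temperature, seed = as.integer(seed)),
            class = "decoder_config")
}

#' Initialize a SMILES decoder
#'
#' @param cfg a [decoder_config()].
#' @param vocab the `smiles_vocab` the decoder emits (persisted with every
#'   checkpoint).
#' @return `smiles_decoder` model object.
#' @export
init_decoder <- function(cfg, vocab) {
  stopifnot(cfg$vocab_size == vocab_size(vocab))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  d <- cfg$model_dim
  layers <- lapply(seq_len(cfg$layers), function(l) {
    nm <- function(s) paste0("dec", l, "_", s)
    list(wq = new_linear(d, d, "kaiming", name = nm("wq")),
         wk = new_linear(d, d, "kaiming", name = nm("wk")),
         wv = new_linear(d, d, "kaiming", name = nm("wv")),
         wo = new_linear(d, d, "kaiming", name = nm("wo")),
         ln1 = new_layernorm(d, nm("ln1")),
         cross_v = new_linear(d, d, "kaiming", name = nm("cv")),
         cross_o = new_linear(d, d, "kaiming", name = nm("co")),
         ln2 = new_layernorm(d, nm("ln2")),
         ff1 = new_linear(d, d * cfg$ffn_mult, "kaiming", name = nm("ff1")),
         ff2 = new_linear(d * cfg$ffn_mult, d, "kaiming", name = nm("ff2")),
         ln3 = new_layernorm(d, nm("ln3")))
  })
  params <- list(
    embed = new_param(init_xavier(cfg$vocab_size, d), "embed"),
    mem_proj = new_linear(cfg$rep_dim, d, "kaiming", name = "mem_proj"),
    layers = layers,
    head1 = new_linear(d, 2L * d, "kaiming", name = "head1"),
    head2 = new_linear(2L * d, max(4L, d %/% 2L), "kaiming", name = "head2"),
    head3 = new_linear(max(4L, d %/% 2L), cfg$vocab_size, "kaiming", name = "head3")
  )
  structure(list(config = cfg, vocab = vocab, params = params),
            class = "smiles_decoder")
}

#' @export
print.smiles_decoder <- function(x, ...) {
  cat("smiles_decoder:", x$config$layers, "layers,", x$config$heads,
      "heads, width", x$config$model_dim, ", vocab", x$config$vocab_size, "\n")
  invisible(x)
}

# Rotary cos/sin matrices for a vector of 0-based positions.
rotary_matrices <- function(pos, d) {
  half <- d %/% 2L
  theta <- 10000^(-(seq_len(half) - 1L) / half)
  ang <- outer(pos, theta)
  idx <- rep(seq_len(half), each = 2L)
  list(cos = cos(ang)[, idx, drop = FALSE], sin = sin(ang)[, idx, drop = FALSE])
}

# Batched teacher-forced forward pass.
# seqs: list of integer token vectors (0-based, start...end).  reps: matrix
# (n_seq x rep_dim).  Returns list(logits node, targets, seq_of_pos).
decoder_forward <- function(model, reps, seqs, tape, training = FALSE) {
  cfg <- model$config
  p <- model$params
  ins <- lapply(seqs, function(s) s[-length(s)])
  outs <- lapply(seqs, function(s) s[-1L])
  lens <- vapply(ins, length, integer(1))
  seq_of_pos <- rep(seq_along(seqs), lens)
  pos <- unlist(lapply(lens, function(L) seq_len(L) - 1L))
  tok <- unlist(ins)
  n <- length(tok)

  emb <- v_rows(use_param(tape, p$embed), tok + 1L)
  rot <- rotary_matrices(pos, cfg$model_dim)
  x <- v_rotary(emb, rot$cos, rot$sin)

  # block-diagonal causal mask
  same <- outer(seq_of_pos, seq_of_pos, "==")
  causal <- outer(pos, pos, ">=")
  mask <- ifelse(same & causal, 0, -1e30)

  mem <- ap_linear(tape, p$mem_proj,
                   apply_input_scaler(model$scaler, ad_const(tape, reps), tape))
  dh <- cfg$model_dim %/% cfg$heads
  for (layer in p$layers) {
    q <- ap_linear(tape, layer$wq, x)
    k <- ap_linear(tape, layer$wk, x)
    v <- ap_linear(tape, layer$wv, x)
    heads_out <- vector("list", cfg$heads)
    for (h in seq_len(cfg$heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      qh <- v_cols(q, cols); kh <- v_cols(k, cols); vh <- v_cols(v, cols)
      scores <- v_scale(v_mm(qh, v_transpose(kh)), 1 / sqrt(dh))
      att <- v_softmax_rows(scores, mask = mask)
      heads_out[[h]] <- v_mm(att, vh)
    }
    attn <- ap_linear(tape, layer$wo, do.call(v_concat_cols, heads_out))
    x <- ap_layernorm(tape, layer$ln1, v_add(x, attn))
    # single-position memory: softmax over one key is 1, so cross-attention
    # contributes the projected memory of the owning sequence at every position
    cross <- ap_linear(tape, layer$cross_o,
                       v_rows(ap_linear(tape, layer$cross_v, mem), seq_of_pos))
    x <- ap_layernorm(tape, layer$ln2, v_add(x, cross))
    ff <- ap_linear(tape, layer$ff2, v_silu(ap_linear(tape, layer$ff1, x)))
    x <- ap_layernorm(tape, layer$ln3, v_add(x, ff))
  }
  z <- v_silu(ap_linear(tape, p$head1, x))
  z <- v_silu(ap_linear(tape, p$head2, z))
  logits <- ap_linear(tape, p$head3, z)
  list(logits = logits, targets = unlist(outs), seq_of_pos = seq_of_pos, pos = pos)
}

#' Teacher-forced logits for one target sequence
#'
#' Position i of the output depends only on the representation and target
#' tokens before i (causal mask); the target embedding carries rotary
#' position encoding.
#'
#' @param model `smiles_decoder`.
#' @param rep representation vector (length `rep_dim`).
#' @param target integer token sequence (0-based indices, starting with the
#'   start token).
#' @return (length(target) - 1) x vocab_size logits matrix.
#' @export
teacher_forced_logits <- function(model, rep, target) {
  if (length(target) > model$config$max_len) stop("target exceeds max_len")
  if (target[1L] != 1L) stop("target must begin with the start token")
  tape <- ad_tape()
  fw <- decoder_forward(model, matrix(rep, nrow = 1L), list(as.integer(target)), tape)
  fw$logits$val
}

#' Eq. 8 token weight
#'
#' Weight of a token with batch frequency `freq` among `n_total` valid
#' tokens: `min(n_total / freq, 100)`; zero-frequency tokens get weight 1.
#'
#' @param freq token frequency (vectorized).
#' @param n_total total valid-token count in the batch.
#' @export
token_weight <- function(freq, n_total) {
  ifelse(freq == 0, 1, pmin(n_total / freq, 100))
}

#' Frequency-weighted cross-entropy reconstruction loss
#'
#' Tokens are weighted inversely to their batch frequency, capped at 100;
#' padding tokens (index 0) and the start-of-sequence token are excluded
#' from both the frequency count and the loss; the result is the weighted
#' token-loss sum divided by the number of valid tokens.
#'
#' @param logits n x vocab matrix of per-position logits.
#' @param targets integer vector (0-based token ids) of length n; the
#'   start token never appears here because targets are the teacher
#'   sequence shifted by one.
#' @return scalar loss.
#' @export
weighted_ce_loss <- function(logits, targets) {
  stopifnot(nrow(logits) == length(targets))
  valid <- targets != 0L
  if (!any(valid)) stop("no valid (non-padding) tokens in batch")
  n_total <- sum(valid)
  freq <- tabulate(targets[valid] + 1L, nbins = ncol(logits))
  w <- token_weight(freq, n_total)
  z <- logits[valid, , drop = FALSE]
  tv <- targets[valid]
  m <- apply(z, 1L, max)
  lse <- m + log(rowSums(exp(z - m)))
  ce <- lse - z[cbind(seq_len(nrow(z)), tv + 1L)]
  sum(ce * w[tv + 1L]) / n_total
}

#' Gumbel-max sampling from logits
#'
#' Adds Gumbel noise to the temperature-scaled log-probabilities and takes
#' the argmax; the sampled index follows `softmax(logits / temperature)`.
#'
#' @param logits numeric vector.
#' @param temperature positive temperature.
#' @param eps numerical floor inside the double logarithm.
#' @return sampled 1-based index into `logits`.
#' @export
gumbel_sample <- function(logits, temperature, eps = 1e-10) {
  stopifnot(temperature > 0)
  z <- logits / temperature
  logp <- z - (max(z) + log(sum(exp(z - max(z)))))
  u <- runif(length(logits))
  g <- -log(-log(u) + eps)
  which.max(logp + g)
}

#' Perturb a representation vector
#'
#' Adds scaled standard-Gaussian noise to a random subset of coordinates:
#' `v = E + N * n (.) m` with mask entries Bernoulli(mask_prob).
#'
#' @param rep representation vector.
#' @param noise_scale N >= 0.
#' @param mask_prob coordinate perturbation probability (default 0.5).
#' @param seed optional RNG seed.
#' @export
perturb_representation <- function(rep, noise_scale, mask_prob = 0.5, seed = NULL) {
  stopifnot(noise_scale >= 0, mask_prob >= 0, mask_prob <= 1)
  if (!is.null(seed)) { old <- .Random.seed_save(); on.exit(.Random.seed_restore(old)); set.seed(seed) }
  n <- rnorm(length(rep))
  m <- rbinom(length(rep), 1L, mask_prob)
  rep + noise_scale * n * m
}

#' Decode a representation vector into a SMILES string
#'
#' Autoregressive Gumbel-max sampling at the given temperature until the
#' end token or `max_len`.  The result is flagged valid when the toolkit
#' parses it and every atom's bond-order sum respects standard valence.
#'
#' @param model `smiles_decoder`.
#' @param rep representation vector.
#' @param temperature sampling temperature.
#' @param max_len maximum generated length.
#' @param seed optional RNG seed.
#' @return list with `smiles`, `valid` (logical), `ids` (token indices).
#' @export
decode_representation <- function(model, rep, temperature = model$config$temperature,
                                  max_len = model$config$max_len, seed = NULL) {
  if (!is.null(seed)) { old <- .Random.seed_save(); on.exit(.Random.seed_restore(old)); set.seed(seed) }
  cfg <- model$config
  ids <- 1L  # start token
  end_id <- model$vocab$index[[END_TOKEN]]
  repmat <- matrix(rep, nrow = 1L)
  for (step in seq_len(max_len - 1L)) {
    tape <- ad_tape()
    fw <- decoder_forward(model, repmat, list(c(ids, end_id)), tape)
    # the appended end token only pads the teacher sequence; logits at the
    # last input position depend on `ids` alone
    logit <- fw$logits$val[length(ids), ]
    nxt <- gumbel_sample(logit, temperature) - 1L
    ids <- c(ids, nxt)
    if (nxt == end_id) break
  }
  smi <- detokenize(ids, model$vocab)
  list(smiles = smi, valid = smiles_valid(smi), ids = ids)
}

#' Chemical validity of a SMILES string
#'
#' A string is valid when the toolkit sanitizes it and every atom's
#' bond-order sum stays within standard valence for its element and formal
#' charge.
#' @param smiles character scalar.
#' @export
smiles_valid <- function(smiles) {
  if (!nzchar(smiles)) return(FALSE)
  # syntax pre-checks the permissive parser would silently repair:
  # balanced branches and paired ring-closure digits (outside brackets)
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L; in_br <- FALSE; digits <- integer(0)
  for (ch in chars) {
    if (ch == "[") in_br <- TRUE
    else if (ch == "]") in_br <- FALSE
    else if (!in_br && ch == "(") depth <- depth + 1L
    else if (!in_br && ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
    else if (!in_br && grepl("[0-9]", ch)) digits <- c(digits, as.integer(ch))
  }
  if (depth != 0L || in_br) return(FALSE)
  if (length(digits) && any(table(digits) %% 2L != 0L)) return(FALSE)
  can <- tryCatch(suppressWarnings(canonicalize_smiles(smiles)),
                  error = function(e) NA_character_)
  if (is.na(can) || !nzchar(can)) return(FALSE)
  g <- tryCatch(suppressWarnings(featurize_molecule(can)), error = function(e) NULL)
  if (is.null(g)) return(FALSE)
  lex <- smiles_atoms(can)
  maxval <- c(C = 4, N = 3, O = 2, S = 6, P = 5, F = 1, Cl = 1, Br = 1, I = 1, B = 3)
  if (g$n_bonds > 0) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(setNames(can, "m"))),
                    error = function(e) NULL)
    if (is.null(sdf)) return(FALSE)
    bb <- ChemmineR::bondblock(sdf[[1]])
    if (is.null(dim(bb))) bb <- matrix(as.numeric(bb[1:3]), 1L, 3L)
    n <- nrow(lex)
    bb <- bb[bb[, 1] <= n & bb[, 2] <= n, , drop = FALSE]
    bsum <- numeric(n)
    for (k in seq_len(nrow(bb))) {
      ord <- bb[k, 3]
      if (lex$aromatic[bb[k, 1]] && lex$aromatic[bb[k, 2]]) ord <- 1.5
      bsum[bb[k, 1]] <- bsum[bb[k, 1]] + ord
      bsum[bb[k, 2]] <- bsum[bb[k, 2]] + ord
    }
    allowed <- maxval[lex$element]
    allowed[is.na(allowed)] <- 6
    allowed <- allowed + abs(lex$charge)
    # aromatic atoms are excluded: counting aromatic bonds as 1.5
    # over-counts heteroatoms that contribute a lone pair to the ring
    # (furan O, pyrrole N); their valence is already vetted by the
    # parser's kekulization
    check <- !lex$aromatic
    if (any(floor(bsum[check]) > allowed[check] + 0.5)) return(FALSE)
  }
  TRUE
}

#' Reconstruction similarity between two molecules
#'
#' AtomPairs fingerprint Tanimoto between the source molecule and a decoded
#' string; an unparseable decode scores 0.
#'
#' @param original,decoded SMILES strings.
#' @return similarity in [0, 1].
#' @export
assess_reconstruction <- function(original, decoded) {
  if (!smiles_valid(decoded)) return(0)
  fps <- mol_fingerprint_sets(canonicalize_smiles(c(original, decoded)))
  a <- fps$ap[[1]]; b <- fps$ap[[2]]
  if (length(a) == 0L && length(b) == 0L) return(1)
  c0 <- multiset_intersection(a, b)
  c0 / (length(a) + length(b) - c0)
}
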