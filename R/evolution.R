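## Representation-space applications: similarity screening with
## early-recognition metrics, stochastic propagation, directed migration,
## chemical fusion, and ligand efficiency.

cosine_matrix <- function(a, b) {
  an <- a / pmax(sqrt(rowSums(a^2)), 1e-12)
  bn <- b / pmax(sqrt(rowSums(b^2)), 1e-12)
  tcrossprod(an, bn)
}

#' Similarity screening of a representation library
#'
#' For every library molecule and every reference set, takes the maximum
#' cosine similarity over the set's references, zeroes scores below the
#' filter threshold, ranks by the sum over reference sets, and flags the
#' top fraction.
#'
#' @param library n x d representation matrix (rownames used as ids).
#' @param reference_sets a single reference matrix or a named list of them.
#' @param threshold post-filter cutoff (scores below it become 0).
#' @param top_frac flagged fraction of the ranked library (one per thousand by default).
#' @return `screening_result`: data.frame with per-set scores, filtered
#'   total, rank and `selected` flag, ordered by rank.
#' @export
screen_library <- function(library, reference_sets, threshold = 0.5,
                           top_frac = 0.001) {
  if (!is.list(reference_sets)) reference_sets <- list(set1 = reference_sets)
  if (any(vapply(reference_sets, nrow, integer(1)) == 0L)) {
    stop("configuration error: empty reference set")
  }
  n <- nrow(library)
  ids <- rownames(library)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  per_set <- vapply(reference_sets, function(refs) {
    stopifnot(ncol(refs) == ncol(library))
    raw <- apply(cosine_matrix(library, refs), 1L, max)
    ifelse(raw < threshold, 0, raw)
  }, numeric(n))
  per_set <- matrix(per_set, nrow = n,
                    dimnames = list(NULL, names(reference_sets)))
  total <- rowSums(per_set)
  rank_ord <- order(total, decreasing = TRUE)
  rk <- integer(n); rk[rank_ord] <- seq_len(n)
  n_top <- max(1L, ceiling(n * top_frac))
  out <- data.frame(id = ids, per_set, total = total, rank = rk,
                    selected = rk <= n_top, stringsAsFactors = FALSE)
  out <- out[rank_ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Early-recognition and ranking metrics
#'
#' `bedroc` is the Boltzmann-enhanced discrimination of ROC (Truchon-Bayly)
#' with exponent `alpha` (default 160.9, matching top-1-percent early recognition);
#' `auroc` the area under the ROC curve; `enrichment_factor` the ratio of
#' the active rate in the top `fraction` to the overall active rate.
#'
#' @param scores numeric scores, larger = earlier rank.
#' @param labels 0/1 (or logical) activity labels.
#' @param alpha BEDROC exponent.
#' @return numeric scalar in [0, 1] (`bedroc`, `auroc`) or >= 0.
#' @export
bedroc <- function(scores, labels, alpha = 160.9) {
  labels <- as.integer(as.logical(labels))
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("metric error: need at least one active and one inactive")
  }
  n <- length(labels)
  ra <- sum(labels) / n
  ranks <- rank(-scores, ties.method = "average")
  ri <- ranks[labels == 1L]
  rie_num <- sum(exp(-alpha * ri / n)) / sum(labels)
  rie_den <- (1 / n) * (1 - exp(-alpha)) / (exp(alpha / n) - 1)
  rie <- rie_num / rie_den
  rie * ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' @rdname bedroc
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("metric error: degenerate labels")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname bedroc
#' @param fraction top fraction for the enrichment factor.
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.01) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("metric error: degenerate labels")
  n <- length(labels)
  n_top <- max(1L, floor(n * fraction))
  top <- order(scores, decreasing = TRUE)[seq_len(n_top)]
  (sum(labels[top]) / n_top) / (sum(labels) / n)
}

#' Per-dimension standard deviation of a representation set
#'
#' Used to scale propagation noise to the occupied width of the
#' representation space (Eq.-style sigma scaling).
#'
#' @param reps n x d representation matrix.
#' @param ref_id identifier of the reference set, recorded for provenance.
#' @return `representation_statistics`: list with `sigma` (length d) and
#'   `ref_id`.
#' @export
representation_statistics <- function(reps, ref_id = "reference-library") {
  structure(list(sigma = apply(reps, 2L, sd), ref_id = ref_id),
            class = "representation_statistics")
}

new_trajectory <- function(header) {
  structure(list(header = header, steps = NULL, reps = NULL), class = "lm_trajectory")
}

trajectory_push <- function(tr, row, rep) {
  tr$steps <- rbind(tr$steps, row)
  tr$reps <- rbind(tr$reps, rep)
  tr
}

#' @export
print.lm_trajectory <- function(x, ...) {
  cat("trajectory:", x$header$mode, "-", nrow(x$steps), "steps\n")
  invisible(x)
}

#' Novel decoded structures along a trajectory
#'
#' De-duplicates valid decoded molecules by canonical SMILES, dropping the
#' start structure; the raw trajectory keeps every decode.
#' @param tr trajectory.
#' @param exclude SMILES to exclude (e.g. the start molecule).
#' @export
trajectory_novel <- function(tr, exclude = character(0)) {
  if (is.null(tr$steps) || !"smiles" %in% names(tr$steps)) return(character(0))
  sm <- tr$steps$smiles[tr$steps$valid %in% TRUE]
  sm <- unique(sm[nzchar(sm)])
  setdiff(sm, exclude)
}

maybe_decode <- function(decoder, rep, temperature) {
  if (is.null(decoder)) return(list(smiles = NA_character_, valid = NA))
  decode_representation(decoder, rep, temperature = temperature)
}

#' Stochastic propagation in representation space
#'
#' Random walk `E <- E + scale * n (.) sigma (.) m` (Gaussian noise scaled
#' by the per-dimension standard deviation of a reference representation
#' set, masked at half of coordinates), decoding the current point at each
#' step and accumulating novel valid structures.
#'
#' @param start representation vector.
#' @param stats [representation_statistics()] for the sigma scaling.
#' @param steps walk length (default 200).
#' @param scale noise scale (default 0.05).
#' @param mask_prob coordinate mask probability.
#' @param temperature decoding temperature (default 0.30).
#' @param decoder optional `smiles_decoder`; without it the walk is traced
#'   without decoding.
#' @param seed RNG seed.
#' @return `lm_trajectory` with per-step decoded SMILES, validity and
#'   cosine similarity to the start.
#' @export
stochastic_propagation <- function(start, stats, steps = 200L, scale = 0.05,
                                   mask_prob = 0.5, temperature = 0.30,
                                   decoder = NULL, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  e0 <- as.numeric(start)
  e <- e0
  tr <- new_trajectory(list(mode = "propagation", sigma_ref = stats$ref_id,
                            scale = scale, mask_prob = mask_prob,
                            temperature = temperature, seed = seed))
  for (s in seq_len(steps)) {
    e <- e + scale * rnorm(length(e)) * stats$sigma * rbinom(length(e), 1L, mask_prob)
    dec <- maybe_decode(decoder, e, temperature)
    tr <- trajectory_push(tr, data.frame(
      step = s, sim_start = as.numeric(cosine_matrix(matrix(e, 1), matrix(e0, 1))),
      smiles = dec$smiles, valid = dec$valid, stringsAsFactors = FALSE), e)
  }
  tr
}

#' Objective specification for directed migration
#'
#' @param mode `"migrate"` (property targets plus a 0.8 similarity anchor
#'   to the start), `"scaffold_hop"` (loss `1 - sim` to a target
#'   representation), or `"fuse"` (see [chemical_fusion()]).
#' @param targets named numeric property targets (migrate mode).
#' @param predictors list of `property_predictor`s aligned with `targets`.
#' @param target_rep target representation (scaffold_hop mode).
#' @param sim_anchor anchor value for the start-similarity loss.
#' @param scale_sim multiplier structure `count(J) * 0.2`; set
#'   `scale_applies_to_prop = TRUE` to scale the property loss too.
#' @param scale_applies_to_prop alternative precedence reading.
#' @export
objective_spec <- function(mode = c("migrate", "scaffold_hop"), targets = NULL,
                           predictors = NULL, target_rep = NULL,
                           sim_anchor = 0.8, scale_applies_to_prop = FALSE) {
  mode <- match.arg(mode)
  if (mode == "migrate" && (is.null(targets) || length(targets) == 0L)) {
    stop("migrate mode requires at least one property target")
  }
  if (mode == "scaffold_hop" && is.null(target_rep)) {
    stop("scaffold_hop mode requires a target representation")
  }
  structure(list(mode = mode, targets = targets, predictors = predictors,
                 target_rep = target_rep, sim_anchor = sim_anchor,
                 scale_applies_to_prop = scale_applies_to_prop),
            class = "objective_spec")
}

#' Similarity loss of directed migration
#'
#' `|sim_start - anchor|`: minimized when the representation keeps the
#' anchor similarity (0.8) to the start molecule.
#' @param sim_start similarity value(s).
#' @param anchor anchor (default 0.8).
#' @export
migration_similarity_loss <- function(sim_start, anchor = 0.8) {
  abs(sim_start - anchor)
}

#' Directed migration of a representation vector
#'
#' Gradient descent (AdamW) on the representation only, under
#' `L = count(J) * 0.2 * |sim_start - 0.8| + sum_j |c_j - f_j(E)|` in
#' migrate mode, or `L = 1 - sim_target` in scaffold-hop mode.  Predictors
#' are frozen; the current point is decoded each `decode_every` steps.
#'
#' @param start representation vector.
#' @param objective an [objective_spec()].
#' @param lr AdamW learning rate (default 2e-5).
#' @param steps optimization steps (default 600).
#' @param temperature decoding temperature (default 0.4).
#' @param decoder optional `smiles_decoder`.
#' @param decode_every decode cadence (steps).
#' @return `lm_trajectory`; `header$final_rep` holds the optimized vector.
#' @export
directed_migration <- function(start, objective, lr = 2e-5, steps = 600L,
                               temperature = 0.4, decoder = NULL,
                               decode_every = 25L) {
  e0 <- as.numeric(start)
  par <- new_param(matrix(e0, nrow = 1L), "rep")
  tr <- new_trajectory(list(mode = objective$mode, lr = lr,
                            temperature = temperature))
  for (s in seq_len(steps)) {
    tape <- ad_tape()
    rep_node <- use_param(tape, par)
    if (objective$mode == "migrate") {
      l_sim <- v_abs(v_sub(v_cosine(rep_node, ad_const(tape, matrix(e0, 1))),
                           ad_const(tape, matrix(objective$sim_anchor, 1, 1))))
      l_prop <- NULL
      for (j in seq_along(objective$targets)) {
        pj <- objective$predictors[[j]]
        # a predictor may be a trained property head or any differentiable
        # synthetic objective function(rep_node, tape) -> node
        pred <- if (is.function(pj)) pj(rep_node, tape)
                else predictor_forward(pj, rep_node, tape, training = FALSE)
        term <- v_sum(v_abs(v_sub(ad_const(tape, matrix(objective$targets[[j]], 1, 1)),
                                  pred)))
        l_prop <- if (is.null(l_prop)) term else v_add(l_prop, term)
      }
      cj <- length(objective$targets)
      if (objective$scale_applies_to_prop) {
        loss <- v_scale(v_add(l_sim, l_prop), cj * 0.2)
      } else {
        loss <- v_add(v_scale(l_sim, cj * 0.2), l_prop)
      }
      parts <- c(l_sim$val[1L], l_prop$val[1L])
    } else {
      sim_t <- v_cosine(rep_node, ad_const(tape, matrix(as.numeric(objective$target_rep), 1)))
      loss <- v_sub(ad_const(tape, matrix(1, 1, 1)), sim_t)
      parts <- c(NA_real_, NA_real_)
    }
    if (!is.finite(loss$val[1L])) stop("optimization error: non-finite migration loss")
    ad_backward(loss)
    adamw_step(list(list(param = par, grad = par_grad(tape, par))), lr = lr, t = s)
    dec <- if (s %% decode_every == 0L) maybe_decode(decoder, as.numeric(par$val), temperature)
           else list(smiles = NA_character_, valid = NA)
    tr <- trajectory_push(tr, data.frame(
      step = s, loss = loss$val[1L], l_sim = parts[1L], l_prop = parts[2L],
      smiles = dec$smiles, valid = dec$valid, stringsAsFactors = FALSE),
      as.numeric(par$val))
  }
  tr$header$final_rep <- as.numeric(par$val)
  tr
}

par_grad <- function(tape, par) {
  g <- NULL
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (identical(nd$param, par) && !is.null(nd$grad)) {
      g <- if (is.null(g)) nd$grad else g + nd$grad
    }
  }
  if (is.null(g)) par$val * 0 else g
}

#' Chemical fusion of reference representations
#'
#' Minimizes `min_r 1 / (1 + 10000^(sim(E_r, E) - 0.6))` with AdamW on the
#' representation, pulling the point toward its nearest reference (the
#' exponential is computed in log space; gradients flow through the argmin
#' branch).
#'
#' @param reference_reps matrix of reference representations (>= 2 rows).
#' @param start starting representation vector.
#' @param lr learning rate (default 3e-5).
#' @param steps optimization steps (default 1000).
#' @param temperature decoding temperature.
#' @param decoder optional decoder.
#' @param decode_every decode cadence.
#' @return `lm_trajectory` with per-step loss and nearest-reference index.
#' @export
chemical_fusion <- function(reference_reps, start, lr = 3e-5, steps = 1000L,
                            temperature = 0.4, decoder = NULL,
                            decode_every = 25L) {
  if (nrow(reference_reps) < 2L) stop("fusion requires at least two reference molecules")
  par <- new_param(matrix(as.numeric(start), nrow = 1L), "rep")
  tr <- new_trajectory(list(mode = "fuse", lr = lr, temperature = temperature))
  lnK <- log(10000)
  for (s in seq_len(steps)) {
    sims <- as.numeric(cosine_matrix(matrix(par$val, 1), reference_reps))
    terms <- 1 / (1 + exp(lnK * (sims - 0.6)))
    r_star <- which.min(terms)
    tape <- ad_tape()
    rep_node <- use_param(tape, par)
    sim_node <- v_cosine(rep_node,
                         ad_const(tape, reference_reps[r_star, , drop = FALSE]))
    # 1 / (1 + 10000^(sim - 0.6)) == sigmoid(-ln(10000) * (sim - 0.6))
    loss <- v_sigmoid(v_scale(v_sub(ad_const(tape, matrix(0.6, 1, 1)), sim_node), lnK))
    if (!is.finite(loss$val[1L])) stop("optimization error: non-finite fusion loss")
    ad_backward(loss)
    adamw_step(list(list(param = par, grad = par_grad(tape, par))), lr = lr, t = s)
    dec <- if (s %% decode_every == 0L) maybe_decode(decoder, as.numeric(par$val), temperature)
           else list(smiles = NA_character_, valid = NA)
    tr <- trajectory_push(tr, data.frame(
      step = s, loss = loss$val[1L], nearest_ref = r_star,
      smiles = dec$smiles, valid = dec$valid, stringsAsFactors = FALSE),
      as.numeric(par$val))
  }
  tr$header$final_rep <- as.numeric(par$val)
  tr
}

#' Ligand efficiency
#'
#' `LE = dG / (1 + ln(n_heavy))`: binding free energy normalized by a
#' logarithmic heavy-atom-count factor, penalizing oversized ligands.
#'
#' @param dG binding free energy (kcal/mol).
#' @param n_heavy heavy-atom count (>= 1).
#' @export
ligand_efficiency <- function(dG, n_heavy) {
  if (any(n_heavy < 1)) stop("domain error: n_heavy must be >= 1")
  dG / (1 + log(n_heavy))
}

#' Write a trajectory as JSON lines plus a novel-structure SMILES file
#'
#' @param tr trajectory.
#' @param path output path for the JSON-lines file; the deduplicated valid
#'   structures go to `paste0(path, ".smi")`.
#' @export
write_trajectory <- function(tr, path) {
  con <- file(path, "w")
  writeLines(jsonlite::toJSON(tr$header, auto_unbox = TRUE), con)
  if (!is.null(tr$steps)) {
    for (i in seq_len(nrow(tr$steps))) {
      writeLines(jsonlite::toJSON(as.list(tr$steps[i, ]), auto_unbox = TRUE), con)
    }
  }
  close(con)
  novel <- trajectory_novel(tr)
  if (length(novel)) writeLines(novel, paste0(path, ".smi"))
  invisible(path)
}
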