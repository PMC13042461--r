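## Deterministic fixture generation.
##
## Molecule libraries are assembled from a fragment grammar (ring cores,
## linkers, terminal substituents) rather than sampled as random strings, so
## every generated SMILES is valid by construction and the library carries a
## controllable amount of shared substructure -- enough spread for
## similarity learning, enough disjoint chemotypes for non-homologous
## splits.

FRAG_CORES <- list(
  list(plain = "c1ccccc1",  slot1 = "c1ccc(%s)cc1",  plain2 = "c2ccccc2",  slot2 = "c2ccc(%s)cc2"),
  list(plain = "c1ccncc1",  slot1 = "c1ccc(%s)nc1",  plain2 = "c2ccncc2",  slot2 = "c2ccc(%s)nc2"),
  list(plain = "c1ccoc1",   slot1 = "c1cc(%s)oc1",   plain2 = "c2ccoc2",   slot2 = "c2cc(%s)oc2"),
  list(plain = "c1ccsc1",   slot1 = "c1cc(%s)sc1",   plain2 = "c2ccsc2",   slot2 = "c2cc(%s)sc2"),
  list(plain = "c1cncnc1",  slot1 = "c1cnc(%s)nc1",  plain2 = "c2cncnc2",  slot2 = "c2cnc(%s)nc2"),
  list(plain = "C1CCCCC1",  slot1 = "C1CCC(%s)CC1",  plain2 = "C2CCCCC2",  slot2 = "C2CCC(%s)CC2"),
  list(plain = "C1CCNCC1",  slot1 = "C1CCN(%s)CC1",  plain2 = "C2CCNCC2",  slot2 = "C2CCN(%s)CC2"),
  list(plain = "C1CCOCC1",  slot1 = "C1CCOC(%s)C1",  plain2 = "C2CCOCC2",  slot2 = "C2CCOC(%s)C2"),
  list(plain = "c1cc[nH]c1", slot1 = "c1cc(%s)[nH]c1", plain2 = "c2cc[nH]c2", slot2 = "c2cc(%s)[nH]c2"),
  list(plain = "C1CCCC1",   slot1 = "C1CCC(%s)C1",   plain2 = "C2CCCC2",   slot2 = "C2CCC(%s)C2")
)

FRAG_SUBSTITUENTS <- c("F", "Cl", "Br", "C", "CC", "O", "OC", "N", "NC",
                       "C#N", "C(F)(F)F", "C(=O)O", "C(=O)N", "C(C)C", "CO", "CCO")

FRAG_LINKERS <- c("", "C", "CC", "CCC", "O", "N", "OC", "CN", "C(=O)",
                  "C(=O)N", "C=C", "S", "OCC")

#' Sample a synthetic molecule library
#'
#' Draws `n` unique, valid, canonical molecules from the fragment grammar
#' (single decorated cores and core-linker-core assemblies).  Deterministic
#' for a fixed seed.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param max_chars maximum SMILES length accepted at generation.
#' @return [parse_molecules()] data.frame of `n` canonical molecules.
#' @export
sample_library <- function(n, seed = 1L, max_chars = 120L) {
  stopifnot(n >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seen <- character(0)
  raw <- character(0)
  tries <- 0L
  max_tries <- 200L * n
  while (length(raw) < n && tries < max_tries) {
    tries <- tries + 1L
    s <- sample_grammar_smiles()
    if (nchar(s) > max_chars) next
    can <- tryCatch(canonicalize_smiles(s), error = function(e) NA_character_)
    if (is.na(can) || can %in% seen || !nzchar(can)) next
    seen <- c(seen, can)
    raw <- c(raw, can)
  }
  if (length(raw) < n) stop("fragment grammar exhausted before ", n, " unique molecules")
  parse_molecules(raw)
}

sample_grammar_smiles <- function() {
  core <- FRAG_CORES[[sample.int(length(FRAG_CORES), 1L)]]
  if (runif(1) < 0.45) {
    nsub <- sample(0:2, 1L, prob = c(0.2, 0.5, 0.3))
    if (nsub == 0L) return(core$plain)
    s1 <- sample(FRAG_SUBSTITUENTS, 1L)
    if (nsub == 1L) return(sprintf(core$slot1, s1))
    s2 <- sample(FRAG_SUBSTITUENTS, 1L)
    # second substituent rides on the first as a chain extension when the
    # core exposes a single slot
    return(sprintf(core$slot1, paste0(s1, if (s1 %in% c("C", "CC", "O", "N", "OC", "CO", "CCO", "NC")) s2 else "")))
  }
  core2 <- FRAG_CORES[[sample.int(length(FRAG_CORES), 1L)]]
  linker <- sample(FRAG_LINKERS, 1L)
  tail <- if (runif(1) < 0.35) sprintf(core2$slot2, sample(FRAG_SUBSTITUENTS, 1L)) else core2$plain2
  sprintf(core$slot1, paste0(linker, tail))
}

# save/restore global RNG state so generators are pure under `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## ---------------------------------------------------------------------------
## Synthetic property labels
## ---------------------------------------------------------------------------

PROPERTY_RULES <- list(
  heteroatom_count = function(lex, g) sum(!lex$element %in% c("C", "H")),
  heavy_atom_count = function(lex, g) nrow(lex),
  ring_count = function(lex, g) g$n_bonds - g$n_atoms + 1L,
  # composition score: weighted heteroatom / aromatic fractions and ring
  # density -- intensive quantities recoverable from attention-pooled
  # (convex-combination) graph representations
  composition_score = function(lex, g) {
    n <- nrow(lex)
    10 * sum(!lex$element %in% c("C", "H")) / n +
      5 * sum(lex$aromatic) / n -
      2 * (g$n_bonds - g$n_atoms + 1L) / n
  })

#' Deterministic synthetic molecular property
#'
#' Evaluates a registered descriptor rule on a molecule and adds optional
#' Gaussian noise.  At `noise_sd = 0` the label is exactly reproducible,
#' which the predictor parameter-recovery tests rely on.
#'
#' @param smiles SMILES string(s).
#' @param rule rule name; one of `heteroatom_count`, `heavy_atom_count`,
#'   `ring_count`, `composition_score`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed for the noise draw.
#' @return numeric labels.
#' @export
synthetic_property <- function(smiles, rule = "composition_score",
                               noise_sd = 0, seed = 1L) {
  fn <- PROPERTY_RULES[[rule]]
  if (is.null(fn)) stop("unknown property rule: ", rule)
  can <- canonicalize_smiles(smiles)
  graphs <- featurize_molecules(can)
  vals <- vapply(seq_along(can), function(i) {
    fn(smiles_atoms(can[i]), graphs[[i]])
  }, numeric(1))
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    vals <- vals + rnorm(length(vals), sd = noise_sd)
  }
  vals
}

## ---------------------------------------------------------------------------
## Fixture bundle
## ---------------------------------------------------------------------------

#' Fixture configuration
#'
#' Desk-scale defaults: 120 training, 16 validation, 16 test molecules and
#' 8 reference molecules drawn from the training set.
#' @param n_train,n_valid,n_test split sizes.
#' @param n_ref number of reference molecules (taken from the train split).
#' @param seed generator seed.
#' @param property_rule label rule for the property table.
#' @param noise_sd property noise.
#' @param guard_cutoff cross-split ECFP4 Tanimoto bound.
#' @param pool_factor candidate pool size multiplier.
#' @export
fixture_config <- function(n_train = 120L, n_valid = 16L, n_test = 16L,
                           n_ref = 8L, seed = 7L,
                           property_rule = "composition_score", noise_sd = 0,
                           guard_cutoff = 0.3, pool_factor = 6L) {
  cfg <- list(n_train = n_train, n_valid = n_valid, n_test = n_test,
              n_ref = n_ref, seed = seed, property_rule = property_rule,
              noise_sd = noise_sd, guard_cutoff = guard_cutoff,
              pool_factor = pool_factor)
  class(cfg) <- "fixture_config"
  cfg
}

# Tiny stable polynomial hash of an R object's serialization (provenance only).
provenance_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build the desk-scale fixture bundle
#'
#' Samples a library from the fragment grammar, assigns train/valid/test
#' splits so that every cross-split ECFP4 Tanimoto is below the guard
#' cutoff (non-homologous splits), computes the three query x reference
#' similarity matrices and the synthetic property table.
#'
#' @param cfg a [fixture_config()].
#' @param with_similarity compute the similarity matrices (the expensive
#'   part); set `FALSE` when only molecules and labels are needed.
#' @return `fixture_bundle`: list with `molecules` (data.frame incl. a
#'   `split` column), `refs`, `matrices` (train/valid/test
#'   `similarity_matrix` objects or NULL), `properties`, `config`, `hash`.
#' @export
build_tiny_fixture <- function(cfg = fixture_config(), with_similarity = TRUE) {
  n_total <- cfg$n_train + cfg$n_valid + cfg$n_test
  pool <- sample_library(n_total * cfg$pool_factor, seed = cfg$seed)
  fps <- mol_fingerprint_sets(pool$smiles)$ecfp
  n_pool <- nrow(pool)

  train_idx <- seq_len(cfg$n_train)
  rest <- setdiff(seq_len(n_pool), train_idx)
  chosen_vt <- integer(0)
  for (i in rest) {
    if (length(chosen_vt) >= cfg$n_valid + cfg$n_test) break
    ref_set <- c(train_idx, chosen_vt)
    sims <- vapply(ref_set, function(j) tanimoto_sets(fps[[i]], fps[[j]]), numeric(1))
    if (max(sims) < cfg$guard_cutoff) chosen_vt <- c(chosen_vt, i)
  }
  if (length(chosen_vt) < cfg$n_valid + cfg$n_test) {
    stop("generation error: pool too homologous for disjoint splits; ",
         "got ", length(chosen_vt), " of ", cfg$n_valid + cfg$n_test)
  }
  valid_idx <- chosen_vt[seq_len(cfg$n_valid)]
  test_idx <- chosen_vt[cfg$n_valid + seq_len(cfg$n_test)]

  mols <- pool[c(train_idx, valid_idx, test_idx), , drop = FALSE]
  mols$split <- rep(c("train", "valid", "test"),
                    c(cfg$n_train, cfg$n_valid, cfg$n_test))
  rownames(mols) <- NULL
  ref_pos <- unique(round(seq(1L, cfg$n_train, length.out = cfg$n_ref)))
  refs <- mols$smiles[ref_pos]

  matrices <- NULL
  if (with_similarity) {
    ens <- generate_conformer_ensembles(mols, seed = cfg$seed)
    if (any(vapply(ens, is.null, logical(1)))) {
      stop("generation error: conformer embedding failed inside fixture")
    }
    ens_ref <- ens[ref_pos]
    sub <- function(split) which(mols$split == split)
    matrices <- lapply(c(train = "train", valid = "valid", test = "test"), function(sp) {
      idx <- sub(sp)
      build_similarity_matrix(mols[idx, , drop = FALSE],
                              mols[ref_pos, , drop = FALSE],
                              seed = cfg$seed,
                              ensembles = c(ens[idx], ens_ref))
    })
  }

  properties <- data.frame(
    smiles = mols$smiles, split = mols$split,
    label = synthetic_property(mols$smiles, rule = cfg$property_rule,
                               noise_sd = cfg$noise_sd, seed = cfg$seed),
    stringsAsFactors = FALSE)

  structure(list(molecules = mols, refs = refs, matrices = matrices,
                 properties = properties, config = cfg,
                 hash = provenance_hash(list(cfg))),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("fixture_bundle:", nrow(x$molecules), "molecules (",
      paste(table(x$molecules$split)[c("train", "valid", "test")], collapse = "/"),
      "),", length(x$refs), "references, hash", x$hash, "\n")
  invisible(x)
}
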