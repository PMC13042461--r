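## Conformational-space pharmacophore similarity (CSPS).
##
## For a molecule pair, CSPS at window k is the maximum pharmacophore
## similarity over all conformer pairs drawn from the two window-k
## ensembles; a fifth component records the difference between the largest
## and smallest window, capturing flexibility gains.  The overlay scorer is
## a Gaussian-overlap similarity after principal-axes superposition that
## blends plain shape overlap with feature-typed overlap (donor, acceptor,
## aromatic, hydrophobe, positive, negative families).

PHARMACOPHORE_FAMILIES <- c("donor", "acceptor", "aromatic", "hydrophobe",
                            "positive", "negative")

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1,
                      Cl = 1, Br = 1, I = 1, B = 3)

#' Pharmacophore feature typing of heavy atoms
#'
#' Assigns each heavy atom to zero or more of six interaction families
#' using structural rules on the molecular graph: donors are N/O bearing at
#' least one hydrogen; acceptors are neutral or anionic N/O excluding
#' pyrrole-type NH; aromatic atoms carry the aromatic flag; hydrophobes are
#' aliphatic carbons without N/O neighbours plus halogens; charges follow
#' the formal charge sign.
#'
#' @param smiles a SMILES string.
#' @return logical matrix n_atoms x 6 (columns `donor`, `acceptor`,
#'   `aromatic`, `hydrophobe`, `positive`, `negative`).
#' @export
pharmacophore_types <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  g <- featurize_molecule(can)
  lex <- smiles_atoms(can)
  n <- nrow(lex)
  # bond-order sum per atom (aromatic bonds count 1.5)
  bsum <- numeric(n)
  if (g$n_bonds > 0) {
    e1 <- g$edges[seq_len(g$n_bonds), , drop = FALSE]
    sdf <- ChemmineR::smiles2sdf(setNames(can, "m"))
    bb <- ChemmineR::bondblock(sdf[[1]])
    if (is.null(dim(bb))) bb <- matrix(as.numeric(bb[1:3]), 1L, 3L)
    bb <- bb[bb[, 1] <= n & bb[, 2] <= n, , drop = FALSE]
    for (k in seq_len(nrow(bb))) {
      ord <- bb[k, 3]
      if (lex$aromatic[bb[k, 1]] && lex$aromatic[bb[k, 2]]) ord <- 1.5
      bsum[bb[k, 1]] <- bsum[bb[k, 1]] + ord
      bsum[bb[k, 2]] <- bsum[bb[k, 2]] + ord
    }
  }
  stdval <- STANDARD_VALENCE[lex$element]
  stdval[is.na(stdval)] <- 4
  h <- ifelse(is.na(lex$h_explicit),
              pmax(0, round(stdval + lex$charge - bsum)),
              lex$h_explicit)
  is_no <- lex$element %in% c("N", "O")
  types <- cbind(
    donor = is_no & h >= 1,
    acceptor = is_no & lex$charge <= 0 &
      !(lex$element == "N" & lex$aromatic & h >= 1),
    aromatic = lex$aromatic,
    hydrophobe = (lex$element == "C" & !lex$aromatic & neighbor_free_of(g, lex, c("N", "O"))) |
      lex$element %in% c("F", "Cl", "Br", "I"),
    positive = lex$charge > 0,
    negative = lex$charge < 0)
  rownames(types) <- lex$element
  types
}

# TRUE for atoms with no neighbour among `elems`.
neighbor_free_of <- function(g, lex, elems) {
  bad <- lex$element %in% elems
  out <- rep(TRUE, nrow(lex))
  if (nrow(g$edges) > 0) {
    hit <- g$edges[bad[g$edges[, 2]], 1]
    out[unique(hit)] <- FALSE
  }
  out
}

# Rotate coordinates into their principal axes (right-handed).
principal_frame <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  if (nrow(xc) == 1L) return(xc)
  s <- svd(xc, nu = 0)
  v <- s$v
  if (ncol(v) < 3L) v <- cbind(v, matrix(0, 3L, 3L - ncol(v)))[, 1:3]
  if (det(v) < 0) v[, 3] <- -v[, 3]
  xc %*% v
}

# Gaussian kernel overlap between two aligned point sets.
gauss_overlap <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sum(exp(-pmax(d2, 0) / (2 * sigma^2)))
}

# Pharmacophore overlay similarity for one conformer pair.
# coords: heavy-atom matrices; types: logical n x 6 family matrices.
conformer_overlap <- function(ca, ta, cb, tb, sigma = 1.5) {
  a <- principal_frame(ca)
  b <- principal_frame(cb)
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  vaa <- gauss_overlap(a, a, sigma)
  vbb <- gauss_overlap(b, b, sigma)
  faa <- feature_overlap(a, ta, a, ta, sigma)
  fbb <- feature_overlap(b, tb, b, tb, sigma)
  best <- 0
  for (fl in flips) {
    b2 <- b %*% fl
    vab <- gauss_overlap(a, b2, sigma)
    s_shape <- vab / (vaa + vbb - vab)
    if (faa + fbb > 0) {
      fab <- feature_overlap(a, ta, b2, tb, sigma)
      s_ph <- if (faa + fbb - fab > 0) fab / (faa + fbb - fab) else 1
    } else {
      s_ph <- s_shape
    }
    best <- max(best, 0.5 * s_shape + 0.5 * s_ph)
  }
  min(max(best, 0), 1)
}

feature_overlap <- function(a, ta, b, tb, sigma) {
  tot <- 0
  for (f in seq_len(ncol(ta))) {
    ia <- which(ta[, f]); ib <- which(tb[, f])
    if (length(ia) == 0L || length(ib) == 0L) next
    tot <- tot + gauss_overlap(a[ia, , drop = FALSE], b[ib, , drop = FALSE], sigma)
  }
  tot
}

#' CSPS vector for a molecule pair
#'
#' Component k (k = 1..4) is the maximum overlay similarity over all
#' conformer pairs within energy window k; component 5 is the difference
#' between the largest- and smallest-window values, clamped to [0, 1].
#' Window components are non-decreasing because the ensembles are nested.
#'
#' @param ens_a,ens_b `conformer_ensemble` objects
#'   (see [generate_conformer_ensembles()]).
#' @param sigma Gaussian overlay width in Angstrom.
#' @return numeric vector of 5 CSPS components in [0, 1].
#' @export
csps_vector <- function(ens_a, ens_b, sigma = 1.5) {
  if (is.null(ens_a) || is.null(ens_b)) stop("conformer ensemble unavailable")
  ta <- pharmacophore_types(ens_a$smiles)
  tb <- pharmacophore_types(ens_b$smiles)
  ia <- ens_a$window_members[[4L]]
  ib <- ens_b$window_members[[4L]]
  scores <- matrix(NA_real_, length(ia), length(ib))
  for (i in seq_along(ia)) for (j in seq_along(ib)) {
    scores[i, j] <- conformer_overlap(ens_a$coords[[ia[i]]], ta,
                                      ens_b$coords[[ib[j]]], tb, sigma)
  }
  comps <- vapply(1:4, function(k) {
    ra <- match(ens_a$window_members[[k]], ia)
    rb <- match(ens_b$window_members[[k]], ib)
    max(scores[ra, rb, drop = FALSE])
  }, numeric(1))
  c(comps, min(max(comps[4L] - comps[1L], 0), 1))
}

#' Build a query x reference similarity matrix
#'
#' Computes the full 8-component label grid (5 CSPS + 3 fingerprint
#' similarities) between every query and reference molecule.  Conformer
#' ensembles and fingerprints are computed once per distinct molecule.
#'
#' @param queries,refs SMILES vectors or [parse_molecules()] outputs.
#' @param seed provenance seed recorded with the matrix.
#' @param alpha,beta AtomPairs Tversky weights.
#' @param sigma overlay width (Angstrom).
#' @param max_conformers per-window conformer cap.
#' @param ensembles optional precomputed ensemble list for
#'   `c(queries, refs)` (in that order) to avoid recomputation.
#' @return `similarity_matrix`: list with `queries`, `refs` (canonical
#'   SMILES), `labels` (Q x R x 8 array, components `csps_w1..csps_w4`,
#'   `csps_diff`, `ecfp4`, `maccs`, `atompairs`), `seed`, `config`.
#' @export
build_similarity_matrix <- function(queries, refs, seed = 1L, alpha = 0.9,
                                    beta = 0.1, sigma = 1.5,
                                    max_conformers = 8L, ensembles = NULL) {
  if (is.character(queries)) queries <- parse_molecules(queries)
  if (is.character(refs)) refs <- parse_molecules(refs)
  nq <- nrow(queries); nr <- nrow(refs)
  if (nq < 1L || nr < 1L) stop("empty query or reference set")
  all_mols <- rbind(queries, refs)
  if (is.null(ensembles)) {
    ensembles <- generate_conformer_ensembles(all_mols, seed = seed,
                                              max_conformers = max_conformers)
  }
  fp <- fingerprint_similarity_array(queries$smiles, refs$smiles, alpha, beta)
  comp_names <- c("csps_w1", "csps_w2", "csps_w3", "csps_w4", "csps_diff",
                  "ecfp4", "maccs", "atompairs")
  labels <- array(NA_real_, c(nq, nr, 8L), dimnames = list(NULL, NULL, comp_names))
  types <- lapply(all_mols$smiles, pharmacophore_types)
  preps <- lapply(seq_along(ensembles), function(k) {
    if (is.null(ensembles[[k]])) return(NULL)
    prep_ensemble(ensembles[[k]], types[[k]], sigma)
  })
  for (i in seq_len(nq)) for (j in seq_len(nr)) {
    ea <- ensembles[[i]]; eb <- ensembles[[nq + j]]
    if (is.null(ea) || is.null(eb)) stop("missing conformer ensemble for a matrix cell")
    labels[i, j, 1:5] <- csps_pair_cached(ea, types[[i]], eb, types[[nq + j]], sigma,
                                          preps[[i]], preps[[nq + j]])
  }
  labels[, , 6:8] <- fp
  structure(list(queries = queries$smiles, refs = refs$smiles, labels = labels,
                 seed = seed,
                 config = list(alpha = alpha, beta = beta, sigma = sigma,
                               max_conformers = max_conformers)),
            class = "similarity_matrix")
}

# Precompute the per-conformer quantities the overlay reuses: the
# principal-axes frame, the shape self-overlap and the feature
# self-overlap.
prep_ensemble <- function(ens, types, sigma) {
  idx <- ens$window_members[[4L]]
  lapply(idx, function(i) {
    fr <- principal_frame(ens$coords[[i]])
    list(frame = fr,
         vself = gauss_overlap(fr, fr, sigma),
         fself = feature_overlap(fr, types, fr, types, sigma))
  })
}

# Overlay score from prepared conformers (same arithmetic as
# conformer_overlap, without recomputing frames and self-overlaps).
overlap_prepped <- function(pa, ta, pb, tb, sigma) {
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  best <- 0
  for (fl in flips) {
    b2 <- pb$frame %*% fl
    vab <- gauss_overlap(pa$frame, b2, sigma)
    s_shape <- vab / (pa$vself + pb$vself - vab)
    if (pa$fself + pb$fself > 0) {
      fab <- feature_overlap(pa$frame, ta, b2, tb, sigma)
      s_ph <- if (pa$fself + pb$fself - fab > 0) fab / (pa$fself + pb$fself - fab) else 1
    } else {
      s_ph <- s_shape
    }
    best <- max(best, 0.5 * s_shape + 0.5 * s_ph)
  }
  min(max(best, 0), 1)
}

# csps_vector with pre-computed pharmacophore typings and prepared frames.
csps_pair_cached <- function(ens_a, ta, ens_b, tb, sigma,
                             prep_a = prep_ensemble(ens_a, ta, sigma),
                             prep_b = prep_ensemble(ens_b, tb, sigma)) {
  ia <- ens_a$window_members[[4L]]
  ib <- ens_b$window_members[[4L]]
  scores <- matrix(NA_real_, length(ia), length(ib))
  for (i in seq_along(ia)) for (j in seq_along(ib)) {
    scores[i, j] <- overlap_prepped(prep_a[[i]], ta, prep_b[[j]], tb, sigma)
  }
  comps <- vapply(1:4, function(k) {
    ra <- match(ens_a$window_members[[k]], ia)
    rb <- match(ens_b$window_members[[k]], ib)
    max(scores[ra, rb, drop = FALSE])
  }, numeric(1))
  c(comps, min(max(comps[4L] - comps[1L], 0), 1))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix:", length(x$queries), "queries x", length(x$refs),
      "references x 8 components (seed", x$seed, ")\n")
  invisible(x)
}

#' Persist / load a similarity matrix
#'
#' The label grid is written as a flat little-endian double array with a
#' JSON sidecar holding shapes, molecule identities, seed and configuration.
#'
#' @param mat `similarity_matrix`.
#' @param dir output directory (created if missing).
#' @export
save_similarity_matrix <- function(mat, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- file(file.path(dir, "labels.bin"), "wb")
  writeBin(as.numeric(mat$labels), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(shape = dim(mat$labels), queries = mat$queries, refs = mat$refs,
         components = dimnames(mat$labels)[[3]], seed = mat$seed,
         config = mat$config),
    file.path(dir, "labels.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_similarity_matrix
#' @export
load_similarity_matrix <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "labels.json"), simplifyVector = TRUE)
  con <- file(file.path(dir, "labels.bin"), "rb")
  vals <- readBin(con, numeric(), n = prod(meta$shape), size = 8L, endian = "little")
  close(con)
  labels <- array(vals, dim = meta$shape,
                  dimnames = list(NULL, NULL, meta$components))
  structure(list(queries = meta$queries, refs = meta$refs, labels = labels,
                 seed = meta$seed, config = meta$config),
            class = "similarity_matrix")
}
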