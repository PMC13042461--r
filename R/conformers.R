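## Conformer ensembles within strain-energy windows.
##
## 3D embedding and conformer enumeration use seeded distance-geometry
## embedding (ETKDG) with MMFF94 minimization and strain energies, run
## through the bundled Python helper (inst/python/embed_conformers.py).
## Conformers are de-duplicated at a 0.5 A optimal-superposition RMSD
## cutoff.  Windows are nested by construction: a conformer enters window k
## when its strain energy relative to the minimum found is at most
## window_k.

ENERGY_WINDOW_FACTORS <- c(0.14806, 0.5060, 0.88836, 1.4806)  # kcal/mol per rotor

#' Strain-energy windows for a molecule
#'
#' The four windows are the rotatable-bond count multiplied by the scaling
#' factors 0.14806, 0.5060, 0.88836 and 1.4806 kcal/mol (near-lowest,
#' first-percentile, medium and mean ligand strain levels), with a floor for
#' rigid molecules so that every ensemble is non-empty.
#'
#' @param mol a row of [parse_molecules()] output, or an integer
#'   rotatable-bond count.
#' @param floor minimum window in kcal/mol (default 0.1).
#' @return numeric vector of 4 window energies (kcal/mol), non-decreasing.
#' @export
energy_windows <- function(mol, floor = 0.1) {
  rot <- if (is.numeric(mol)) mol else mol$rot_bonds
  stopifnot(length(rot) == 1L, rot >= 0)
  pmax(rot * ENERGY_WINDOW_FACTORS, floor)
}

# Path to the bundled conformer-embedding helper (works both from the
# installed package and from a source checkout).
conformer_helper_path <- function() {
  p <- system.file("python", "embed_conformers.py", package = "latentmol")
  if (nzchar(p)) return(p)
  if (file.exists("inst/python/embed_conformers.py")) return("inst/python/embed_conformers.py")
  stop("embed_conformers.py helper not found")
}

# Optimal-superposition RMSD between two conformers (Kabsch alignment):
# the proper rotation R maximizing tr(R' b' a) is U V' for svd(b'a) = USV',
# with the smallest singular direction flipped when det(UV') < 0.
kabsch_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  a <- sweep(a, 2L, colMeans(a)); b <- sweep(b, 2L, colMeans(b))
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diffs <- a - b %*% r
  sqrt(sum(diffs^2) / nrow(a))
}

#' De-duplicate conformers by pairwise RMSD
#'
#' Conformers are visited in increasing energy order; a conformer is kept
#' only if its optimal-superposition RMSD to every kept conformer is at
#' least `cutoff`.
#'
#' @param coords list of n x 3 coordinate matrices.
#' @param energies numeric strain energies, same length.
#' @param cutoff RMSD cutoff in Angstrom (default 0.5).
#' @return integer indices of retained conformers.
#' @export
dedup_conformers <- function(coords, energies, cutoff = 0.5) {
  ord <- order(energies)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (kabsch_rmsd(coords[[i]], coords[[j]]) < cutoff) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

#' Generate nested conformer ensembles for molecules
#'
#' For every molecule, embeds up to `budget` conformers with seeded
#' distance-geometry embedding, minimizes them with MMFF94, removes
#' redundant conformers at a 0.5 A RMSD cutoff, and assigns the survivors
#' to the four nested windows by strain energy relative to the minimum
#' found.  Deterministic for a fixed `seed`.
#'
#' @param mols output of [parse_molecules()] (or character SMILES vector).
#' @param seed integer seed for the embedding.
#' @param budget conformer embeddings attempted per molecule.
#' @param max_conformers retained conformers per window cap (lowest-energy
#'   first); desk-scale compute bound.
#' @param floor rigid-molecule window floor, kcal/mol.
#' @param rmsd_cutoff de-duplication cutoff in Angstrom.
#' @return list of `conformer_ensemble` objects (NULL, with a warning, for
#'   molecules whose 3D embedding failed); each has `smiles`, `windows`,
#'   `energies` (relative, kcal/mol), `coords` (heavy-atom matrices) and
#'   `window_members` (4 integer index vectors, nested).
#' @export
generate_conformer_ensembles <- function(mols, seed = 1L, budget = 50L,
                                         max_conformers = 8L,
                                         floor = 0.1, rmsd_cutoff = 0.5) {
  if (is.character(mols)) mols <- parse_molecules(mols)
  n <- nrow(mols)
  td <- tempfile("conf"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  smi <- file.path(td, "in.smi")
  writeLines(paste(mols$smiles, paste0("m", seq_len(n)), sep = "\t"), smi)
  outjson <- file.path(td, "confs.json")
  status <- system2("python", c(conformer_helper_path(), smi, outjson,
                                as.character(budget), as.character(seed)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(outjson)) stop("conformer embedding backend failed")
  res <- jsonlite::read_json(outjson, simplifyVector = FALSE)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    ri <- res[[paste0("m", i)]]
    if (is.null(ri) || !identical(ri$status, "ok")) {
      warning("3D embedding failed, molecule skipped: ", mols$smiles[i])
      next
    }
    windows <- energy_windows(mols$rot_bonds[i], floor = floor)
    coords <- lapply(ri$coords, function(m) {
      do.call(rbind, lapply(m, function(p) as.numeric(unlist(p))))
    })
    dimfix <- vapply(coords, nrow, integer(1)) == mols$heavy_atoms[i]
    coords <- coords[dimfix]
    energies <- as.numeric(ri$energies)[dimfix]
    if (length(coords) == 0L) {
      warning("3D embedding failed, molecule skipped: ", mols$smiles[i])
      next
    }
    energies <- energies - min(energies)
    keep <- dedup_conformers(coords, energies, cutoff = rmsd_cutoff)
    coords <- coords[keep]; energies <- energies[keep]
    members <- lapply(windows, function(w) {
      idx <- which(energies <= w + 1e-9)
      idx[order(energies[idx])][seq_len(min(length(idx), max_conformers))]
    })
    out[[i]] <- structure(list(smiles = mols$smiles[i], windows = windows,
                               energies = energies, coords = coords,
                               window_members = lapply(members, sort),
                               seed = seed),
                          class = "conformer_ensemble")
  }
  out
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer_ensemble:", x$smiles, "-",
      paste(vapply(x$window_members, length, integer(1)), collapse = "/"),
      "conformers in windows",
      paste(sprintf("%.2f", x$windows), collapse = "/"), "kcal/mol\n")
  invisible(x)
}
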