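## Fingerprint similarity labels: ECFP4 Tanimoto, MACCS Tanimoto and
## AtomPairs Tversky.  Fingerprints come from the toolkit (OpenBabel ECFP4 /
## MACCS through ChemmineR, ChemmineR's own atom-pair descriptors); the
## similarity coefficients are computed by direct set arithmetic so the
## asymmetric Tversky parameterization is explicit and testable.

# Compute fingerprint sets for a vector of canonical SMILES.
# Returns list with $ecfp, $maccs (lists of sorted integer bit sets) and
# $ap (lists of atom-pair descriptor multisets as sorted numeric vectors).
mol_fingerprint_sets <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(setNames(smiles, paste0("m", seq_along(smiles))))
  ec <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "ECFP4"))
  mc <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "MACCS"))
  apset <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  aps <- ChemmineR::ap(apset)
  list(ecfp = lapply(seq_len(nrow(ec)), function(i) which(ec[i, ] != 0)),
       maccs = lapply(seq_len(nrow(mc)), function(i) which(mc[i, ] != 0)),
       ap = lapply(aps, function(x) sort(as.numeric(x))))
}

# Tanimoto coefficient on two bit sets.
tanimoto_sets <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  c0 <- length(intersect(a, b))
  c0 / (length(a) + length(b) - c0)
}

# Multiset intersection size (descriptors may repeat).
multiset_intersection <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0L) return(0L)
  sum(pmin(ta[common], tb[common]))
}

# Tversky similarity on multisets with the reference as the prototype side:
# T = c / (c + alpha*|R \ Q| + beta*|Q \ R|).
tversky_multisets <- function(query, ref, alpha = 0.9, beta = 0.1) {
  if (length(query) == 0L && length(ref) == 0L) return(1)
  c0 <- multiset_intersection(query, ref)
  c0 / (c0 + alpha * (length(ref) - c0) + beta * (length(query) - c0))
}

#' Fingerprint similarity vector for a molecule pair
#'
#' Computes the three fingerprint components of the similarity label:
#' ECFP4 Tanimoto, MACCS Tanimoto, and AtomPairs Tversky (asymmetric, with
#' the reference molecule as the prototype side).
#'
#' @param query,ref SMILES strings.
#' @param alpha,beta Tversky weights for the reference-minus-query and
#'   query-minus-reference difference terms.
#' @return named numeric vector `c(ecfp4, maccs, atompairs)`, all in [0, 1].
#' @export
fingerprint_similarity <- function(query, ref, alpha = 0.9, beta = 0.1) {
  fps <- mol_fingerprint_sets(canonicalize_smiles(c(query, ref)))
  c(ecfp4 = tanimoto_sets(fps$ecfp[[1]], fps$ecfp[[2]]),
    maccs = tanimoto_sets(fps$maccs[[1]], fps$maccs[[2]]),
    atompairs = tversky_multisets(fps$ap[[1]], fps$ap[[2]], alpha, beta))
}

# Q x R x 3 fingerprint similarity array; fingerprints computed once.
fingerprint_similarity_array <- function(queries, refs, alpha = 0.9, beta = 0.1) {
  all <- c(queries, refs)
  fps <- mol_fingerprint_sets(all)
  nq <- length(queries); nr <- length(refs)
  arr <- array(NA_real_, c(nq, nr, 3L),
               dimnames = list(NULL, NULL, c("ecfp4", "maccs", "atompairs")))
  for (i in seq_len(nq)) for (j in seq_len(nr)) {
    k <- nq + j
    arr[i, j, 1L] <- tanimoto_sets(fps$ecfp[[i]], fps$ecfp[[k]])
    arr[i, j, 2L] <- tanimoto_sets(fps$maccs[[i]], fps$maccs[[k]])
    arr[i, j, 3L] <- tversky_multisets(fps$ap[[i]], fps$ap[[k]], alpha, beta)
  }
  arr
}

# Pairwise ECFP4 Tanimoto matrix between two SMILES sets (used by the
# split guard and the fixture generator).
ecfp4_cross_tanimoto <- function(a, b) {
  fps <- mol_fingerprint_sets(c(a, b))
  na <- length(a)
  out <- matrix(NA_real_, na, length(b))
  for (i in seq_len(na)) for (j in seq_along(b)) {
    out[i, j] <- tanimoto_sets(fps$ecfp[[i]], fps$ecfp[[na + j]])
  }
  out
}
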