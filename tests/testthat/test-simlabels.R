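# Similarity labels: fingerprints, energy windows, conformer ensembles,
# CSPS, and the query x reference matrix.

fingerprint_similarity_array_test <- function(a, b) {
  latentmol:::fingerprint_similarity_array(a, b)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

test_that("fingerprint self-similarity is (1,1,1) and Tanimoto is symmetric", {
  fp <- fingerprint_similarity("CCO", "CCO")
  expect_equal(unname(fp), c(1, 1, 1))
  lib <- tiny_library()
  set.seed(1)
  idx <- matrix(sample.int(nrow(lib), 20, replace = TRUE), ncol = 2)
  arr_ab <- fingerprint_similarity_array_test(lib$smiles[idx[, 1]], lib$smiles[idx[, 2]])
  arr_ba <- fingerprint_similarity_array_test(lib$smiles[idx[, 2]], lib$smiles[idx[, 1]])
  for (k in seq_len(nrow(idx))) {
    expect_equal(arr_ab[k, k, "ecfp4"], arr_ba[k, k, "ecfp4"])
    expect_equal(arr_ab[k, k, "maccs"], arr_ba[k, k, "maccs"])
  }
  expect_true(all(arr_ab >= 0 & arr_ab <= 1))
})

test_that("ECFP4 Tanimoto equals explicit bit-set arithmetic", {
  sdf <- ChemmineR::smiles2sdf(c(a = "c1ccccc1", b = "c1ccncc1"))
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  m <- ChemmineR::as.matrix(fp)
  A <- which(m[1, ] != 0); B <- which(m[2, ] != 0)
  manual <- length(intersect(A, B)) / length(union(A, B))
  got <- fingerprint_similarity("c1ccccc1", "c1ccncc1")[["ecfp4"]]
  expect_equal(got, manual)
})

test_that("AtomPairs Tversky is asymmetric with the reference as prototype", {
  a <- "CCCCCCCC"; b <- "CCO"
  t_ab <- fingerprint_similarity(a, b)[["atompairs"]]
  t_ba <- fingerprint_similarity(b, a)[["atompairs"]]
  expect_false(isTRUE(all.equal(t_ab, t_ba)))
  # alpha = beta = 0.5 is the symmetric Dice-like case
  expect_equal(fingerprint_similarity(a, b, alpha = 0.5, beta = 0.5)[["atompairs"]],
               fingerprint_similarity(b, a, alpha = 0.5, beta = 0.5)[["atompairs"]])
})

test_that("energy windows follow the rotor scaling with a rigid floor", {
  expect_equal(energy_windows(10L)[2], 5.060)
  expect_equal(energy_windows(0L), rep(0.1, 4))
  lib <- tiny_library()
  for (i in seq_len(10)) {
    w <- energy_windows(lib$rot_bonds[i])
    expect_true(all(diff(w) >= 0))
  }
})

test_that("conformer RMSD de-duplication retains one of two near-identical conformers", {
  set.seed(5)
  base <- matrix(rnorm(15), 5, 3)
  near <- base + matrix(rnorm(15, sd = 0.05), 5, 3)    # RMSD well below 0.5
  far <- base + matrix(c(rep(2, 5), rep(0, 10)), 5, 3) # same shape, but rotated copies dedup
  kept <- dedup_conformers(list(base, near), c(0, 0.2), cutoff = 0.5)
  expect_length(kept, 1L)
  expect_identical(kept, 1L)  # lower-energy conformer wins
  d <- latentmol:::kabsch_rmsd(base, near)
  expect_lt(d, 0.5)
  # a rigidly rotated copy superposes exactly
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(latentmol:::kabsch_rmsd(base, base %*% rot), 1e-10)
})

test_that("rigid molecules get a single conformer; flexible ones several", {
  ens <- cached("ens_rigid_flex", function() {
    generate_conformer_ensembles(parse_molecules(c("c1ccccc1", "CCCC")), seed = 1L)
  })
  for (k in 1:4) expect_length(ens[[1]]$window_members[[k]], 1L)
  # n-butane: anti + gauche rotamers inside the widest window
  expect_gte(length(ens[[2]]$window_members[[4]]), 2L)
  dihedral <- function(x) {
    b1 <- x[2, ] - x[1, ]; b2 <- x[3, ] - x[2, ]; b3 <- x[4, ] - x[3, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    atan2(sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2)) * 180 / pi
  }
  mem <- ens[[2]]$window_members[[4]][1:2]
  d1 <- abs(dihedral(ens[[2]]$coords[[mem[1]]]))
  d2 <- abs(dihedral(ens[[2]]$coords[[mem[2]]]))
  expect_gt(abs(d1 - d2), 30)          # distinct rotamer basins
  # nesting: smaller windows are subsets of larger ones
  for (k in 1:3) {
    expect_true(all(ens[[2]]$window_members[[k]] %in% ens[[2]]$window_members[[k + 1]]))
  }
})

test_that("CSPS self-similarity is ~1 for rigid molecules, windows monotone", {
  ens <- cached("ens_csps", function() {
    generate_conformer_ensembles(
      parse_molecules(c("c1ccccc1", "c1ccncc1", "CCCCO")), seed = 1L)
  })
  self <- csps_vector(ens[[1]], ens[[1]])
  expect_true(all(self[1:4] >= 1 - 1e-6))
  expect_lte(self[5], 1e-6)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    v <- csps_vector(ens[[pair[1]]], ens[[pair[2]]])
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v[1:4]) >= -1e-9))   # nested ensembles
    expect_equal(v[5], min(max(v[4] - v[1], 0), 1))
  }
  # 1x1 conformer pair: window-1 component equals the direct overlay score
  ta <- pharmacophore_types("c1ccccc1"); tb <- pharmacophore_types("c1ccncc1")
  direct <- latentmol:::conformer_overlap(ens[[1]]$coords[[1]], ta,
                                          ens[[2]]$coords[[1]], tb)
  expect_equal(csps_vector(ens[[1]], ens[[2]])[1], direct)
})

test_that("pharmacophore typing follows the structural rules", {
  ty <- pharmacophore_types("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(colnames(ty),
                   c("donor", "acceptor", "aromatic", "hydrophobe", "positive", "negative"))
  expect_identical(sum(ty[, "aromatic"]), 6L)
  expect_true(any(ty[, "donor"]))            # carboxylic OH
  expect_true(sum(ty[, "acceptor"]) >= 3)
  ty2 <- pharmacophore_types("C[N+](C)(C)C")
  expect_true(any(ty2[, "positive"]))
})

test_that("similarity matrix has complete shape, deterministic rows, coherent cells", {
  sm <- cached("tiny_matrix", function() {
    build_similarity_matrix(c("CCO", "CCO"), c("c1ccccc1", "CCN", "CCCO"), seed = 2L)
  })
  expect_identical(dim(sm$labels), c(2L, 3L, 8L))
  expect_false(anyNA(sm$labels))
  expect_true(all(sm$labels >= 0 & sm$labels <= 1))
  # identical queries give identical label rows
  expect_equal(sm$labels[1, , ], sm$labels[2, , ])
  # cells match independent pairwise recomputation
  fp <- fingerprint_similarity("CCO", "CCN")
  expect_equal(unname(sm$labels[1, 2, 6:8]), unname(fp))
})

test_that("similarity matrices persist to a binary container with JSON sidecar", {
  sm <- cached("tiny_matrix", function() {
    build_similarity_matrix(c("CCO", "CCO"), c("c1ccccc1", "CCN", "CCCO"), seed = 2L)
  })
  dir <- tempfile("mat")
  save_similarity_matrix(sm, dir)
  back <- load_similarity_matrix(dir)
  expect_equal(back$labels, sm$labels)
  expect_identical(back$queries, sm$queries)
  expect_identical(back$seed, sm$seed)
})
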