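# Screening, early-recognition metrics, propagation, migration, fusion,
# ligand efficiency.

test_that("screening scores, filters at 0.5, and ranks like brute force", {
  set.seed(6)
  d <- 16L
  lib <- matrix(rnorm(20 * d), 20, d)
  rownames(lib) <- paste0("mol", 1:20)
  refs1 <- lib[c(3, 7), ] + matrix(rnorm(2 * d, sd = 0.05), 2, d)
  refs2 <- matrix(rnorm(3 * d), 3, d)
  res <- screen_library(lib, list(a = refs1, b = refs2))
  expect_setequal(res$id, rownames(lib))
  expect_identical(sort(res$rank), 1:20)
  # identical query -> score 1 for its set
  res_self <- screen_library(lib, list(a = lib[3, , drop = FALSE]))
  expect_equal(res_self$a[res_self$id == "mol3"], 1, tolerance = 1e-12)
  # filtered scores are 0 or >= 0.5
  expect_true(all(res$a == 0 | res$a >= 0.5))
  expect_true(all(res$b == 0 | res$b >= 0.5))
  # brute-force recomputation of the ranking
  cosm <- function(a, b) {
    an <- a / sqrt(rowSums(a^2)); bn <- b / sqrt(rowSums(b^2)); tcrossprod(an, bn)
  }
  s1 <- apply(cosm(lib, refs1), 1, max); s1[s1 < 0.5] <- 0
  s2 <- apply(cosm(lib, refs2), 1, max); s2[s2 < 0.5] <- 0
  manual_order <- rownames(lib)[order(s1 + s2, decreasing = TRUE)]
  expect_identical(res$id, manual_order)
  expect_error(screen_library(lib, list(a = refs1[0, , drop = FALSE])),
               "empty reference set")
})

test_that("the screening post-filter zeroes sub-threshold per-set scores", {
  lib <- matrix(c(1, 0, 0.49, sqrt(1 - 0.49^2), 0.51, sqrt(1 - 0.51^2)),
                3, 2, byrow = TRUE)
  refs <- matrix(c(1, 0), 1, 2)
  res <- screen_library(lib, refs)
  got <- res$set1[match(1:3, res$id)]
  expect_equal(got, c(1, 0, 0.51), tolerance = 1e-9)
})

test_that("BEDROC rewards early recognition and matches its analytic null", {
  n <- 400; n_act <- 20
  labels <- c(rep(1, n_act), rep(0, n - n_act))
  perfect <- -seq_len(n)           # actives (first) get the best scores
  expect_gte(bedroc(perfect, labels), 0.99)
  expect_lte(bedroc(-perfect, labels), 0.01)
  # random ranking: mean over permutations ~ affine image of E[RIE] = 1
  alpha <- 160.9; ra <- n_act / n
  null_value <- ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
  set.seed(31)
  mc <- mean(replicate(200, bedroc(sample(n), labels)))
  expect_equal(mc, null_value, tolerance = 0.15)
  expect_error(bedroc(perfect, rep(1, n)), "metric error")
})

test_that("AUROC and enrichment factor behave on known orderings", {
  labels <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(auroc(10:1, labels), 1)
  expect_equal(auroc(1:10, labels), 0)
  expect_equal(enrichment_factor(10:1, labels, fraction = 0.2), 5)  # 2/2 vs 2/10
})

test_that("stochastic propagation respects degenerate settings and drifts away", {
  set.seed(2)
  e0 <- rnorm(32)
  stats0 <- representation_statistics(matrix(rnorm(50 * 32), 50, 32), "lib")
  tr_id <- stochastic_propagation(e0, stats0, steps = 5, scale = 0, seed = 1)
  expect_true(all(abs(tr_id$reps[5, ] - e0) == 0))
  zero_sigma <- representation_statistics(matrix(1, 3, 32), "flat")  # sd 0
  tr_z <- stochastic_propagation(e0, zero_sigma, steps = 5, scale = 0.1, seed = 1)
  expect_true(all(abs(tr_z$reps[5, ] - e0) == 0))
  tr <- stochastic_propagation(e0, stats0, steps = 60, seed = 4)
  expect_identical(nrow(tr$steps), 60L)
  expect_lt(tail(tr$steps$sim_start, 1), 1)
  expect_identical(tr$header$sigma_ref, "lib")
})

test_that("directed migration minimizes a convex synthetic objective", {
  set.seed(9)
  d <- 64L
  e0 <- rnorm(d, sd = 0.015)
  # quadratic optimum placed at cosine 0.8 from the start, so the property
  # term and the similarity anchor share a minimizer
  u <- rnorm(d); u <- u - e0 * sum(u * e0) / sum(e0^2); u <- u / sqrt(sum(u^2))
  target <- 0.8 * e0 + 0.6 * sqrt(sum(e0^2)) * u
  quad <- function(rep_node, tape) {
    latentmol:::v_sum(latentmol:::v_square(
      latentmol:::v_sub(rep_node, latentmol:::ad_const(tape, matrix(target, 1)))))
  }
  obj <- objective_spec("migrate", targets = c(q = 0), predictors = list(quad))
  tr <- directed_migration(e0, obj, lr = 2e-5, steps = 600L, decoder = NULL)
  expect_lt(tail(tr$steps$loss, 1), tr$steps$loss[1] / 10)
  # non-increasing in >= 95% of steps, up to optimizer jitter whose
  # amplitude (~1e-5) sits three orders below the loss scale
  drops <- diff(tr$steps$loss) <= 1e-3 * tr$steps$loss[1]
  expect_gt(mean(drops), 0.95)
})

test_that("the migration similarity loss is minimized exactly at 0.8", {
  expect_equal(migration_similarity_loss(0.8), 0)
  grid <- seq(0, 1, by = 0.01)
  expect_equal(grid[which.min(migration_similarity_loss(grid))], 0.8)
})

test_that("scaffold-hop loss is 1 - sim and zero when target equals start", {
  set.seed(3)
  e0 <- rnorm(16)
  obj <- objective_spec("scaffold_hop", target_rep = e0)
  tr <- directed_migration(e0, obj, lr = 1e-4, steps = 3L)
  expect_lt(tr$steps$loss[1], 1e-9)
  expect_error(objective_spec("scaffold_hop"), "target representation")
  expect_error(objective_spec("migrate"), "property target")
})

test_that("chemical fusion pulls toward the nearest reference", {
  # start at cosine exactly 0.6 to the nearest reference: term = 1/2
  start <- c(1, 0, rep(0, 6))
  refs <- rbind(c(0.6, 0.8, rep(0, 6)), c(-1, 0, rep(0, 6)))
  tr <- chemical_fusion(refs, start, lr = 1e-3, steps = 120L)
  expect_equal(tr$steps$loss[1], 0.5, tolerance = 1e-9)
  expect_lt(tail(tr$steps$loss, 1), tr$steps$loss[1])
  expect_true(all(tr$steps$nearest_ref == 1L))
  # term limits of the fusion sigmoid: 10000^0.4 ~ 40 at sim = 1,
  # 10000^-0.6 ~ 0.004 at sim = 0
  term <- function(sim) 1 / (1 + exp(log(10000) * (sim - 0.6)))
  expect_lt(term(1), 0.05)
  expect_gt(term(0), 0.95)
  expect_error(chemical_fusion(refs[1, , drop = FALSE], start), "at least two")
})

test_that("ligand efficiency normalizes by the log heavy-atom count", {
  expect_equal(ligand_efficiency(-7.5, 1), -7.5)
  expect_equal(ligand_efficiency(0, 30), 0)
  expect_equal(ligand_efficiency(-50, 25), -50 / (1 + log(25)))
  expect_error(ligand_efficiency(-5, 0), "domain error")
})

test_that("trajectories serialize to JSON lines with a deduplicated structure list", {
  set.seed(1)
  stats0 <- representation_statistics(matrix(rnorm(40 * 8), 40, 8))
  tr <- stochastic_propagation(rnorm(8), stats0, steps = 4, seed = 2)
  tr$steps$smiles <- c("CCO", "CCO", "CCN", NA)
  tr$steps$valid <- c(TRUE, TRUE, TRUE, NA)
  path <- tempfile(fileext = ".jsonl")
  write_trajectory(tr, path)
  expect_identical(length(readLines(path)), 5L)   # header + 4 steps
  expect_setequal(readLines(paste0(path, ".smi")), c("CCO", "CCN"))
})
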