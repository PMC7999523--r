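test_that("coordination matrix equals brute-force Pearson", {
  expr <- expr_from_matrix(rbind(
    g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1)
  ))
  cm <- coordination_matrix(expr, "CTR")
  expect_equal(cm["g1", "g2"], 1)
  expect_equal(cm["g1", "g3"], -1)
  expect_equal(diag(unclass(cm)), c(g1 = 1, g2 = 1, g3 = 1))

  # 5-gene seeded fixture against the double-loop oracle, to 1e-12
  set.seed(61)
  mat <- matrix(stats::rlnorm(5 * 4, log(100), 0.3), nrow = 5,
                dimnames = list(paste0("g", 1:5), NULL))
  cm5 <- coordination_matrix(expr_from_matrix(mat), "CTR")
  expect_equal(unclass(cm5), oracle_cor_matrix(mat), tolerance = 1e-12,
               ignore_attr = TRUE)

  # larger instance, still exact
  set.seed(62)
  mat50 <- matrix(stats::rlnorm(50 * 4, log(100), 0.3), nrow = 50,
                  dimnames = list(sprintf("g%02d", 1:50), NULL))
  cm50 <- coordination_matrix(expr_from_matrix(mat50), "CTR")
  expect_equal(unclass(cm50), oracle_cor_matrix(mat50), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(cm50)))
})

test_that("zero-variance genes leave the universe; <3 replicas error", {
  mat <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(2, 1, 4, 3))
  cm <- coordination_matrix(expr_from_matrix(mat), "CTR")
  expect_setequal(rownames(cm), c("g1", "g3"))
  expect_equal(attr(cm, "excluded"), "g2")
  expect_error(coordination_matrix(expr_from_matrix(mat[, 1:2]), "CTR"),
               "3 replicas")
})

test_that("pair classification is strict at every boundary", {
  expect_equal(classify_rho(0.95), "synergistic")
  expect_equal(classify_rho(0.90), "unclassified")   # boundary excluded
  expect_equal(classify_rho(-0.90), "unclassified")
  expect_equal(classify_rho(-0.95), "antagonistic")
  expect_equal(classify_rho(0.05), "unclassified")
  expect_equal(classify_rho(-0.05), "unclassified")
  expect_equal(classify_rho(0.03), "independent")
  expect_equal(classify_rho(0.50), "unclassified")
  # partition of [-1, 1] minus boundaries: exactly one class everywhere
  grid <- seq(-1, 1, by = 0.001)
  grid <- setdiff(grid, c(-0.9, 0.9, -0.05, 0.05))
  cls <- classify_rho(grid)
  expect_true(all(cls %in% c("synergistic", "antagonistic", "independent",
                             "unclassified")))
  expect_equal(sum(cls == "synergistic"), sum(grid > 0.9))
  expect_equal(sum(cls == "antagonistic"), sum(grid < -0.9))
  expect_equal(sum(cls == "independent"), sum(abs(grid) < 0.05))
  expect_error(classify_rho(1.2), "<= 1")
})

test_that("critical_rho inverts the t test for paired observations", {
  expect_equal(round(critical_rho(4, 0.05), 2), 0.90)
  expect_equal(round(critical_rho(3, 0.05), 3), 0.988)
  # grid-search inversion oracle
  expect_equal(critical_rho(4, 0.05), oracle_critical_rho(4, 0.05),
               tolerance = 1e-5)
  expect_equal(critical_rho(6, 0.05), oracle_critical_rho(6, 0.05),
               tolerance = 1e-5)
  # alpha -> 0 drives the threshold to 1; more replicas lower it
  expect_gt(critical_rho(4, 1e-8), 0.9999)
  expect_true(all(diff(vapply(3:10, critical_rho, 1)) < 0))
  expect_error(critical_rho(2), ">= 3")
})

test_that("profile similarity classifies identical/flipped/random profiles", {
  set.seed(63)
  n <- 60
  base <- matrix(stats::rnorm(n * 6, 100, 15), nrow = n,
                 dimnames = list(sprintf("g%02d", 1:n), NULL))
  # make g01 and g02 near-identical, g03 their mirror
  base[2, ] <- base[1, ] + stats::rnorm(6, 0, 0.5)
  base[3, ] <- 200 - base[1, ] + stats::rnorm(6, 0, 0.5)
  cm <- coordination_matrix(expr_from_matrix(base), "CTR")

  sim_ab <- profile_similarity(cm, "g01", "g02")
  expect_equal(sim_ab$class, "similar")
  expect_gt(sim_ab$r_squared, 0.9)
  expect_gt(sim_ab$slope, 0)

  opp <- profile_similarity(cm, "g01", "g03")
  expect_equal(opp$class, "opposite")
  expect_lt(opp$slope, 0)

  neu <- profile_similarity(cm, "g04", "g05")
  expect_equal(neu$class, "neutral")
  expect_lt(neu$r_squared, 0.9)

  # symmetry: same class and R^2 either way round
  ba <- profile_similarity(cm, "g02", "g01")
  expect_equal(ba$class, sim_ab$class)
  expect_equal(ba$r_squared, sim_ab$r_squared, tolerance = 1e-9)
})

test_that("independent random profiles of length 500 stay neutral", {
  set.seed(64)
  pa <- stats::runif(500, -1, 1)
  pb <- stats::runif(500, -1, 1)
  fit <- stats::lm.fit(cbind(1, pa), pb)
  r2 <- 1 - sum(fit$residuals^2) / sum((pb - mean(pb))^2)
  expect_lt(r2, 0.9)
})

test_that("small universes warn and fall back to neutral", {
  mat <- matrix(stats::rnorm(5 * 4, 100, 10), nrow = 5,
                dimnames = list(paste0("g", 1:5), NULL))
  cm <- coordination_matrix(expr_from_matrix(mat), "CTR")
  expect_warning(out <- profile_similarity(cm, "g1", "g2"), "below 10")
  expect_equal(out$class, "neutral")
})

test_that("pathway coordination counts match exhaustive enumeration", {
  set.seed(65)
  n <- 12
  mat <- matrix(stats::rlnorm(n * 4, log(100), 0.25), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
  mat[1:3, ] <- plant_correlation(mat[1:3, , drop = FALSE], 1)
  cm <- coordination_matrix(expr_from_matrix(mat), "CTR")

  all3 <- count_pathway_coordination(cm, c("g01", "g02", "g03"))
  expect_equal(all3$n_synergistic, 3L)        # all pairs at rho = 1
  expect_equal(all3$pct_synergistic, 100)

  set4 <- sprintf("g%02d", 4:7)
  cnt <- count_pathway_coordination(cm, set4)
  # exhaustive enumeration oracle
  pairs <- utils::combn(set4, 2)
  cls <- classify_rho(apply(pairs, 2, function(p) cm[p[1], p[2]]))
  expect_equal(cnt$n_pairs, 6L)
  expect_equal(cnt$n_synergistic, sum(cls == "synergistic"))
  expect_equal(cnt$n_independent, sum(cls == "independent"))
  expect_equal(cnt$n_unclassified, sum(cls == "unclassified"))

  # absent genes are skipped and reported; empty intersection errors
  mixed <- count_pathway_coordination(cm, c("g01", "g02", "NOPE"))
  expect_equal(attr(mixed, "skipped"), "NOPE")
  expect_equal(mixed$n_genes, 2L)
  expect_error(count_pathway_coordination(cm, c("X", "Y")), "intersect")
  # case-insensitive matching
  expect_equal(count_pathway_coordination(cm, c("G01", "G02"))$n_pairs, 1L)
})

test_that("fabric remodeling reports exact deltas for planted modules", {
  set.seed(66)
  mk <- function(rho_mod) {
    base <- matrix(stats::rlnorm(20 * 4, log(100), 0.2), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
    base[1:3, ] <- plant_correlation(base[1:3, , drop = FALSE], rho_mod,
                                     exact = TRUE)
    coordination_matrix(expr_from_matrix(base), "CTR")
  }
  ca <- mk(0.3); cb <- mk(0.97)
  fr <- fabric_remodeling(ca, cb, c("g01", "g02", "g03"))
  delta <- fr[fr$condition == "delta", ]
  expect_equal(delta$n_synergistic, 3L)       # every within-module pair
  expect_equal(delta$n_unclassified, -3L)

  # identical matrices give all-zero deltas
  fr0 <- fabric_remodeling(ca, ca, c("g01", "g02", "g03"))
  d0 <- fr0[fr0$condition == "delta", ]
  expect_true(all(d0[c("n_synergistic", "n_antagonistic", "n_independent",
                       "n_unclassified", "pct_synergistic",
                       "pct_similar_profiles")] == 0))

  # seeded two-condition run matches brute-force recomputation
  brute <- function(cm, genes) {
    pairs <- utils::combn(genes, 2)
    sum(classify_rho(apply(pairs, 2, function(p) cm[p[1], p[2]])) ==
          "synergistic")
  }
  genes <- sprintf("g%02d", c(1:3, 8, 12))
  frg <- fabric_remodeling(ca, cb, genes)
  expect_equal(frg$n_synergistic[1], brute(ca, genes))
  expect_equal(frg$n_synergistic[2], brute(cb, genes))
  expect_error(fabric_remodeling(ca, cb, "g01"), "fewer than 2")
})

test_that("tiled class counting equals the naive full-matrix scan", {
  set.seed(67)
  mat <- matrix(stats::rlnorm(40 * 4, log(100), 0.3), nrow = 40,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
  expr <- expr_from_matrix(mat)
  cm <- coordination_matrix(expr, "CTR")
  cls <- classify_rho(cm[upper.tri(cm)])
  naive <- table(factor(cls, levels = c("synergistic", "antagonistic",
                                        "independent", "unclassified")))
  for (tile in c(7, 16, 100)) {
    got <- coordination_class_counts(expr, "CTR", tile_size = tile)
    expect_equal(got$n_pairs, choose(40, 2))
    expect_equal(got$n_synergistic, unname(naive[["synergistic"]]))
    expect_equal(got$n_antagonistic, unname(naive[["antagonistic"]]))
    expect_equal(got$n_independent, unname(naive[["independent"]]))
    expect_equal(got$n_unclassified, unname(naive[["unclassified"]]))
  }
})

test_that("coordination edge lists carry classified pairs only", {
  mat <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8.1),
               g3 = c(9, 7, 8, 2), g4 = c(4, 3, 2, 1))
  cm <- coordination_matrix(expr_from_matrix(mat), "CTR")
  edges <- coordination_edges(cm)
  expect_true(all(edges$class != "unclassified"))
  expect_equal(nrow(edges),
               sum(classify_rho(cm[upper.tri(cm)]) != "unclassified"))
})
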