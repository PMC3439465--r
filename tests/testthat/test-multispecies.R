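test_that("patristic distances and multipliers follow the tree", {
  tr <- "((A:1,B:1):1,C:2);"
  w <- species_weights_from_tree(tr, focal = "A", species = c("B", "C"))
  expect_equal(w$distances, c(B = 2, C = 4))
  expect_equal(w$multipliers, c(B = 2 / 3, C = 4 / 3))
  expect_equal(mean(w$multipliers), 1)
  # zero distance gets the floor before normalization
  tr0 <- "((A:0,B:0):1,C:2);"
  w0 <- species_weights_from_tree(tr0, focal = "A", species = c("B", "C"))
  expect_equal(unname(w0$distances["B"]), 0)
  expect_true(all(w0$multipliers > 0))
  expect_error(species_weights_from_tree(tr, "Z", c("B")), "leaf not found")
  expect_error(species_weights_from_tree("((A,B),C);", "A", "B"),
               "branch lengths")
})

test_that("matched priors reduce the matrix model to the scalar model", {
  set.seed(5)
  G <- 30; p <- 4
  Xv <- matrix(rnorm(G * p), G, p,
               dimnames = list(paste0("g", 1:G), paste0("m", 1:p)))
  X <- score_matrix(Xv, center = TRUE)
  e1 <- expression_experiment(matrix(rnorm(G), G, 1), "e1",
                              gene_ids = rownames(Xv), species_id = "sp1")
  ctr <- center_panel(list(e1), X)
  prior <- prior_spec(c = 3, nu = 3, S = 0.9, p_exp = 1, p = p)
  panel <- species_panel(ctr$experiments)
  mp <- matrix_prior(c = 3, E = 1, delta = 3, Q = matrix(3 * 0.9, 1, 1),
                     p_exp = 1, p = p)
  for (i in 1:50) {
    gm <- as.integer(runif(p) < 0.5)
    expect_equal(log_posterior_gamma_multi(gm, ctr$X, panel, mp),
                 log_posterior_gamma(gm, ctr$X, ctr$experiments, prior),
                 tolerance = 1e-8)
  }
})

test_that("species order does not change the multi-species posterior", {
  set.seed(61)
  G <- 15
  Xv <- matrix(rnorm(G * 3), G, 3,
               dimnames = list(paste0("g", 1:G), paste0("m", 1:3)))
  X <- score_matrix(Xv, center = TRUE)
  es <- lapply(1:3, function(i)
    expression_experiment(matrix(rnorm(G), G, 1), paste0("e", i),
                          gene_ids = rownames(Xv),
                          species_id = paste0("s", i)))
  ctr <- center_panel(es, X)
  mult <- c(s1 = 0.8, s2 = 1, s3 = 1.2)
  mp <- matrix_prior(c = 2, E = 3, delta = 5, Q = diag(1, 3),
                     p_exp = 1, p = 3)
  pan_a <- species_panel(ctr$experiments, multipliers = mult)
  pan_b <- species_panel(rev(ctr$experiments), multipliers = mult)
  gm <- c(1, 0, 1)
  expect_equal(log_posterior_gamma_multi(gm, ctr$X, pan_a, mp),
               log_posterior_gamma_multi(gm, ctr$X, pan_b, mp),
               tolerance = 1e-9)
})

test_that("matrix-t closed form matches the grid/quadrature oracle", {
  set.seed(9)
  G <- 5
  Xv <- matrix(rnorm(G * 2), G, 2,
               dimnames = list(paste0("g", 1:G), c("m1", "m2")))
  X2 <- score_matrix(Xv, center = TRUE)
  Y <- matrix(rnorm(G * 2), G, 2)
  eA <- expression_experiment(Y[, 1, drop = FALSE], "eA",
                              gene_ids = rownames(Xv), species_id = "s1")
  eB <- expression_experiment(Y[, 2, drop = FALSE], "eB",
                              gene_ids = rownames(Xv), species_id = "s2")
  ctr <- center_panel(list(eA, eB), X2)
  panel <- species_panel(ctr$experiments, multipliers = c(s1 = 1, s2 = 1))
  mp <- matrix_prior(c = 2, E = 2, delta = 4, Q = diag(0.8, 2),
                     p_exp = 1, p = 2)
  Yc <- sapply(ctr$experiments, function(e) e$values[, 1])
  for (gm in list(c(0, 0), c(1, 0), c(0, 1))) {
    idx <- which(gm == 1)
    x <- if (length(idx)) unclass(ctr$X)[, idx] else NULL
    expect_equal(log_posterior_gamma_multi(gm, ctr$X, panel, mp),
                 oracle_log_marglik_matrix(Yc, x, mp) + 2 * log(0.5),
                 tolerance = 1e-2)
  }
})

test_that("raising a species' multiplier reduces its decoy's pull", {
  # species s2 alone carries a spurious association with motif 2
  set.seed(67)
  G <- 60
  Xv <- matrix(rnorm(G * 3), G, 3,
               dimnames = list(paste0("g", 1:G), paste0("m", 1:3)))
  X <- score_matrix(Xv, center = TRUE)
  y1 <- 1.0 * Xv[, 1] + rnorm(G, sd = 0.5)      # honest species
  y2 <- 1.5 * Xv[, 2] + rnorm(G, sd = 0.5)      # misleading species
  e1 <- expression_experiment(cbind(y1), "e1", gene_ids = rownames(Xv),
                              species_id = "s1")
  e2 <- expression_experiment(cbind(y2), "e2", gene_ids = rownames(Xv),
                              species_id = "s2")
  ctr <- center_panel(list(e1, e2), X)
  mp <- matrix_prior(c = 5, E = 2, delta = 4, Q = diag(0.5, 2),
                     p_exp = 1, p = 3)
  lodds_decoy <- vapply(c(0.5, 1, 2, 4, 8), function(m2) {
    pan <- species_panel(ctr$experiments, multipliers = c(s1 = 1, s2 = m2))
    log_posterior_gamma_multi(c(1, 1, 0), ctr$X, pan, mp) -
      log_posterior_gamma_multi(c(1, 0, 0), ctr$X, pan, mp)
  }, numeric(1))
  expect_true(all(diff(lodds_decoy) < 0))
})

test_that("pooled marginals are convex combinations of the inputs", {
  m1 <- c(a = 1, b = 0)
  m2 <- c(a = 0, b = 1)
  expect_equal(pooled_marginals(list(m1, m2)), c(a = 0.5, b = 0.5))
  expect_equal(pooled_marginals(list(m1, m1)), m1)
  expect_equal(pooled_marginals(list(m1, m2), weights = c(1, 0)), m1)
  set.seed(71)
  ms <- lapply(1:3, function(i) setNames(runif(4), letters[1:4]))
  pooled <- pooled_marginals(ms)
  lo <- do.call(pmin, ms); hi <- do.call(pmax, ms)
  expect_true(all(pooled >= lo - 1e-12 & pooled <= hi + 1e-12))
  expect_error(pooled_marginals(list(m1, c(x = 1, b = 0))), "mismatch")
})

test_that("cross-species correlation behaves on known profiles", {
  G <- 20
  set.seed(73)
  vals <- matrix(rnorm(G * 2), G, 2,
                 dimnames = list(paste0("g", 1:G), NULL))
  ea <- expression_experiment(vals, "a")
  eb_same <- expression_experiment(vals, "b")
  map <- cbind(paste0("g", 1:G), paste0("g", 1:G))
  expect_equal(as.numeric(cross_species_correlation(ea, eb_same, map)), 1)
  eb_neg <- expression_experiment(-vals, "b")
  expect_equal(as.numeric(cross_species_correlation(ea, eb_neg, map)), -1)
  expect_error(cross_species_correlation(ea, eb_same, map[1:2, ]),
               "fewer than 3")
  # correlated profiles at n = 200 recover the generating correlation
  n <- 200
  za <- rnorm(n); zb <- 0.8 * za + sqrt(1 - 0.64) * rnorm(n)
  e1 <- expression_experiment(cbind(za), "a",
                              gene_ids = paste0("h", 1:n))
  e2 <- expression_experiment(cbind(zb), "b",
                              gene_ids = paste0("h", 1:n))
  r <- cross_species_correlation(e1, e2,
                                 cbind(paste0("h", 1:n), paste0("h", 1:n)))
  expect_equal(as.numeric(r), 0.8, tolerance = 0.1)
  expect_equal(attr(r, "n_pairs"), n)
})
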