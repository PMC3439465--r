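test_that("panel centering removes observed means and is idempotent", {
  vals <- cbind(c(1, 2, 3), c(1, 2, NA))
  e <- expression_experiment(vals, "e1")
  X <- score_matrix(matrix(rnorm(6), 3, 2,
                           dimnames = list(paste0("g", 1:3), NULL)))
  e$gene_ids <- rownames(unclass(X)); rownames(e$values) <- e$gene_ids
  ctr <- center_panel(list(e), X)
  expect_equal(ctr$experiments[[1]]$values[, 1], c(-1, 0, 1),
               ignore_attr = TRUE)
  expect_equal(ctr$experiments[[1]]$values[1:2, 2], c(-0.5, 0.5),
               ignore_attr = TRUE)
  ctr2 <- center_panel(ctr$experiments, ctr$X)
  expect_equal(ctr2$experiments[[1]]$values, ctr$experiments[[1]]$values,
               tolerance = 1e-12)
  bad <- expression_experiment(cbind(c(1, NA, NA)), "bad")
  expect_error(center_panel(list(bad), score_matrix(matrix(0, 3, 1))),
               "< 2 observed")
})

test_that("default prior follows the stated estimation rules", {
  # orthonormal X: full-model coefficients are X'y, c their variance
  set.seed(13)
  G <- 12; p <- 3
  Q <- qr.Q(qr(matrix(rnorm(G * p), G, p)))
  X <- score_matrix(Q, centered = TRUE)   # treat as given design
  y <- rnorm(G)
  e <- expression_experiment(cbind(y), "e1",
                             gene_ids = rownames(unclass(X)))
  e$centered <- TRUE
  pr <- default_prior(X, list(e), p_exp = 1)
  expect_equal(pr$c, var(as.numeric(crossprod(Q, y))), tolerance = 1e-8)
  expect_equal(pr$S, var(y), tolerance = 1e-12)
  expect_equal(pr$nu, 3L)
  expect_equal(pr$pi, 1 / 3)
  # user-supplied c passes through untouched
  pr2 <- default_prior(X, list(e), p_exp = 1, c = 7)
  expect_identical(pr2$c, 7)
  # degenerate data
  e0 <- expression_experiment(cbind(rep(0, G)), "e0",
                              gene_ids = rownames(unclass(X)))
  expect_error(default_prior(X, list(e0), p_exp = 1), "zero data variance")
  expect_error(default_prior(X, list(e), p_exp = 3), "p_exp")
})

test_that("closed-form log posterior matches numerical integration", {
  set.seed(7)
  G <- 6; p <- 2
  Xv <- matrix(rnorm(G * p), G, p,
               dimnames = list(paste0("g", 1:G), c("m1", "m2")))
  X <- score_matrix(Xv, center = TRUE)
  y <- matrix(rnorm(G * 2), G, 2)
  y[2, 1] <- NA                                  # exercise the mask path
  e1 <- expression_experiment(y, "e1", gene_ids = rownames(Xv))
  ctr <- center_panel(list(e1), X)
  prior <- prior_spec(c = 5, nu = 3, S = 0.8, p_exp = 1, p = 2)
  for (gm in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    expect_equal(log_posterior_gamma(gm, ctr$X, ctr$experiments, prior),
                 oracle_log_posterior(gm, ctr$X, ctr$experiments, prior),
                 tolerance = 1e-3)
  }
})

test_that("an all-true mask is identical to the unmasked path", {
  pan <- toy_panel(G = 20, p = 3, seed = 17)
  e <- pan$experiments[[1]]
  e2 <- e
  e2$mask <- matrix(TRUE, nrow(e$values), ncol(e$values))
  for (gm in list(c(0, 0, 0), c(1, 0, 1))) {
    prior <- prior_spec(c = 2, S = 1, p_exp = 1, p = 3)
    expect_identical(log_posterior_gamma(gm, pan$X, list(e), prior),
                     log_posterior_gamma(gm, pan$X, list(e2), prior))
  }
})

test_that("masking a gene equals deleting its row", {
  pan <- toy_panel(G = 25, p = 4, seed = 19)
  e <- pan$experiments[[1]]
  prior <- prior_spec(c = 3, S = 1, p_exp = 1, p = 4)
  masked <- e
  masked$values[5, ] <- 0; masked$mask[5, ] <- FALSE
  deleted <- e
  deleted$values <- deleted$values[-5, , drop = FALSE]
  deleted$mask <- deleted$mask[-5, , drop = FALSE]
  deleted$gene_ids <- deleted$gene_ids[-5]
  for (gm in list(c(0, 0, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 1))) {
    expect_equal(log_posterior_gamma(gm, pan$X, list(masked), prior),
                 log_posterior_gamma(gm, pan$X, list(deleted), prior),
                 tolerance = 1e-10)
  }
})

test_that("g-prior posterior differences are invariant to column rescaling", {
  pan <- toy_panel(G = 30, p = 4, seed = 23)
  prior <- prior_spec(c = 4, S = 1, p_exp = 1, p = 4)
  Xs <- unclass(pan$X)
  Xs[, 2] <- Xs[, 2] * 37.5
  Xs[, 4] <- Xs[, 4] * -0.01
  X2 <- score_matrix(Xs, centered = TRUE)
  states <- list(c(0, 0, 0, 0), c(0, 1, 0, 0), c(1, 1, 0, 1),
                 c(0, 0, 1, 1), c(1, 1, 1, 1))
  lp1 <- vapply(states, function(gm)
    log_posterior_gamma(gm, pan$X, pan$experiments, prior), numeric(1))
  lp2 <- vapply(states, function(gm)
    log_posterior_gamma(gm, X2, pan$experiments, prior), numeric(1))
  expect_equal(lp1 - lp1[1], lp2 - lp2[1], tolerance = 1e-8)
})

test_that("experiments contribute additive independent factors", {
  pan <- toy_panel(G = 20, p = 3, seed = 29, n_exp = 2)
  prior <- prior_spec(c = 2, S = 1, p_exp = 1, p = 3)
  gm <- c(1, 0, 1)
  both <- log_posterior_gamma(gm, pan$X, pan$experiments, prior)
  solo <- vapply(pan$experiments, function(e)
    log_posterior_gamma(gm, pan$X, list(e), prior), numeric(1))
  k <- sum(gm); p <- 3
  lprior_gamma <- k * log(prior$pi) + (p - k) * log(1 - prior$pi)
  expect_equal(both, sum(solo) - lprior_gamma, tolerance = 1e-10)
  # duplicating an experiment adds its contribution once more
  dup <- log_posterior_gamma(gm, pan$X,
                             c(pan$experiments, pan$experiments[1]), prior)
  expect_equal(dup, both + (solo[1] - lprior_gamma), tolerance = 1e-10)
})

test_that("exact duplicate columns raise a collinearity error", {
  pan <- toy_panel(G = 15, p = 3, seed = 31)
  Xd <- unclass(pan$X)
  Xd[, 3] <- Xd[, 2]
  X2 <- score_matrix(Xd, centered = TRUE)
  prior <- prior_spec(c = 2, S = 1, p_exp = 1, p = 3)
  expect_error(log_posterior_gamma(c(0, 1, 1), X2, pan$experiments, prior),
               "singular")
})

test_that("enumeration normalizes, exposes marginals, and finds planted MAP", {
  pan <- toy_panel(G = 40, p = 3, beta = 3, sigma = 0.05, seed = 37)
  prior <- prior_spec(c = 10, S = 0.5, p_exp = 1, p = 3)
  enum <- enumerate_posterior(pan$X, pan$experiments, prior)
  expect_equal(sum(enum$probs), 1, tolerance = 1e-12)
  expect_equal(nrow(enum$models), 8L)
  # marginal of motif j equals the sum over containing models
  for (j in 1:3)
    expect_equal(enum$marginals[[j]],
                 sum(enum$probs[enum$models[, j] == 1L]), tolerance = 1e-12)
  # noise -> 0: the generative model (only m1) is the MAP
  expect_equal(unname(enum$models[enum$map_model, ]), c(1L, 0L, 0L))
  expect_error(enumerate_posterior(pan$X, pan$experiments, prior,
                                   max_p = 2), "max_p")
})

test_that("posterior mass concentrates on the planted model as noise shrinks", {
  # fixed design and noise realization, rescaled by sigma, so the path to
  # the noiseless limit is monotone
  set.seed(41)
  G <- 40
  Xv <- matrix(rnorm(G * 3), G, 3,
               dimnames = list(sprintf("g%02d", 1:G), paste0("m", 1:3)))
  eps <- rnorm(G)
  probs <- vapply(c(2, 0.5, 0.1, 0.02), function(sg) {
    X <- score_matrix(Xv, center = TRUE)
    e <- expression_experiment(cbind(Xv[, 1] + sg * eps), "e1",
                               gene_ids = rownames(Xv))
    ctr <- center_panel(list(e), X)
    prior <- prior_spec(c = 200, S = sg^2 + 0.1, p_exp = 0.5, p = 3)
    enum <- enumerate_posterior(ctr$X, ctr$experiments, prior)
    enum$probs[apply(enum$models, 1, function(m)
      identical(unname(m), c(1L, 0L, 0L)))]
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_gt(probs[4], 0.9)
})

test_that("expression TSV round-trips including NAs", {
  vals <- matrix(c(1.5, NA, 2.5, 3, 4, 5), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("r1", "r2")))
  e <- expression_experiment(vals, "eX")
  f <- tempfile(fileext = ".tsv")
  write_expression_tsv(e, f)
  e2 <- read_expression_tsv(f, experiment_id = "eX")
  expect_equal(e2$values, e$values)
  expect_equal(e2$mask, e$mask)
})
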