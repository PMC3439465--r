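#' Species variance multipliers from a phylogenetic tree
#'
#' Computes the patristic (path-length) distance from the focal species to
#' each nearby species and converts distances to variance multipliers
#' `m_s`, which inflate the observation noise of experiments from more
#' distant species. A floor is applied to zero distances (a species
#' identical to the focal one still carries some divergence in regulatory
#' content), then multipliers are normalized to mean one so the total
#' information is comparable to the single-species case.
#'
#' @param tree a newick string, a newick file path, or an `ape::phylo`.
#' @param focal label of the focal (newly sequenced) species leaf.
#' @param species labels of the nearby species leaves.
#' @param floor minimum distance substituted before normalization
#'   (default 0.05).
#' @return list with `distances` and `multipliers`, both named by species.
#' @export
species_weights_from_tree <- function(tree, focal, species, floor = 0.05) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be newick or an ape phylo")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  leaves <- tree$tip.label
  missing <- setdiff(c(focal, species), leaves)
  if (length(missing))
    stop("leaf not found in tree: ", paste(missing, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  d <- D[focal, species]
  d_f <- pmax(d, floor)
  m <- d_f / mean(d_f)
  list(distances = setNames(as.numeric(d), species),
       multipliers = setNames(as.numeric(m), species))
}

#' Assemble a multi-species experiment panel
#'
#' @param experiments list of [expression_experiment()]s; each must carry a
#'   `species_id` matching a name of `multipliers`.
#' @param multipliers named positive multipliers `m_s` per species (see
#'   [species_weights_from_tree()]); species absent from the vector get 1.
#' @param focal_species label of the focal species (metadata).
#' @return object of class `SpeciesPanel`: list with `experiments`,
#'   `multipliers` (one per experiment, resolved by species) and
#'   `focal_species`.
#' @export
species_panel <- function(experiments, multipliers = NULL,
                          focal_species = NULL) {
  if (inherits(experiments, "ExpressionExperiment"))
    experiments <- list(experiments)
  if (!length(experiments)) stop("empty panel")
  sp <- vapply(experiments, function(e)
    if (is.null(e$species_id)) "species" else e$species_id, character(1))
  m <- rep(1, length(experiments))
  if (!is.null(multipliers)) {
    if (any(multipliers <= 0)) stop("multipliers must be positive")
    hit <- sp %in% names(multipliers)
    m[hit] <- multipliers[sp[hit]]
  }
  structure(list(experiments = experiments, species = sp,
                 multipliers = m, focal_species = focal_species),
            class = "SpeciesPanel")
}

#' Matrix-variate prior for the multi-species model
#'
#' The coefficient matrix `B_gamma` (included motifs x experiments) has a
#' matrix-normal prior with row covariance `Omega` (default the g-prior
#' analogue `c (X_gamma' X_gamma)^-1`, which makes the single-experiment
#' case collapse exactly onto the scalar model) and column covariance equal
#' to the experiment covariance `Sigma`, which carries an inverse-Wishart
#' prior `IW(delta, Q)`.
#'
#' @param c g-prior scale used when `Omega` is not supplied.
#' @param delta inverse-Wishart degrees of freedom; must be at least
#'   `E + 2` so the prior mean exists (default `E + 2`).
#' @param Q E x E positive-definite scale matrix (default `S_scale * I`).
#' @param S_scale scalar used for the default `Q`.
#' @param p_exp,p a-priori expected number of motifs and panel size, giving
#'   the Bernoulli inclusion probability `pi = p_exp / p`.
#' @param Omega optional user-supplied p x p coefficient row covariance
#'   (its gamma-submatrix is used); overrides the g-prior form.
#' @param E number of experiments (panel columns).
#' @return object of class `MatrixPrior`.
#' @export
matrix_prior <- function(c, E, delta = E + 2L, Q = NULL, S_scale = 1,
                         p_exp, p, Omega = NULL) {
  if (delta <= E + 1L) stop("delta must exceed E + 1 (got ", delta, ")")
  if (is.null(Q)) Q <- diag(S_scale, E)
  Q <- as.matrix(Q)
  if (!isTRUE(all.equal(Q, t(Q))) ||
      inherits(tryCatch(chol(Q), error = identity), "error"))
    stop("Q must be symmetric positive-definite")
  pi <- p_exp / p
  if (pi <= 0 || pi >= 1) stop("pi = p_exp/p must lie in (0, 1)")
  structure(list(c = c, E = as.integer(E), delta = delta, Q = Q,
                 p_exp = p_exp, pi = pi, Omega = Omega),
            class = "MatrixPrior")
}

#' Default matrix prior estimated from the panel
#'
#' Mirrors [default_prior()]: `c` is the variance of full-model
#' least-squares coefficients averaged over the effective experiment
#' columns, `Q = S_scale * I` with `S_scale` the mean variance of the
#' effective observations, and `delta = E + 2`.
#'
#' @param X centered [score_matrix()].
#' @param panel a [species_panel()].
#' @param p_exp a-priori expected number of included motifs.
#' @param noise optional known per-experiment variances (see
#'   [log_posterior_gamma_multi()]).
#' @return a [matrix_prior()].
#' @export
default_matrix_prior <- function(X, panel, p_exp = 3, noise = NULL) {
  eff <- effective_observations(X, panel, noise)
  Y <- eff$Y
  p <- ncol(X)
  Xm <- unclass(X)[eff$genes, , drop = FALSE]
  XtX <- crossprod(Xm)
  cs <- apply(Y, 2, function(y) {
    beta <- tryCatch(solve(XtX, crossprod(Xm, y)), error = function(e) {
      ridge <- 1e-6 * sum(diag(XtX)) / p
      solve(XtX + diag(ridge, p), crossprod(Xm, y))
    })
    if (p >= 2) var(as.numeric(beta)) else mean(beta^2)
  })
  S_scale <- mean(apply(Y, 2, var))
  if (!is.finite(S_scale) || S_scale <= 0) stop("zero data variance")
  matrix_prior(c = mean(cs), E = ncol(Y), S_scale = S_scale,
               p_exp = p_exp, p = p)
}

## Collapse the replicate/species observation layer: per experiment,
## average observed replicates per gene and rescale the column by
## sqrt(nbar_e / (m_s sigma_e^2)) (sigma_e^2 = 1 when noise is NULL, i.e.
## absorbed into the experiment covariance). Genes unobserved in any
## experiment are dropped (complete-case over the effective matrix).
effective_observations <- function(X, panel, noise = NULL) {
  stopifnot(inherits(panel, "SpeciesPanel"))
  genes <- rownames(X)
  E <- length(panel$experiments)
  if (!is.null(noise) && length(noise) != E)
    stop("noise must have one variance per experiment")
  Ybar <- matrix(NA_real_, length(genes), E)
  nobs <- matrix(0, length(genes), E)
  for (e in seq_len(E)) {
    ex <- panel$experiments[[e]]
    miss <- setdiff(ex$gene_ids, genes)
    if (length(miss))
      stop("experiment '", ex$experiment_id,
           "' has genes absent from the score matrix: ",
           paste(head(miss, 3), collapse = ", "))
    idx <- match(ex$gene_ids, genes)
    n_g <- rowSums(ex$mask)
    s_g <- rowSums(ifelse(ex$mask, ex$values, 0))
    nobs[idx, e] <- n_g
    Ybar[idx, e] <- ifelse(n_g > 0, s_g / pmax(n_g, 1L), NA_real_)
  }
  keep <- rowSums(nobs == 0) == 0L
  if (!all(keep))
    warning(sum(!keep), " gene(s) without observations in some experiment ",
            "dropped from the multi-species analysis")
  Ybar <- Ybar[keep, , drop = FALSE]
  nbar <- colMeans(nobs[keep, , drop = FALSE])
  sig2 <- if (is.null(noise)) rep(1, E) else noise
  wcol <- sqrt(nbar / (panel$multipliers * sig2))
  Y <- sweep(Ybar, 2, wcol, "*")
  ids <- vapply(panel$experiments, `[[`, character(1), "experiment_id")
  colnames(Y) <- ids
  list(Y = Y, genes = genes[keep], weights = wcol)
}

lmvgamma <- function(a, E) {
  (E * (E - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(E)) / 2))
}

#' Log posterior of gamma under the multi-species matrix-variate model
#'
#' Experiments from several species are coupled through a matrix-variate
#' model: after collapsing replicates into precision-normalized effective
#' observations (each experiment column scaled by
#' `sqrt(nbar_e / (m_s sigma_e^2))`, with the species multiplier `m_s`
#' inflating the noise of distant species), the effective G x E matrix
#' follows `Y ~ MN(X_gamma B, I_G, Sigma)` with
#' `B | Sigma ~ MN(0, Omega, Sigma)` and `Sigma ~ IW(delta, Q)`. `B` and
#' `Sigma` integrate analytically to a matrix-t marginal; with one
#' experiment, one replicate, unit multiplier and matched priors
#' (`delta = nu`, `Q = nu S`) this reduces exactly to
#' [log_posterior_gamma()]. When `noise` is `NULL` the per-experiment
#' observation variance is absorbed into `Sigma` rather than marginalized
#' separately.
#'
#' @param gamma binary inclusion vector of length p.
#' @param X centered [score_matrix()].
#' @param panel a [species_panel()] of centered experiments aligned to `X`.
#' @param prior a [matrix_prior()].
#' @param noise optional vector of known per-experiment variances
#'   `sigma_e^2` used in the precision weighting.
#' @return scalar log posterior (unnormalized).
#' @export
log_posterior_gamma_multi <- function(gamma, X, panel, prior, noise = NULL) {
  stopifnot(inherits(prior, "MatrixPrior"))
  eff <- effective_observations(X, panel, noise)
  make_log_posterior_multi(X, eff, prior)(gamma)
}

## closure over precomputed effective-observation statistics
make_log_posterior_multi <- function(X, eff, prior) {
  Y <- eff$Y
  G <- nrow(Y); E <- ncol(Y)
  if (prior$E != E) stop("prior built for E = ", prior$E,
                         " experiments, panel has ", E)
  Xm <- unclass(X)[eff$genes, , drop = FALSE]
  p <- ncol(Xm)
  XtX <- crossprod(Xm)
  XtY <- crossprod(Xm, Y)
  YtY <- crossprod(Y)
  delta <- prior$delta; Q <- prior$Q; c_ <- prior$c
  lpi <- log(prior$pi); l1mpi <- log1p(-prior$pi)
  const <- -(G * E / 2) * log(pi) + lmvgamma((delta + G) / 2, E) -
    lmvgamma(delta / 2, E) +
    (delta / 2) * as.numeric(determinant(Q)$modulus)
  Omega <- prior$Omega
  function(gamma) {
    gamma <- as.integer(gamma)
    if (length(gamma) != p) stop("gamma must have length p = ", p)
    idx <- which(gamma == 1L)
    k <- length(idx)
    lp <- k * lpi + (p - k) * l1mpi + const
    if (k == 0L) {
      Smat <- YtY
      ldetK <- 0
    } else {
      A <- XtX[idx, idx, drop = FALSE]
      B <- XtY[idx, , drop = FALSE]
      if (is.null(Omega)) {              # g-prior analogue
        R <- tryCatch(chol(A), error = function(e)
          stop("X_gamma'X_gamma numerically singular for the included motifs"))
        Z <- backsolve(R, B, transpose = TRUE)
        Smat <- YtY - (c_ / (1 + c_)) * crossprod(Z)
        ldetK <- k * log1p(c_)
      } else {
        Og <- Omega[idx, idx, drop = FALSE]
        Oinv <- solve(Og)
        M <- Oinv + A
        R <- chol(M)
        Z <- backsolve(R, B, transpose = TRUE)
        Smat <- YtY - crossprod(Z)
        ldetK <- as.numeric(determinant(Og)$modulus) +
          as.numeric(determinant(M)$modulus)
      }
    }
    lp - (E / 2) * ldetK -
      ((delta + G) / 2) * as.numeric(determinant(Q + Smat)$modulus)
  }
}

#' Pool marginal inclusion probabilities across per-species analyses
#'
#' The simple multi-species alternative: run the single-species model
#' independently per species and combine the per-motif marginals as a
#' (weighted) mean.
#'
#' @param results list of [run_search()] results (or named marginal
#'   vectors) sharing the same motif panel.
#' @param weights optional non-negative weights, one per result
#'   (normalized internally; default equal).
#' @return named vector of pooled marginals.
#' @export
pooled_marginals <- function(results, weights = NULL) {
  margs <- lapply(results, function(r)
    if (inherits(r, "SearchResult")) r$marginals else r)
  ids <- names(margs[[1]])
  same <- vapply(margs, function(m) identical(names(m), ids), logical(1))
  if (!all(same)) stop("motif panels mismatch across results")
  if (is.null(weights)) weights <- rep(1, length(margs))
  if (length(weights) != length(margs) || any(weights < 0) ||
      sum(weights) == 0)
    stop("weights must be non-negative, one per result, not all zero")
  weights <- weights / sum(weights)
  out <- numeric(length(ids))
  for (i in seq_along(margs)) out <- out + weights[i] * margs[[i]]
  setNames(out, ids)
}

#' Cross-species expression correlation of a co-regulated gene set
#'
#' Internal consistency check for borrowing expression across species: the
#' Pearson correlation of per-gene mean expression (over replicates)
#' between two experiments, across a homologous gene map. A value close to
#' one supports the assumption that the co-regulated set behaves
#' concordantly in the two species.
#'
#' @param expr_a,expr_b [expression_experiment()]s from the two species.
#' @param gene_map two-column data.frame/matrix of (gene id in a, gene id
#'   in b) homologous pairs.
#' @return correlation coefficient with attribute `"n_pairs"`.
#' @export
cross_species_correlation <- function(expr_a, expr_b, gene_map) {
  gene_map <- as.matrix(gene_map)
  if (ncol(gene_map) != 2L) stop("gene_map must have two columns")
  mean_expr <- function(e, ids) {
    idx <- match(ids, e$gene_ids)
    vapply(idx, function(i) {
      if (is.na(i)) return(NA_real_)
      v <- e$values[i, e$mask[i, ]]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  a <- mean_expr(expr_a, gene_map[, 1])
  b <- mean_expr(expr_b, gene_map[, 2])
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L)
    stop("fewer than 3 mapped gene pairs with observations in both species")
  out <- cor(a[ok], b[ok])
  attr(out, "n_pairs") <- sum(ok)
  out
}
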