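#' Construct an expression experiment
#'
#' One experiment holds a genes x replicates matrix of (log-scale)
#' expression values for one species; `NA` marks values missing on the
#' array. All sufficient statistics downstream are computed over observed
#' entries only, so genes may be missing in any subset of replicates.
#'
#' @param values numeric matrix (genes x replicates), `NA` allowed.
#' @param experiment_id label.
#' @param gene_ids gene identifiers (default rownames).
#' @param species_id optional species tag (used by the multi-species model).
#' @return object of class `ExpressionExperiment`: list with `experiment_id`,
#'   `species_id`, `gene_ids`, `values`, `mask` (TRUE = observed) and a
#'   `centered` flag.
#' @export
expression_experiment <- function(values, experiment_id = "exp",
                                  gene_ids = rownames(values),
                                  species_id = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in experiment")
  rownames(values) <- gene_ids
  obj <- list(experiment_id = experiment_id, species_id = species_id,
              gene_ids = gene_ids, values = values, mask = !is.na(values),
              centered = FALSE)
  class(obj) <- "ExpressionExperiment"
  obj
}

#' @export
print.ExpressionExperiment <- function(x, ...) {
  cat(sprintf("ExpressionExperiment '%s': %d genes x %d replicates, %d missing%s\n",
              x$experiment_id, nrow(x$values), ncol(x$values),
              sum(!x$mask), if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Center an expression panel and score matrix
#'
#' Mean-centers every replicate column of every experiment over its
#' observed entries, and mean-centers the score matrix columns over genes.
#' Centering is idempotent; the removed constants are recorded.
#'
#' @param experiments an `ExpressionExperiment` or list of them.
#' @param X a [score_matrix()].
#' @return list with elements `experiments` (all centered) and `X`
#'   (centered `ScoreMatrix`).
#' @export
center_panel <- function(experiments, X) {
  if (inherits(experiments, "ExpressionExperiment"))
    experiments <- list(experiments)
  experiments <- lapply(experiments, function(e) {
    stopifnot(inherits(e, "ExpressionExperiment"))
    nobs <- colSums(e$mask)
    if (any(nobs < 2L))
      stop("experiment '", e$experiment_id, "': replicate ",
           which(nobs < 2L)[1L], " has < 2 observed genes")
    ctr <- colSums(ifelse(e$mask, e$values, 0)) / nobs
    e$values <- sweep(e$values, 2, ctr)
    e$centering <- ctr
    e$centered <- TRUE
    e
  })
  if (!isTRUE(attr(X, "centered")))
    X <- score_matrix(unclass(X), center = TRUE,
                      floored_genes = attr(X, "floored_genes"))
  list(experiments = experiments, X = X)
}

#' Default prior specification for the selection model
#'
#' The g-prior scale `c` is set to the variance of the full-model
#' least-squares coefficients averaged over experiments (ridge-stabilized
#' when the Gram matrix is singular); the noise-prior scale `S` is the
#' sample variance of observed centered expression values averaged over
#' experiments and replicates; `nu = 3` is the smallest integer for which
#' the inverse-gamma prior mean (the expected noise level) exists; and the
#' inclusion probability is `pi = p_exp / p` with `p_exp` the number of
#' motifs expected a priori in the model.
#'
#' @param X centered [score_matrix()].
#' @param experiments centered experiment list (see [center_panel()]).
#' @param p_exp a-priori expected number of included motifs (default 3;
#'   fungal networks are driven by few motifs).
#' @param c,nu,S optional overrides of the estimated/default values.
#' @return object of class `PriorSpec`: list with `c`, `nu`, `S`, `p_exp`,
#'   `pi`.
#' @export
default_prior <- function(X, experiments, p_exp = 3, c = NULL, nu = 3,
                          S = NULL) {
  if (inherits(experiments, "ExpressionExperiment"))
    experiments <- list(experiments)
  p <- ncol(X)
  if (p_exp <= 0 || p_exp >= p)
    stop("p_exp must lie strictly between 0 and p = ", p)
  if (nu < 3) stop("nu must be >= 3 (expected noise level must exist)")
  stats <- lapply(experiments, function(e) experiment_stats(e, X))
  if (is.null(S)) {
    vars <- unlist(lapply(stats, function(st) st$rep_vars))
    S <- mean(vars)
    if (!is.finite(S) || S <= 0) stop("zero data variance")
  }
  if (is.null(c)) {
    cs <- vapply(stats, function(st) {
      A <- st$XtXw
      beta <- tryCatch(solve(A, st$Xty), error = function(e) {
        ridge <- 1e-6 * sum(diag(A)) / p
        solve(A + diag(ridge, p), st$Xty)
      })
      if (p >= 2) var(as.numeric(beta)) else mean(beta^2)
    }, numeric(1))
    c <- mean(cs)
    if (!is.finite(c) || c <= 0) stop("could not estimate g-prior scale c")
  }
  prior_spec(c = c, nu = nu, S = S, p_exp = p_exp, p = p)
}

#' @rdname default_prior
#' @param p number of candidate motifs (to derive `pi`).
#' @export
prior_spec <- function(c, nu = 3, S, p_exp, p) {
  pi <- p_exp / p
  if (pi <= 0 || pi >= 1) stop("pi = p_exp/p must lie in (0, 1)")
  if (c <= 0 || S <= 0) stop("c and S must be positive")
  structure(list(c = c, nu = as.integer(nu), S = S, p_exp = p_exp, pi = pi),
            class = "PriorSpec")
}

#' @export
print.PriorSpec <- function(x, ...) {
  cat(sprintf("PriorSpec: c=%.4g, nu=%d, S=%.4g, p_exp=%.3g (pi=%.4g)\n",
              x$c, x$nu, x$S, x$p_exp, x$pi))
  invisible(x)
}

## pooled sufficient statistics of one experiment, aligned to X's genes:
## genes absent from the experiment count as unobserved everywhere
experiment_stats <- function(e, X) {
  stopifnot(inherits(e, "ExpressionExperiment"))
  Xm <- unclass(X)
  miss <- setdiff(e$gene_ids, rownames(Xm))
  if (length(miss))
    stop("experiment '", e$experiment_id,
         "' has genes absent from the score matrix: ",
         paste(head(miss, 3), collapse = ", "))
  idx <- match(e$gene_ids, rownames(Xm))
  G <- nrow(Xm)
  w <- numeric(G)
  ysum <- numeric(G)
  vals <- ifelse(e$mask, e$values, 0)
  w[idx] <- rowSums(e$mask)
  ysum[idx] <- rowSums(vals)
  rep_vars <- vapply(seq_len(ncol(e$values)), function(r) {
    v <- e$values[e$mask[, r], r]
    if (length(v) >= 2L) var(v) else NA_real_
  }, numeric(1))
  list(XtXw = crossprod(Xm, Xm * w),
       Xty = as.numeric(crossprod(Xm, ysum)),
       yty = sum(vals^2),
       n = sum(e$mask),
       rep_vars = rep_vars[!is.na(rep_vars)])
}

## closure evaluating log p(gamma | data) up to the model-independent
## constant; caches nothing itself (callers cache by bitstring)
make_log_posterior <- function(X, experiments, prior) {
  if (inherits(experiments, "ExpressionExperiment"))
    experiments <- list(experiments)
  stopifnot(inherits(prior, "PriorSpec"))
  stats <- lapply(experiments, function(e) experiment_stats(e, X))
  p <- ncol(X)
  motif_ids <- colnames(X)
  c_ <- prior$c; nu <- prior$nu; S <- prior$S
  lpi <- log(prior$pi); l1mpi <- log1p(-prior$pi)
  shrink <- c_ / (1 + c_)
  function(gamma) {
    gamma <- as.integer(gamma)
    if (length(gamma) != p) stop("gamma must have length p = ", p)
    idx <- which(gamma == 1L)
    k <- length(idx)
    lp <- k * lpi + (p - k) * l1mpi
    for (st in stats) {
      n <- st$n
      if (k == 0L) {
        rss <- st$yty
        pen <- 0
      } else {
        A <- st$XtXw[idx, idx, drop = FALSE]
        R <- tryCatch(chol(A), error = function(err) NULL)
        if (is.null(R)) {
          dup <- motif_ids[idx][duplicated(round(t(unclass(X)[, idx]), 10))]
          stop("X_gamma'X_gamma numerically singular; collinear motifs: ",
               paste(unique(c(dup, motif_ids[idx])), collapse = ", "))
        }
        z <- backsolve(R, st$Xty[idx], transpose = TRUE)
        rss <- st$yty - shrink * sum(z^2)
        pen <- -(k / 2) * log1p(c_)
      }
      lp <- lp + pen - (n / 2) * log(2 * pi) +
        lgamma((n + nu) / 2) - lgamma(nu / 2) +
        (nu / 2) * log(nu * S / 2) -
        ((n + nu) / 2) * log((nu * S + rss) / 2)
    }
    lp
  }
}

#' Log posterior of a motif-inclusion vector
#'
#' Evaluates `log p(gamma | data)` (up to the model-independent
#' normalizing constant) for the spike-and-slab regression of expression on
#' motif scores. Per experiment e with replicates r, observed entries of
#' `y` follow `y = X_gamma beta + eps`, `eps ~ N(0, sigma_e^2)`; the
#' coefficient prior is the Zellner g-prior
#' `beta | sigma_e^2 ~ N(0, c sigma_e^2 (X_gamma' X_gamma)^-1)` (Gram
#' matrix over observed entries), the noise prior
#' `sigma_e^2 ~ Inv-Gamma(nu/2, nu S/2)`, and inclusion indicators are
#' independent Bernoulli(pi). Replicates of an experiment share
#' `sigma_e^2` and are pooled in its sufficient statistics; experiments
#' contribute independent marginal-likelihood factors with beta and
#' sigma^2 integrated analytically (a Student-type closed form). Missing
#' values enter only through the observation masks, so masking a gene is
#' exactly equivalent to deleting its row.
#'
#' @param gamma binary vector of length p (1 = motif included).
#' @param X centered [score_matrix()].
#' @param experiments centered experiment(s).
#' @param prior a [prior_spec()].
#' @return scalar log posterior (unnormalized).
#' @export
log_posterior_gamma <- function(gamma, X, experiments, prior) {
  make_log_posterior(X, experiments, prior)(gamma)
}

#' Exact posterior over all motif subsets by enumeration
#'
#' Evaluates the log posterior of every one of the `2^p` inclusion vectors
#' and normalizes. Feasible only for small candidate panels; serves as the
#' exact reference for the stochastic search.
#'
#' @inheritParams log_posterior_gamma
#' @param max_p refuse to enumerate beyond this many candidates (default 15).
#' @return list with `models` (2^p x p 0/1 matrix), `log_post`, `probs`
#'   (normalized, sum 1), `marginals` (named per-motif inclusion
#'   probabilities) and `map_model` (row index of the MAP).
#' @export
enumerate_posterior <- function(X, experiments, prior, max_p = 15L) {
  p <- ncol(X)
  if (p > max_p) stop("p = ", p, " exceeds max_p = ", max_p)
  logpost <- make_log_posterior(X, experiments, prior)
  n_mod <- 2L^p
  models <- matrix(0L, nrow = n_mod, ncol = p,
                   dimnames = list(NULL, colnames(X)))
  for (j in seq_len(p))
    models[, j] <- rep(rep(c(0L, 1L), each = 2L^(j - 1L)),
                       length.out = n_mod)
  lp <- apply(models, 1L, logpost)
  pr <- exp(lp - log_sum_exp(lp))
  pr <- pr / sum(pr)
  list(models = models, log_post = lp, probs = pr,
       marginals = setNames(as.numeric(crossprod(models, pr)), colnames(X)),
       map_model = which.max(lp))
}

#' Read an expression table (TSV) as an experiment
#'
#' Expects a header line, a first column of gene ids and one column per
#' replicate; `NA` marks missing values.
#'
#' @param path TSV file path.
#' @param experiment_id label (defaults to the file name).
#' @param species_id optional species tag.
#' @return an [expression_experiment()].
#' @export
read_expression_tsv <- function(path, experiment_id = NULL,
                                species_id = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (is.null(experiment_id))
    experiment_id <- sub("\\.(tsv|txt)$", "", basename(path))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  expression_experiment(vals, experiment_id = experiment_id,
                        species_id = species_id)
}

#' @rdname read_expression_tsv
#' @param e an `ExpressionExperiment` to write.
#' @export
write_expression_tsv <- function(e, path) {
  df <- data.frame(gene = e$gene_ids, e$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
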