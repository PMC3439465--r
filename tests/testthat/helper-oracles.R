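# Independent numerical oracles used to verify closed-form marginal
# likelihoods and matching scores. These deliberately avoid the package's
# analytic code paths: integrals are done by brute-force quadrature and
# probabilities by naive chain-rule evaluation.

log_sum_exp_h <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

simpson_weights <- function(n, h) {
  stopifnot(n %% 2L == 1L, n >= 3L)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

# log marginal likelihood of one experiment's observed entries by
# quadrature over sigma^2 (log scale) and a brute-force grid over beta.
# Z: stacked design of observed rows; y: stacked observed values.
oracle_log_marglik <- function(Z, y, prior, n_sig = 161L, n_beta = 121L) {
  n <- length(y)
  k <- if (is.null(Z)) 0L else ncol(Z)
  nu <- prior$nu; S <- prior$S; cc <- prior$c
  s2_hat <- max(sum(y^2) / max(n, 1L), S / 10)
  lo <- log(min(S, s2_hat) / 400)
  hi <- log(max(S, s2_hat) * 400)
  u <- seq(lo, hi, length.out = n_sig)
  wu <- simpson_weights(n_sig, u[2] - u[1])
  s2 <- exp(u)
  lprior_s2 <- (nu / 2) * log(nu * S / 2) - lgamma(nu / 2) -
    (nu / 2 + 1) * log(s2) - nu * S / (2 * s2) + u   # + u: d(sigma2) = s2 du
  if (k == 0L) {
    ll <- -(n / 2) * log(2 * pi * s2) - sum(y^2) / (2 * s2)
    return(log_sum_exp_h(ll + lprior_s2 + log(wu)))
  }
  ZtZ <- crossprod(Z)
  Zty <- as.numeric(crossprod(Z, y))
  yty <- sum(y^2)
  ZtZinv <- solve(ZtZ)
  bhat <- as.numeric(ZtZinv %*% Zty)
  shrink <- cc / (1 + cc)
  ldet_prior <- 0.5 * as.numeric(determinant(ZtZ / cc)$modulus)
  out <- vapply(seq_along(s2), function(i) {
    # beta grid adapted to the conditional posterior at this sigma^2
    sd_i <- sqrt(max(diag(ZtZinv)) * s2[i] * shrink)
    half <- 12 * max(sd_i, 1e-6)
    ctr <- shrink * bhat
    grids <- lapply(seq_len(k), function(j)
      seq(ctr[j] - half, ctr[j] + half, length.out = n_beta))
    wb <- simpson_weights(n_beta, grids[[1]][2] - grids[[1]][1])
    B <- as.matrix(expand.grid(grids))
    lwB <- rowSums(log(as.matrix(expand.grid(rep(list(wb), k)))))
    quadB <- rowSums((B %*% ZtZ) * B)
    rssB <- yty - 2 * as.numeric(B %*% Zty) + quadB
    priorB <- rowSums((B %*% (ZtZ / cc)) * B)   # beta' (ZtZ/c) beta
    ll <- -(n / 2) * log(2 * pi * s2[i]) - rssB / (2 * s2[i])
    lp <- -(k / 2) * log(2 * pi * s2[i]) + ldet_prior -
      priorB / (2 * s2[i])
    log_sum_exp_h(ll + lp + lwB)
  }, numeric(1))
  log_sum_exp_h(out + lprior_s2 + log(wu))
}

# oracle for the full log posterior of gamma (up to the same constant as
# the package: none - both include all normalizing factors except p(data))
oracle_log_posterior <- function(gamma, X, experiments, prior, ...) {
  Xm <- unclass(X)
  idx <- which(as.integer(gamma) == 1L)
  k <- length(idx)
  p <- ncol(Xm)
  lp <- k * log(prior$pi) + (p - k) * log(1 - prior$pi)
  for (e in experiments) {
    Zs <- list(); ys <- list()
    gidx <- match(e$gene_ids, rownames(Xm))
    for (r in seq_len(ncol(e$values))) {
      obs <- which(e$mask[, r])
      ys[[r]] <- e$values[obs, r]
      Zs[[r]] <- if (k > 0L)
        Xm[gidx[obs], idx, drop = FALSE] else NULL
    }
    Z <- if (k > 0L) do.call(rbind, Zs) else NULL
    y <- unlist(ys)
    lp <- lp + oracle_log_marglik(Z, y, prior, ...)
  }
  lp
}

# naive matching-score evaluator: enumerate windows, multiply
# probabilities position by position, chain-rule the background directly
# from the model tables
oracle_matching_score <- function(pw, sequence, bg) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  w <- pw$width
  L <- length(chars)
  total <- 0
  n_valid <- 0L
  for (st in seq_len(max(L - w + 1L, 0L))) {
    word <- chars[st:(st + w - 1L)]
    if (any(word == "N")) next
    n_valid <- n_valid + 1L
    pm <- 1
    for (j in seq_len(w)) pm <- pm * pw$probs[word[j], j]
    pb <- 1
    for (j in seq_len(w)) {
      ord <- min(j - 1L, bg$order)
      tab <- if (ord == bg$order) bg$transition else bg$lower[[ord + 1L]]
      row <- if (ord == 0L) 1L else
        paste(word[(j - ord):(j - 1L)], collapse = "")
      pb <- pb * tab[row, word[j]]
    }
    total <- total + pm / pb
  }
  if (n_valid == 0L) return(NA_real_)
  as.numeric(log2(total))
}

# matrix-t oracle: brute-force integration of the coefficient matrix B on
# a grid and the experiment covariance Sigma by quadrature, for the
# collapsed multi-species model p(Y | gamma) with the g-prior row
# covariance. Supports k = 0 or 1 included motifs and E = 1 or 2.
oracle_log_marglik_matrix <- function(Y, x, prior,
                                      n_b = 65L, n_s = 21L, n_r = 21L,
                                      s_range = 60) {
  G <- nrow(Y); E <- ncol(Y)
  delta <- prior$delta; Q <- prior$Q; cc <- prior$c
  k <- if (is.null(x)) 0L else 1L
  # inverse-Wishart log density (log-Sigma-element parametrization applied
  # by the caller through the Jacobian below)
  liw <- function(Sig) {
    as.numeric(-((delta + E + 1) / 2) * determinant(Sig)$modulus -
      0.5 * sum(diag(solve(Sig, Q))) +
      (delta / 2) * determinant(Q)$modulus -
      (delta * E / 2) * log(2) - lmvgamma_h(delta / 2, E))
  }
  ll_given <- function(Sig) {
    # integrate B (k x E grid) for fixed Sigma; k = 0 -> no integral
    Sinv <- solve(Sig)
    ldetS <- as.numeric(determinant(Sig)$modulus)
    if (k == 0L) {
      return(-(G * E / 2) * log(2 * pi) - (E / 2) * 0 - (G / 2) * ldetS -
               0.5 * sum(diag(Sinv %*% crossprod(Y))))
    }
    xtx <- sum(x^2)
    omega <- cc / xtx                      # g-prior row covariance (1x1)
    bhat <- as.numeric(crossprod(Y, x)) / xtx
    half <- 8 * sqrt(max(diag(Sig)) * max(omega, 1 / xtx))
    B <- sweep(U * half, 2, bhat, "+")     # each row: coefficients over E
    lwB <- lwU + E * log(half)
    # residual trace term: tr(Sinv (Y - x b')'(Y - x b')), vectorized in b
    YtY <- crossprod(Y); xtY <- as.numeric(crossprod(x, Y))
    BS <- B %*% Sinv
    quadB <- rowSums(BS * B)                       # b' Sinv b
    trA <- sum(diag(Sinv %*% YtY)) - 2 * as.numeric(BS %*% xtY) +
      xtx * quadB
    ll <- -(G * E / 2) * log(2 * pi) - (G / 2) * ldetS - trA / 2
    # matrix-normal prior on B (1 x E): row cov omega, col cov Sigma
    lpB <- -(E / 2) * log(2 * pi) - (E / 2) * log(omega) - ldetS / 2 -
      0.5 * quadB / omega
    log_sum_exp_h(ll + lpB + lwB)
  }
  # unit grid for the B integral (rescaled per Sigma node)
  ub <- seq(-1, 1, length.out = n_b)
  wb <- simpson_weights(n_b, ub[2] - ub[1])
  U <- as.matrix(expand.grid(rep(list(ub), E)))
  lwU <- rowSums(log(as.matrix(expand.grid(rep(list(wb), E)))))
  # Sigma parametrized as (log s1, log s2, r); E = 1 uses s1 only
  s_scale <- mean(diag(Q)) / max(delta - E - 1, 1)
  s_hat <- mean(diag(crossprod(Y))) / G
  lo <- min(s_scale, s_hat) / s_range
  hi <- max(s_scale, s_hat) * s_range
  u <- seq(log(lo), log(hi), length.out = n_s)
  wu <- simpson_weights(n_s, u[2] - u[1])
  if (E == 1L) {
    vals <- vapply(seq_along(u), function(i) {
      Sig <- matrix(exp(u[i]), 1, 1)
      ll_given(Sig) + liw(Sig) + u[i]      # Jacobian d s / d log s = s
    }, numeric(1))
    return(log_sum_exp_h(vals + log(wu)))
  }
  r <- seq(-0.985, 0.985, length.out = n_r)
  wr <- simpson_weights(n_r, r[2] - r[1])
  acc <- numeric(n_s * n_s * n_r)
  ii <- 0L
  for (i1 in seq_along(u)) for (i2 in seq_along(u)) {
    s1 <- exp(u[i1]); s2 <- exp(u[i2])
    for (ir in seq_along(r)) {
      cv <- r[ir] * sqrt(s1 * s2)
      Sig <- matrix(c(s1, cv, cv, s2), 2, 2)
      # Jacobian: d(S11,S22,S12)/d(log s1, log s2, r) = s1 s2 sqrt(s1 s2)
      lj <- 1.5 * (log(s1) + log(s2))
      ii <- ii + 1L
      acc[ii] <- ll_given(Sig) + liw(Sig) + lj +
        log(wu[i1]) + log(wu[i2]) + log(wr[ir])
    }
  }
  log_sum_exp_h(acc)
}

lmvgamma_h <- function(a, E) {
  (E * (E - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(E)) / 2))
}
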