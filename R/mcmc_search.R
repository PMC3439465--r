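#' Configuration of the stochastic model search
#'
#' Defaults follow the reference protocol of 10 parallel chains of 100,000
#' iterations each; burn-in (not part of that protocol) defaults to 10%
#' per chain.
#'
#' @param n_chains number of independent chains (default 10).
#' @param n_iter iterations per chain (default 100000).
#' @param burn_in_fraction fraction of each chain discarded (default 0.1).
#' @param seed integer seed; the whole search is deterministic given it.
#' @param move_mix probability of an add/delete (single-flip) proposal, the
#'   complement being a swap (default 0.5).
#' @param rb_thin compute the Rao-Blackwell marginal update every
#'   `rb_thin`-th kept iteration (default 1 = every kept iteration).
#' @return object of class `ChainConfig`.
#' @export
chain_config <- function(n_chains = 10L, n_iter = 100000L,
                         burn_in_fraction = 0.1, seed = 1L,
                         move_mix = 0.5, rb_thin = 1L) {
  if (n_chains < 1L || n_iter < 1L) stop("n_chains and n_iter must be >= 1")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  if (move_mix < 0 || move_mix > 1) stop("move_mix must be in [0, 1]")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in_fraction = burn_in_fraction,
                 seed = as.integer(seed), move_mix = move_mix,
                 rb_thin = as.integer(rb_thin)),
            class = "ChainConfig")
}

#' Propose a neighbouring inclusion vector
#'
#' With probability `move_mix` one uniformly chosen coordinate is flipped
#' (add/delete); otherwise one included and one excluded coordinate,
#' each chosen uniformly, exchange their states (swap). When a swap is
#' impossible (empty or full model) a flip is proposed instead. Both moves
#' are symmetric, so the Metropolis ratio needs no proposal correction.
#'
#' @param gamma binary vector.
#' @param move_mix probability of the flip move (default 0.5).
#' @return proposed binary vector (attribute `"move"` records the type).
#' @export
propose_move <- function(gamma, move_mix = 0.5) {
  p <- length(gamma)
  k <- sum(gamma)
  flip <- runif(1) < move_mix || k == 0L || k == p
  if (flip) {
    j <- sample.int(p, 1L)
    gamma[j] <- 1L - gamma[j]
    attr(gamma, "move") <- "flip"
  } else {
    ins <- which(gamma == 1L)
    outs <- which(gamma == 0L)
    i <- ins[sample.int(length(ins), 1L)]
    o <- outs[sample.int(length(outs), 1L)]
    gamma[i] <- 0L
    gamma[o] <- 1L
    attr(gamma, "move") <- "swap"
  }
  gamma
}

#' Metropolis search over motif-inclusion vectors
#'
#' Runs `n_chains` independent Metropolis chains over the inclusion vector
#' gamma, each initialized by Bernoulli(pi) draws, with add/delete and swap
#' proposals accepted with probability `min(1, exp(logpost' - logpost))`.
#' Post-burn-in iterations contribute to (i) visit counts of distinct
#' models, (ii) visit-frequency marginals, and (iii) Rao-Blackwellized
#' marginals, where the inclusion probability of motif j is averaged as the
#' exact two-point conditional `p(gamma_j = 1 | gamma_-j, data)` at each
#' kept state. Log posteriors are cached by bitstring across chains.
#'
#' @inheritParams log_posterior_gamma
#' @param config a [chain_config()].
#' @return object of class `SearchResult`: list with `visited` (data.frame:
#'   model bitstring, log posterior, visit count), `model_probs`
#'   (normalized over visited models), `marginals` (Rao-Blackwell),
#'   `marginals_freq` (visit frequency), `map_model` (0/1 vector),
#'   `acceptance` (per chain), `motif_ids`, `config`.
#' @export
run_search <- function(X, experiments, prior, config = chain_config()) {
  stopifnot(inherits(config, "ChainConfig"))
  logpost <- make_log_posterior(X, experiments, prior)
  p <- ncol(X)
  motif_ids <- colnames(X)
  set.seed(config$seed)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  visits <- new.env(hash = TRUE, parent = emptyenv())
  lp_of <- function(key, gamma) {
    v <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(v)) {
      v <- logpost(gamma)
      assign(key, v, envir = cache)
    }
    v
  }
  burn <- floor(config$burn_in_fraction * config$n_iter)
  rb_sum <- numeric(p); rb_n <- 0L
  freq_sum <- numeric(p); kept_n <- 0L
  acc <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    gamma <- NULL
    for (try in seq_len(100L)) {
      g0 <- as.integer(runif(p) < prior$pi)
      key0 <- rawToChar(as.raw(48L + g0))
      lp0 <- lp_of(key0, g0)
      if (is.finite(lp0)) { gamma <- g0; key <- key0; lp <- lp0; break }
    }
    if (is.null(gamma))
      stop("could not find a finite-posterior initial state in 100 draws")
    n_acc <- 0L
    for (t in seq_len(config$n_iter)) {
      # --- propose (symmetric): flip one coordinate, or swap in/out ---
      k <- sum(gamma)
      if (runif(1) < config$move_mix || k == 0L || k == p) {
        j <- sample.int(p, 1L)
        prop <- gamma; prop[j] <- 1L - prop[j]
      } else {
        ins <- which(gamma == 1L); outs <- which(gamma == 0L)
        prop <- gamma
        prop[ins[sample.int(k, 1L)]] <- 0L
        prop[outs[sample.int(p - k, 1L)]] <- 1L
      }
      pkey <- rawToChar(as.raw(48L + prop))
      plp <- lp_of(pkey, prop)
      if (plp >= lp || log(runif(1)) < plp - lp) {
        gamma <- prop; key <- pkey; lp <- plp
        n_acc <- n_acc + 1L
      }
      if (t > burn) {
        kept_n <- kept_n + 1L
        freq_sum <- freq_sum + gamma
        cnt <- get0(key, envir = visits, inherits = FALSE)
        assign(key, if (is.null(cnt)) 1L else cnt + 1L, envir = visits)
        if (kept_n %% config$rb_thin == 0L) {
          cond <- numeric(p)
          for (j in seq_len(p)) {
            g1 <- gamma; g1[j] <- 1L
            g0 <- gamma; g0[j] <- 0L
            lp1 <- if (gamma[j] == 1L) lp else
              lp_of(rawToChar(as.raw(48L + g1)), g1)
            lp0 <- if (gamma[j] == 0L) lp else
              lp_of(rawToChar(as.raw(48L + g0)), g0)
            cond[j] <- 1 / (1 + exp(lp0 - lp1))
          }
          rb_sum <- rb_sum + cond
          rb_n <- rb_n + 1L
        }
      }
    }
    acc[ch] <- n_acc / config$n_iter
  }
  keys <- ls(visits)
  counts <- vapply(keys, function(k) get(k, envir = visits), integer(1))
  lps <- vapply(keys, function(k) get(k, envir = cache), numeric(1))
  pr <- exp(lps - log_sum_exp(lps))
  pr <- pr / sum(pr)
  map_key <- keys[which.max(lps)]
  res <- list(
    visited = data.frame(model = keys, log_post = lps, count = counts,
                         row.names = NULL, stringsAsFactors = FALSE),
    model_probs = setNames(pr, keys),
    marginals = setNames(rb_sum / max(rb_n, 1L), motif_ids),
    marginals_freq = setNames(freq_sum / max(kept_n, 1L), motif_ids),
    map_model = setNames(as.integer(strsplit(map_key, "")[[1]]), motif_ids),
    acceptance = acc,
    motif_ids = motif_ids,
    config = config)
  class(res) <- "SearchResult"
  res
}

#' @export
print.SearchResult <- function(x, ...) {
  cat(sprintf(paste0("SearchResult: %d distinct models visited ",
                     "(%d chains x %d iterations, mean acceptance %.2f)\n"),
              nrow(x$visited), x$config$n_chains, x$config$n_iter,
              mean(x$acceptance)))
  top <- head(sort(x$marginals, decreasing = TRUE), 5L)
  cat("Top marginals:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Select motifs by marginal inclusion probability
#'
#' Returns the motifs whose Rao-Blackwellized marginal inclusion
#' probability exceeds `threshold` (0.5 by convention; lower values such as
#' 0.3 can be used when motif effects are expected to be diluted), sorted
#' by decreasing marginal. The MAP model is reported separately as an
#' attribute.
#'
#' @param result a [run_search()] result.
#' @param threshold marginal probability cutoff in `[0, 1]` (default 0.5).
#' @return data.frame with columns `motif` and `marginal`, sorted
#'   descending; attribute `"map_model"` carries the MAP inclusion vector.
#' @export
select_motifs <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "SearchResult"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  m <- result$marginals
  sel <- m[m > threshold]
  if (!length(sel))
    message("no motif exceeds marginal threshold ", threshold)
  out <- data.frame(motif = names(sort(sel, decreasing = TRUE)),
                    marginal = as.numeric(sort(sel, decreasing = TRUE)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "map_model") <- result$map_model
  out
}
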