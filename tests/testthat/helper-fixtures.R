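# Small in-code fixtures shared across tests.

random_promoters <- function(n = 4, len = 120, seed = 1,
                             freqs = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE, prob = freqs),
                             collapse = ""))
  promoter_set(setNames(seqs, sprintf("g%02d", seq_len(n))),
               species_id = "toy")
}

toy_background <- function(order = 1, seed = 2, pseudocount = 0.5) {
  suppressWarnings(fit_markov_background(
    random_promoters(n = 5, len = 300, seed = seed),
    order = order, pseudocount = pseudocount))
}

random_pwm <- function(w, seed = NULL, id = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- matrix(rexp(4 * w), 4)
  pwm(sweep(pr, 2, colSums(pr), "/"), id = id)
}

# tiny regression panel with known structure: G genes, p candidate columns,
# gaussian scores, y driven by the first column
toy_panel <- function(G = 30, p = 4, beta = 2, sigma = 0.5, seed = 3,
                      n_rep = 1, n_exp = 1, miss = 0) {
  set.seed(seed)
  Xv <- matrix(rnorm(G * p), G, p,
               dimnames = list(sprintf("g%02d", seq_len(G)),
                               paste0("m", seq_len(p))))
  X <- score_matrix(Xv, center = TRUE)
  exps <- lapply(seq_len(n_exp), function(e) {
    vals <- matrix(beta * Xv[, 1], G, n_rep) +
      matrix(rnorm(G * n_rep, sd = sigma), G, n_rep)
    if (miss > 0) vals[runif(length(vals)) < miss] <- NA
    expression_experiment(vals, sprintf("e%d", e),
                          gene_ids = rownames(Xv), species_id = "sp1")
  })
  ctr <- center_panel(exps, X)
  list(X = ctr$X, experiments = ctr$experiments)
}
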