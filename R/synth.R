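#' Specification of a synthetic benchmark panel
#'
#' Defines the study conditions for the synthetic generator: promoters
#' drawn from a background base composition with binding sites of the true
#' motifs planted in the co-regulated genes, and expression generated from
#' the linear model `y_ger = sum_j beta_j X_gj + eps`,
#' `eps ~ N(0, sigma_e^2 m_s)`, independently per replicate.
#'
#' The defaults are the package's reference benchmark: 100 genes of which
#' 30 are co-regulated, 25 candidate motifs of widths 5-12 of which 2 are
#' causal with effect sizes +1 and -1, 3 single-replicate experiments with
#' noise sd 0.3, promoters of 500 nt with a mildly AT-rich composition,
#' and no missing data.
#'
#' @param n_genes total genes G (default 100).
#' @param n_coregulated genes receiving planted sites (default 30).
#' @param n_candidates size of the candidate motif panel (default 25); used
#'   only when `motif_panel` is `NULL`, in which case random-consensus PWMs
#'   (focus 0.85) of widths cycling through 5..12 are generated.
#' @param motif_panel optional list of [pwm()]s or consensus strings.
#' @param true_motifs indices of the causal motifs (default `c(3, 4)`,
#'   which under the default width cycle are the width-7 and width-8
#'   candidates - typical binding-site core widths; very short planted
#'   patterns are poorly identifiable from matching scores).
#' @param beta effect sizes of the causal motifs (default `c(1, -1)`).
#' @param n_experiments number of experiments E (default 3).
#' @param replicates replicates per experiment (recycled; default 1).
#' @param noise_sd per-experiment noise sd `sigma_e` (recycled; default 0.3).
#' @param species data.frame with columns `species_id` and `multiplier`
#'   (default one species, multiplier 1); experiments are assigned to
#'   species round-robin.
#' @param missing_fraction completely-at-random missingness (default 0).
#' @param base_freqs background base composition A, C, G, T used to draw
#'   promoters (default `c(0.3, 0.2, 0.2, 0.3)`).
#' @param fit_order Markov order used when fitting the scoring background
#'   on the generated promoters (default 2; fixture-scale data cannot
#'   support the genome-scale order 6).
#' @param promoter_length promoter length L in nt (default 500).
#' @param seed generator seed.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_genes = 100L, n_coregulated = 30L,
                           n_candidates = 25L, motif_panel = NULL,
                           true_motifs = c(3L, 4L), beta = c(1, -1),
                           n_experiments = 3L, replicates = 1L,
                           noise_sd = 0.3, species = NULL,
                           missing_fraction = 0,
                           base_freqs = c(0.3, 0.2, 0.2, 0.3),
                           fit_order = 2L, promoter_length = 500L,
                           seed = 1L) {
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  if (length(beta) != length(true_motifs))
    stop("beta must have one effect per true motif")
  if (is.null(species))
    species <- data.frame(species_id = "sp1", multiplier = 1)
  if (any(species$multiplier <= 0)) stop("multipliers must be positive")
  base_freqs <- base_freqs / sum(base_freqs)
  spec <- list(n_genes = as.integer(n_genes),
               n_coregulated = as.integer(n_coregulated),
               n_candidates = as.integer(n_candidates),
               motif_panel = motif_panel,
               true_motifs = as.integer(true_motifs), beta = beta,
               n_experiments = as.integer(n_experiments),
               replicates = rep_len(as.integer(replicates), n_experiments),
               noise_sd = rep_len(noise_sd, n_experiments),
               species = species, missing_fraction = missing_fraction,
               base_freqs = base_freqs, fit_order = as.integer(fit_order),
               promoter_length = as.integer(promoter_length),
               seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  spec
}

## materialize the motif panel as PWMs (generating random-consensus PWMs
## where needed); deterministic given the spec seed
panel_pwms <- function(spec) {
  if (!is.null(spec$motif_panel)) {
    pwms <- lapply(seq_along(spec$motif_panel), function(i) {
      m <- spec$motif_panel[[i]]
      if (inherits(m, "PWM")) m
      else pwm_from_consensus(m, id = sprintf("m%02d_%s", i, m))
    })
    return(pwms)
  }
  set.seed(spec$seed + 77L)
  widths <- rep_len(5:12, spec$n_candidates)
  seen <- character(0)
  pwms <- vector("list", spec$n_candidates)
  for (i in seq_len(spec$n_candidates)) {
    repeat {
      cons <- paste(sample(BASES, widths[i], replace = TRUE), collapse = "")
      if (!cons %in% seen) break
    }
    seen <- c(seen, cons)
    pwms[[i]] <- pwm_from_consensus(cons, focus = 0.85,
                                    id = sprintf("m%02d_%s", i, cons))
  }
  pwms
}

#' Generate synthetic promoter sequences with planted sites
#'
#' Draws promoters i.i.d. from the spec's base composition and, for each
#' co-regulated gene, plants one site per true motif (sampled from the
#' motif's PWM, not its consensus) at a uniformly chosen, non-overlapping
#' position. Ground-truth plant positions are returned.
#'
#' @param spec a [synthetic_spec()].
#' @param species_id which species' promoters to generate (default the
#'   first in the spec).
#' @return a [promoter_set()] with attribute `"plants"` (data.frame: gene,
#'   motif, position, site) and attribute `"pwms"` (the materialized
#'   candidate panel).
#' @export
generate_promoters <- function(spec, species_id = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  pwms <- panel_pwms(spec)
  if (is.null(species_id)) species_id <- spec$species$species_id[1]
  sp_off <- match(species_id, spec$species$species_id)
  if (is.na(sp_off)) stop("unknown species_id: ", species_id)
  set.seed(spec$seed + 131L * sp_off)
  L <- spec$promoter_length
  widths <- vapply(pwms[spec$true_motifs], `[[`, integer(1), "width")
  if (sum(widths) > L)
    stop("promoter_length too short for the planted sites")
  G <- spec$n_genes
  seq_mat <- matrix(sample.int(4L, G * L, replace = TRUE,
                               prob = spec$base_freqs), nrow = G)
  plants <- list()
  for (g in seq_len(spec$n_coregulated)) {
    taken <- integer(0)
    for (ti in seq_along(spec$true_motifs)) {
      pw <- pwms[[spec$true_motifs[ti]]]
      w <- pw$width
      site <- vapply(seq_len(w), function(j)
        sample.int(4L, 1L, prob = pw$probs[, j]), integer(1))
      for (attempt in seq_len(200L)) {
        pos <- sample.int(L - w + 1L, 1L)
        if (!any(seq.int(pos, pos + w - 1L) %in% taken)) break
        if (attempt == 200L) stop("could not place non-overlapping site; ",
                                  "promoter_length too short")
      }
      taken <- c(taken, seq.int(pos, pos + w - 1L))
      seq_mat[g, seq.int(pos, pos + w - 1L)] <- site
      plants[[length(plants) + 1L]] <-
        data.frame(gene = g, motif = pw$id, position = pos,
                   site = paste(BASES[site], collapse = ""),
                   stringsAsFactors = FALSE)
    }
  }
  seqs <- apply(seq_mat, 1, function(r) paste(BASES[r], collapse = ""))
  ps <- promoter_set(seqs, gene_ids = sprintf("gene%03d", seq_len(G)),
                     species_id = species_id, max_length = max(1000L, L))
  attr(ps, "plants") <- if (length(plants)) do.call(rbind, plants) else
    data.frame(gene = integer(0), motif = character(0),
               position = integer(0), site = character(0))
  attr(ps, "pwms") <- pwms
  ps
}

#' Generate synthetic expression experiments from a score matrix
#'
#' Applies the linear model `y_ger = sum_j beta_j X_gj + eps` with
#' `eps ~ N(0, sigma_e^2 m_s)` independently per replicate, then masks
#' entries completely at random at the spec's `missing_fraction`.
#'
#' @param spec a [synthetic_spec()].
#' @param X [score_matrix()] built from the generated promoters (its motif
#'   columns must include the true motifs).
#' @return list of [expression_experiment()]s with species tags; attribute
#'   `"truth"` carries the full-length `beta` and `gamma` vectors.
#' @export
generate_expression <- function(spec, X) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  Xm <- unclass(X)
  if (nrow(Xm) != spec$n_genes)
    stop("dimension mismatch: X has ", nrow(Xm), " genes, spec expects ",
         spec$n_genes)
  pwms <- panel_pwms(spec)
  ids <- vapply(pwms, `[[`, character(1), "id")
  true_ids <- ids[spec$true_motifs]
  if (!all(true_ids %in% colnames(Xm)))
    stop("X lacks columns for the true motifs")
  beta_full <- setNames(numeric(ncol(Xm)), colnames(Xm))
  beta_full[true_ids] <- spec$beta
  mu <- as.numeric(Xm %*% beta_full)
  set.seed(spec$seed + 997L)
  sp_of_exp <- rep_len(seq_len(nrow(spec$species)), spec$n_experiments)
  exps <- vector("list", spec$n_experiments)
  for (e in seq_len(spec$n_experiments)) {
    R <- spec$replicates[e]
    sd_e <- spec$noise_sd[e] *
      sqrt(spec$species$multiplier[sp_of_exp[e]])
    vals <- matrix(mu, nrow = spec$n_genes, ncol = R) +
      matrix(rnorm(spec$n_genes * R, sd = sd_e), ncol = R)
    if (spec$missing_fraction > 0) {
      drop <- matrix(runif(length(vals)) < spec$missing_fraction,
                     nrow = nrow(vals))
      # keep at least 2 observations per replicate for centering
      for (r in seq_len(R)) {
        obs <- which(!drop[, r])
        if (length(obs) < 2L) drop[seq_len(2L), r] <- FALSE
      }
      vals[drop] <- NA_real_
    }
    rownames(vals) <- rownames(Xm)
    exps[[e]] <- expression_experiment(
      vals, experiment_id = sprintf("exp%d", e),
      species_id = spec$species$species_id[sp_of_exp[e]])
  }
  attr(exps, "truth") <- list(beta = beta_full,
                              gamma = as.integer(beta_full != 0),
                              true_ids = true_ids)
  exps
}

#' Generate a complete synthetic panel (promoters, scores, expression)
#'
#' Convenience wrapper: generates promoters with planted sites, fits the
#' scoring background on them at the spec's `fit_order`, builds the
#' centered score matrix for the candidate panel, and generates expression
#' from the (uncentered) scores.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `promoters`, `bg`, `pwms`, `X` (centered
#'   `ScoreMatrix`), `X_raw` (uncentered), `experiments` (centered), and
#'   `truth`.
#' @export
simulate_panel <- function(spec) {
  promoters <- generate_promoters(spec)
  bg <- suppressWarnings(
    fit_markov_background(promoters, order = spec$fit_order,
                          pseudocount = 0.5))
  pwms <- attr(promoters, "pwms")
  X_raw <- build_score_matrix(pwms, promoters, bg, center = FALSE)
  experiments <- generate_expression(spec, X_raw)
  truth <- attr(experiments, "truth")
  ctr <- center_panel(experiments, X_raw)
  list(promoters = promoters, bg = bg, pwms = pwms,
       X = ctr$X, X_raw = X_raw, experiments = ctr$experiments,
       truth = truth, plants = attr(promoters, "plants"))
}
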