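#' Robustness / sensitivity protocol plan
#'
#' Describes the sweep used to probe the stability of motif selection:
#' random control-gene subsets (default 8 subsets of 200 genes), optional
#' leave-one-out folds over experiments, and a grid of sparsity settings
#' `p_exp` (default 3, 5, 8 - fungal regulation relies on few motifs).
#' Marginal probabilities averaged over the control subsets are the
#' reported quantity.
#'
#' @param n_control_subsets number of control-gene subsets (default 8).
#' @param subset_size genes per subset (default 200).
#' @param p_exp_grid sparsity grid (default `c(3, 5, 8)`).
#' @param loo_over_experiments repeat per leave-one-out experiment fold
#'   (default `TRUE`).
#' @param seed master seed; per-run seeds are spawned deterministically.
#' @param n_chains,n_iter,burn_in_fraction,rb_thin chain settings for the
#'   inner searches (defaults follow [chain_config()]).
#' @return object of class `RobustnessPlan`.
#' @export
robustness_plan <- function(n_control_subsets = 8L, subset_size = 200L,
                            p_exp_grid = c(3, 5, 8),
                            loo_over_experiments = TRUE, seed = 1L,
                            n_chains = 10L, n_iter = 100000L,
                            burn_in_fraction = 0.1, rb_thin = 1L) {
  if (!length(p_exp_grid)) stop("p_exp_grid must be non-empty")
  if (n_control_subsets < 1L || subset_size < 1L)
    stop("n_control_subsets and subset_size must be >= 1")
  structure(list(n_control_subsets = as.integer(n_control_subsets),
                 subset_size = as.integer(subset_size),
                 p_exp_grid = p_exp_grid,
                 loo_over_experiments = isTRUE(loo_over_experiments),
                 seed = as.integer(seed),
                 n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in_fraction = burn_in_fraction,
                 rb_thin = as.integer(rb_thin)),
            class = "RobustnessPlan")
}

#' Stratified sample of control genes
#'
#' Samples `size` genes from a labelled pool so that each group (functional
#' or phylogenetic stratum) contributes proportionally to its size, with
#' largest-remainder rounding of the quotas (ties broken by group order of
#' first appearance), then samples without replacement within groups.
#'
#' @param gene_ids character vector of candidate control genes.
#' @param groups stratum label per gene (same length as `gene_ids`).
#' @param size total number of genes to draw (`<= length(gene_ids)`).
#' @param seed optional seed; given the seed the draw is deterministic.
#' @return character vector of sampled gene ids.
#' @export
sample_control_genes <- function(gene_ids, groups = NULL, size,
                                 seed = NULL) {
  if (!length(gene_ids)) stop("empty control pool")
  if (size > length(gene_ids))
    stop("size (", size, ") exceeds pool size (", length(gene_ids), ")")
  if (is.null(groups)) groups <- rep("all", length(gene_ids))
  if (length(groups) != length(gene_ids))
    stop("groups must have one label per gene")
  if (!is.null(seed)) set.seed(seed)
  glev <- unique(groups)                 # order of first appearance
  n_g <- vapply(glev, function(g) sum(groups == g), integer(1))
  quota <- size * n_g / length(gene_ids)
  base <- floor(quota)
  rem <- size - sum(base)
  if (rem > 0) {
    frac <- quota - base
    room <- n_g - base
    ord <- order(-frac)                  # stable: ties keep group order
    for (i in ord) {
      if (rem == 0L) break
      if (room[i] > 0L) { base[i] <- base[i] + 1L; rem <- rem - 1L }
    }
  }
  out <- character(0)
  for (i in seq_along(glev)) {
    ids <- gene_ids[groups == glev[i]]
    if (base[i] > 0L)
      out <- c(out, ids[sample.int(length(ids), base[i])])
  }
  out
}

## deterministic per-run seed spawned from the master seed (kept < 2^31)
spawn_seed <- function(master, index) {
  as.integer((as.numeric(master) * 10007 + index * 7919) %% 2147483647)
}

subset_experiment <- function(e, genes) {
  keep <- e$gene_ids %in% genes
  e$values <- e$values[keep, , drop = FALSE]
  e$mask <- e$mask[keep, , drop = FALSE]
  e$gene_ids <- e$gene_ids[keep]
  e$centered <- FALSE
  e
}

#' Run the robustness protocol
#'
#' For each control subset x leave-one-out fold x sparsity value, rebuilds
#' the gene panel (co-regulated genes plus the control subset), re-centers,
#' re-estimates the prior and reruns the stochastic search; failed inner
#' runs are logged and excluded from averages. The reported quantity is the
#' per-motif marginal averaged over control subsets, with per-fold and
#' per-`p_exp` breakdowns retained.
#'
#' @param x_builder function taking a character vector of gene ids and
#'   returning the (uncentered) [score_matrix()] for those genes.
#' @param experiments list of [expression_experiment()]s covering the full
#'   gene panel.
#' @param plan a [robustness_plan()].
#' @param coreg_genes ids of the co-regulated gene set (always included).
#' @param control_pool ids of the available control genes.
#' @param control_groups stratum label per control gene (optional).
#' @return object of class `RobustnessResult`: list with `runs` (tidy
#'   data.frame: subset, fold, p_exp, motif, marginal), `averaged`
#'   (mean over subsets per motif x fold x p_exp), `overall` (mean per
#'   motif over all successful runs), `n_runs`, `failures`.
#' @export
run_robustness <- function(x_builder, experiments, plan, coreg_genes,
                           control_pool, control_groups = NULL) {
  stopifnot(inherits(plan, "RobustnessPlan"))
  if (inherits(experiments, "ExpressionExperiment"))
    experiments <- list(experiments)
  E <- length(experiments)
  if (plan$loo_over_experiments && E < 2L)
    stop("leave-one-out requires at least 2 experiments")
  folds <- if (plan$loo_over_experiments) seq_len(E) else 0L
  rows <- list()
  failures <- character(0)
  run_idx <- 0L
  for (ss in seq_len(plan$n_control_subsets)) {
    ctrl <- sample_control_genes(control_pool, control_groups,
                                 plan$subset_size,
                                 seed = spawn_seed(plan$seed, ss))
    panel_genes <- c(coreg_genes, ctrl)
    for (f in folds) {
      keep_exp <- if (f == 0L) experiments else experiments[-f]
      for (pe in plan$p_exp_grid) {
        run_idx <- run_idx + 1L
        res <- tryCatch({
          X <- x_builder(panel_genes)
          exps <- lapply(keep_exp, subset_experiment, genes = panel_genes)
          ctr <- center_panel(exps, X)
          prior <- default_prior(ctr$X, ctr$experiments, p_exp = pe)
          cfg <- chain_config(n_chains = plan$n_chains,
                              n_iter = plan$n_iter,
                              burn_in_fraction = plan$burn_in_fraction,
                              rb_thin = plan$rb_thin,
                              seed = spawn_seed(plan$seed, 1000L + run_idx))
          run_search(ctr$X, ctr$experiments, prior, cfg)
        }, error = function(err) err)
        if (inherits(res, "error")) {
          failures <- c(failures,
                        sprintf("subset %d fold %d p_exp %g: %s",
                                ss, f, pe, conditionMessage(res)))
          next
        }
        rows[[length(rows) + 1L]] <-
          data.frame(subset = ss, fold = f, p_exp = pe,
                     motif = names(res$marginals),
                     marginal = as.numeric(res$marginals),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    stop("all inner runs failed; first failure: ", failures[1])
  runs <- do.call(rbind, rows)
  averaged <- aggregate(marginal ~ motif + fold + p_exp, data = runs, mean)
  overall <- aggregate(marginal ~ motif, data = runs, mean)
  out <- list(runs = runs, averaged = averaged,
              overall = setNames(overall$marginal, overall$motif),
              n_runs = run_idx, n_success = length(rows),
              failures = failures, plan = plan)
  class(out) <- "RobustnessResult"
  out
}

#' @export
print.RobustnessResult <- function(x, ...) {
  cat(sprintf("RobustnessResult: %d/%d inner runs succeeded\n",
              x$n_success, x$n_runs))
  top <- head(sort(x$overall, decreasing = TRUE), 5L)
  cat("Top subset-averaged marginals:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
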