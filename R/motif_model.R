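#' Construct a position weight matrix (PWM)
#'
#' A motif is represented by a 4 x w column-stochastic matrix of
#' per-position base probabilities. The consensus is the per-column argmax
#' base, ties broken alphabetically.
#'
#' @param probs 4 x w numeric matrix, rows in order A, C, G, T; each column
#'   must sum to one.
#' @param id motif identifier; defaults to the consensus string.
#' @param source `"discovered"` or `"supplied"`.
#' @return object of class `PWM`: list with `probs`, `width`, `consensus`,
#'   `id`, `source`.
#' @export
pwm <- function(probs, id = NULL, source = c("supplied", "discovered")) {
  source <- match.arg(source)
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A, C, G, T)")
  if (any(probs < 0)) stop("probs must be non-negative")
  csum <- colSums(probs)
  if (any(abs(csum - 1) > 1e-12))
    stop("each PWM column must sum to 1 (max deviation ",
         format(max(abs(csum - 1))), ")")
  rownames(probs) <- BASES
  consensus <- paste(BASES[apply(probs, 2, which.max)], collapse = "")
  if (is.null(id)) id <- consensus
  obj <- list(probs = probs, width = ncol(probs), consensus = consensus,
              id = id, source = source)
  class(obj) <- "PWM"
  obj
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d, %s), consensus %s\n",
              x$id, x$width, x$source, x$consensus))
  invisible(x)
}

#' Build a PWM from a consensus string
#'
#' Convenience constructor placing probability `focus` on the consensus
#' base at each position and `(1 - focus)/3` elsewhere.
#'
#' @param consensus DNA string over A, C, G, T.
#' @param focus probability of the consensus base per column (default 0.85).
#' @param id motif identifier.
#' @return a [pwm()].
#' @export
pwm_from_consensus <- function(consensus, focus = 0.85, id = consensus) {
  codes <- encode_seq(toupper(consensus))
  if (anyNA(codes)) stop("consensus must contain only A, C, G, T")
  probs <- matrix((1 - focus) / 3, nrow = 4L, ncol = length(codes))
  probs[cbind(codes, seq_along(codes))] <- focus
  pwm(probs, id = id)
}

## estimate a PWM from aligned site sequences (integer code matrix,
## n_sites x w) with add-pseudocount smoothing
pwm_from_sites <- function(site_codes, pseudocount = 0.5, id = NULL) {
  w <- ncol(site_codes)
  counts <- vapply(seq_len(w), function(j)
    tabulate(site_codes[, j], nbins = 4L), numeric(4))
  counts <- counts + pseudocount
  pwm(sweep(counts, 2, colSums(counts), "/"), id = id, source = "discovered")
}

log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log motif probability of every width-w window (NA where window has N)
pwm_window_logprobs <- function(pwm_obj, codes) {
  w <- pwm_obj$width
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_win <- L - w + 1L
  lp <- log(pwm_obj$probs)               # -Inf allowed for zero entries
  out <- numeric(n_win)
  has_na <- rep(FALSE, n_win)
  for (j in seq_len(w)) {
    base <- codes[seq_len(n_win) + j - 1L]
    has_na <- has_na | is.na(base)
    term <- rep(0, n_win)
    term[!is.na(base)] <- lp[cbind(base[!is.na(base)], j)]
    out <- out + term
  }
  out[has_na] <- NA_real_
  out
}

#' Matching score of a motif against a promoter sequence
#'
#' The matching score of motif m against gene g is
#' \deqn{S_{mg} = \log_2 \sum_{x \in A_g} \frac{P(x \mid \Theta_m)}
#'   {P(x \mid \Theta_0)}}{S = log2 sum_x P(x|motif)/P(x|background)}
#' where \eqn{A_g} is the set of all N-free width-w windows of the
#' promoter, \eqn{\Theta_m} the motif probability matrix (product of column
#' probabilities) and \eqn{\Theta_0} the Markov background. The provided
#' strand only is scanned (set `both_strands = TRUE` to also scan the
#' reverse complement when orientation is unresolved).
#'
#' @param pwm a [pwm()].
#' @param sequence DNA string over A, C, G, T, N (or a pre-encoded integer
#'   vector as produced internally).
#' @param bg a [fit_markov_background()] model.
#' @param both_strands also scan the reverse complement (default `FALSE`).
#' @param floor_score score assigned when the sequence has no N-free window
#'   of the motif's width (default `log2(.Machine$double.xmin)`); such genes
#'   are flagged via the `"floored"` attribute.
#' @return scalar score (log2 scale); attribute `"floored"` is `TRUE` when
#'   the floor was applied.
#' @export
matching_score <- function(pwm, sequence, bg, both_strands = FALSE,
                           floor_score = log2(.Machine$double.xmin)) {
  stopifnot(inherits(pwm, "PWM"), inherits(bg, "BackgroundModel"))
  codes <- if (is.numeric(sequence)) sequence else encode_seq(toupper(sequence))
  lr <- window_log2_ratios(pwm, codes, bg)
  if (both_strands) {
    rc <- rev(ifelse(is.na(codes), NA_integer_, 5L - codes))
    lr <- c(lr, window_log2_ratios(pwm, rc, bg))
  }
  lr <- lr[!is.na(lr)]
  if (!length(lr)) {
    out <- floor_score
    attr(out, "floored") <- TRUE
    return(out)
  }
  m <- max(lr)
  out <- if (!is.finite(m)) m else m + log2(sum(2^(lr - m)))
  # all-zero motif probabilities across every window also floor the score
  if (!is.finite(out)) {
    out <- floor_score
    attr(out, "floored") <- TRUE
    return(out)
  }
  attr(out, "floored") <- FALSE
  out
}

## per-window log2 likelihood ratios; NA for windows containing N
window_log2_ratios <- function(pwm_obj, codes, bg) {
  lp_m <- pwm_window_logprobs(pwm_obj, codes)
  if (!length(lp_m)) return(numeric(0))
  lp_b <- bg_window_logprobs(bg, codes, pwm_obj$width)
  if (any(!is.na(lp_b) & !is.finite(lp_b)))
    stop("zero background probability for some window; ",
         "fit the background with a positive pseudocount")
  (lp_m - lp_b) / log(2)
}

#' Build the gene-by-motif matching score matrix
#'
#' Scores every motif against every promoter and optionally mean-centers
#' each column over genes, as assumed by the regression model.
#'
#' @param pwms list of [pwm()] objects with unique ids.
#' @param promoters a [promoter_set()].
#' @param bg background model.
#' @param center mean-center columns over genes (default `TRUE`).
#' @param ... passed to [matching_score()].
#' @return object of class `ScoreMatrix`: a G x p numeric matrix with gene
#'   ids as rownames, motif ids as colnames, and attributes `centered`,
#'   `column_centers` and `floored_genes`.
#' @export
build_score_matrix <- function(pwms, promoters, bg, center = TRUE, ...) {
  stopifnot(inherits(promoters, "PromoterSet"))
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  if (length(pwms) == 0L) stop("empty motif list")
  ids <- vapply(pwms, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate motif ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  codes <- lapply(promoters$sequences, encode_seq)
  vals <- matrix(NA_real_, nrow = length(codes), ncol = length(pwms),
                 dimnames = list(promoters$gene_ids, ids))
  floored <- character(0)
  for (m in seq_along(pwms)) {
    for (g in seq_along(codes)) {
      s <- matching_score(pwms[[m]], codes[[g]], bg, ...)
      if (isTRUE(attr(s, "floored")))
        floored <- union(floored, promoters$gene_ids[g])
      vals[g, m] <- as.numeric(s)
    }
  }
  if (length(floored))
    warning("floor score used for gene(s) without valid windows: ",
            paste(floored, collapse = ", "))
  score_matrix(vals, centered = FALSE, floored_genes = floored,
               center = center)
}

#' Construct / re-center a ScoreMatrix
#'
#' @param values G x p numeric matrix with gene rownames and motif colnames.
#' @param centered are the columns already centered?
#' @param floored_genes genes whose scores were floored.
#' @param center center the columns now?
#' @return a `ScoreMatrix`.
#' @export
score_matrix <- function(values, centered = FALSE, floored_genes = character(0),
                         center = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  if (!all(is.finite(values))) stop("score matrix must be finite")
  centers <- rep(0, ncol(values))
  if (center) {
    centers <- colMeans(values)
    values <- sweep(values, 2, centers)
    centered <- TRUE
  }
  structure(values, class = c("ScoreMatrix", "matrix", "array"),
            centered = centered, column_centers = centers,
            floored_genes = floored_genes)
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d genes x %d motifs (%scentered)\n",
              nrow(x), ncol(x), if (isTRUE(attr(x, "centered"))) "" else "not "))
  invisible(x)
}

#' Discover candidate motifs by seed enumeration and refinement
#'
#' A seed-and-refine enumerator in the spirit of word-enumeration motif
#' finders: for each width, every N-free w-mer occurring in the promoters
#' seeds a candidate; the windows within Hamming distance `ceiling(w/4)` of
#' the seed form its site set; a PWM is estimated from the sites
#' (pseudocount 0.5) and refined by re-collecting the positive
#' log-likelihood-ratio windows and re-estimating; candidates are
#' deduplicated by consensus and ranked per width by their total
#' log-likelihood ratio over sites.
#'
#' @param promoters a [promoter_set()] (typically the co-regulated genes).
#' @param bg background model.
#' @param widths integer vector of motif widths (default 5:12; admissible
#'   range 3..20).
#' @param top_k maximum number of candidates returned per width (default 30).
#' @param refine_iters refinement iterations (default 3).
#' @param min_sites seeds matched by fewer sites are dropped (default 2).
#' @return list of [pwm()] objects (ids `w<width>_<rank>`), each with an
#'   `enrichment` element.
#' @export
discover_candidates <- function(promoters, bg, widths = 5:12, top_k = 30L,
                                refine_iters = 3L, min_sites = 2L) {
  stopifnot(inherits(promoters, "PromoterSet"))
  if (length(promoters$sequences) == 0L) stop("empty promoters")
  if (any(widths < 3L | widths > 20L)) stop("widths must be within 3..20")
  if (top_k < 1L) stop("top_k must be >= 1")
  code_list <- lapply(promoters$sequences, encode_seq)
  n_seq <- length(code_list)
  out <- list()
  for (w in widths) {
    wm <- window_code_matrix(code_list, w)        # N-free windows + origin
    wins <- wm$wins
    if (nrow(wins) == 0L) next
    bg_lp <- unlist(lapply(code_list, function(cc) {
      v <- bg_window_logprobs(bg, cc, w)
      v[rowSums(is.na(embed_codes(cc, w))) == 0L]
    }))
    seeds <- unique(wins)
    maxd <- ceiling(w / 4)
    # motifs occur in of the order of one site per promoter: cap the site
    # set at 2 per sequence and 3 per sequence overall, keeping the
    # highest-ratio windows (prevents drift to diffuse low-information PWMs)
    cap_sites <- function(idx, lr) {
      idx <- idx[order(-lr[idx])]
      keep <- integer(0); per_seq <- integer(n_seq)
      for (i in idx) {
        sq <- wm$seq_of[i]
        if (per_seq[sq] >= 2L) next
        per_seq[sq] <- per_seq[sq] + 1L
        keep <- c(keep, i)
        if (length(keep) >= 3L * n_seq) break
      }
      keep
    }
    cands <- list()
    for (i in seq_len(nrow(seeds))) {
      d <- hamming_to(seeds[i, ], wins)
      hit <- which(d <= maxd)
      if (length(hit) < min_sites) next
      pw <- pwm_from_sites(wins[hit, , drop = FALSE], pseudocount = 0.5)
      for (it in seq_len(refine_iters)) {
        lr <- pwm_lp_on(pw, wins) - bg_lp
        hit <- cap_sites(which(lr > 0), lr)
        if (length(hit) < min_sites) break
        pw <- pwm_from_sites(wins[hit, , drop = FALSE], pseudocount = 0.5)
      }
      if (length(hit) < min_sites) next
      enr <- sum(pwm_lp_on(pw, wins[hit, , drop = FALSE]) - bg_lp[hit])
      cands[[length(cands) + 1L]] <- list(pw = pw, enr = enr)
    }
    if (!length(cands)) next
    enr <- vapply(cands, `[[`, numeric(1), "enr")
    cands <- cands[order(-enr)]
    seen <- character(0)
    kept <- list()
    for (cd in cands) {
      if (cd$pw$consensus %in% seen) next
      seen <- c(seen, cd$pw$consensus)
      kept[[length(kept) + 1L]] <- cd
      if (length(kept) >= top_k) break
    }
    for (r in seq_along(kept)) {
      pw <- kept[[r]]$pw
      pw$id <- sprintf("w%d_%d", w, r)
      pw$enrichment <- kept[[r]]$enr
      out[[length(out) + 1L]] <- pw
    }
  }
  out
}

embed_codes <- function(codes, w) {
  L <- length(codes)
  if (L < w) return(matrix(integer(0), ncol = w))
  idx <- outer(seq_len(L - w + 1L), 0:(w - 1L), `+`)
  matrix(codes[idx], ncol = w)
}

## all N-free windows of width w pooled over sequences, with the index of
## the sequence each window came from
window_code_matrix <- function(code_list, w) {
  mats <- lapply(code_list, function(cc) {
    m <- embed_codes(cc, w)
    m[rowSums(is.na(m)) == 0L, , drop = FALSE]
  })
  list(wins = do.call(rbind, mats),
       seq_of = rep(seq_along(mats), vapply(mats, nrow, integer(1))))
}

hamming_to <- function(seed, wins) {
  rowSums(wins != matrix(seed, nrow(wins), length(seed), byrow = TRUE))
}

## log motif probability of N-free window rows
pwm_lp_on <- function(pw, wins) {
  lp <- log(pw$probs)
  out <- numeric(nrow(wins))
  for (j in seq_len(ncol(wins))) out <- out + lp[cbind(wins[, j], j)]
  out
}

#' Serialize PWMs to / from a minimal plain-text matrix format
#'
#' One block per motif: a `MOTIF <id> <consensus>` line, a
#' `letter-probability matrix: w= <w>` line, then w rows of four
#' probabilities (A C G T).
#'
#' @param pwms list of [pwm()] objects.
#' @param path file path.
#' @return `write_pwms` returns `path` invisibly; `read_pwms` a list of PWMs.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (pw in pwms) {
    writeLines(sprintf("MOTIF %s %s", pw$id, pw$consensus), con)
    writeLines(sprintf("letter-probability matrix: w= %d", pw$width), con)
    writeLines(apply(pw$probs, 2, function(col)
      paste(sprintf("%.10g", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_pwms
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(s) {
    id <- strsplit(lines[s], " ")[[1]][2]
    w <- as.integer(sub(".*w= *", "", lines[s + 1L]))
    rows <- lines[(s + 2L):(s + 1L + w)]
    probs <- vapply(strsplit(trimws(rows), "\\s+"),
                    function(r) as.numeric(r), numeric(4))
    # guard against rounding of the serialized probabilities
    pwm(sweep(probs, 2, colSums(probs), "/"), id = id)
  })
}

#' Write / read a score matrix as TSV (gene rows, motif columns)
#'
#' @param x a `ScoreMatrix`.
#' @param path file path.
#' @return `write_score_matrix` returns `path` invisibly;
#'   `read_score_matrix` a `ScoreMatrix` (centering flag restored from a
#'   header comment).
#' @export
write_score_matrix <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# score_matrix centered=%s",
                     isTRUE(attr(x, "centered"))), con)
  df <- data.frame(gene = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  centered <- grepl("centered=TRUE", hdr)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  score_matrix(vals, centered = centered)
}
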