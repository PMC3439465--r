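#' @importFrom stats var rnorm runif rbinom setNames aggregate cor
#' @importFrom utils read.table write.table head
NULL

BASES <- c("A", "C", "G", "T")

## integer codes 1..4 for ACGT, NA for N; internal representation used
## throughout scoring and background fitting
encode_seq <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], c(BASES, "N"))
  x[x == 5L] <- NA_integer_
  x
}

decode_seq <- function(codes) {
  out <- c(BASES, "N")[ifelse(is.na(codes), 5L, codes)]
  paste(out, collapse = "")
}

#' Construct a set of promoter sequences for one species
#'
#' A `PromoterSet` holds one upstream (promoter) sequence per gene,
#' 5'->3' as provided, orientation already resolved by the data preparer
#' (genes on the negative strand are expected to have been reverse
#' complemented before extraction). Sequences are canonicalized to the
#' alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param sequences character vector of DNA sequences (one per gene).
#' @param gene_ids character vector of unique gene identifiers.
#' @param species_id single label for the species.
#' @param max_length maximum admissible sequence length (default 1000 nt,
#'   the customary upstream window for yeast promoters).
#' @return an object of class `PromoterSet`: a list with elements
#'   `species_id`, `gene_ids` and `sequences` (named character vector).
#' @export
promoter_set <- function(sequences, gene_ids = names(sequences),
                         species_id = "species", max_length = 1000L) {
  if (length(sequences) == 0L) stop("no records: promoter set is empty")
  if (is.null(gene_ids) || length(gene_ids) != length(sequences))
    stop("gene_ids must be provided, one per sequence")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  sequences <- toupper(sequences)
  bad <- regexpr("[^ACGTN]", sequences)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-ACGTN character in '%s' at position %d",
                 gene_ids[i], bad[i]))
  }
  if (any(nchar(sequences) > max_length))
    stop("sequence longer than max_length (", max_length, ") for gene ",
         gene_ids[which(nchar(sequences) > max_length)[1L]])
  obj <- list(species_id = species_id,
              gene_ids = gene_ids,
              sequences = setNames(sequences, gene_ids))
  class(obj) <- "PromoterSet"
  obj
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat(sprintf("PromoterSet '%s': %d genes, lengths %d-%d nt\n",
              x$species_id, length(x$gene_ids),
              min(nchar(x$sequences)), max(nchar(x$sequences))))
  invisible(x)
}

#' Read promoter sequences from a FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) of pre-extracted
#' upstream regions. Lowercase letters usually mark repeat-masked bases;
#' `mask_policy = "to_N"` converts them to `N` so that masked positions are
#' excluded from background counting and motif scoring, while `"keep"`
#' simply case-folds them.
#'
#' @param path path to a FASTA file.
#' @param mask_policy `"keep"` or `"to_N"` (handling of lowercase letters).
#' @param species_id label for the resulting set; defaults to the file name.
#' @param max_length passed to [promoter_set()].
#' @return a [promoter_set()] with one record per FASTA entry, file order
#'   preserved; record ids are the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta_promoters <- function(path, mask_policy = c("keep", "to_N"),
                                 species_id = NULL, max_length = 1000L) {
  mask_policy <- match.arg(mask_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("not FASTA-formatted: ",
                                            conditionMessage(e)))
  if (length(recs) == 0L) stop("no records in ", path)
  seqs <- as.character(recs)
  ids <- sub("\\s.*$", "", names(recs))
  if (mask_policy == "to_N") seqs <- gsub("[acgtn]", "N", seqs)
  if (is.null(species_id))
    species_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  promoter_set(seqs, gene_ids = ids, species_id = species_id,
               max_length = max_length)
}

#' Reverse complement of a DNA sequence
#'
#' Strict alphabet `A`,`C`,`G`,`T`,`N`; `N` is self-complementary. The
#' operation is an involution.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  bad <- regexpr("[^ACGTN]", toupper(seq))
  if (any(bad > 0L))
    stop("invalid character at position ", bad[which(bad > 0L)[1L]])
  vapply(toupper(seq), function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
}

all_contexts <- function(k) {
  if (k == 0L) return("")
  do.call(paste0, rev(expand.grid(rep(list(BASES), k),
                                  stringsAsFactors = FALSE)))
}

## counts of (context of length k, next base) over all N-free windows,
## pooled over sequences; returns 4^k x 4 matrix with contexts as rownames
count_transitions <- function(code_list, k) {
  n_ctx <- 4L^k
  counts <- matrix(0, nrow = n_ctx, ncol = 4L)
  pow <- 4L^(seq_len(k) - 1L)           # little-endian within context
  for (codes in code_list) {
    L <- length(codes)
    if (L < k + 1L) next
    # context index for window ending right before position t (t = k+1..L):
    # sum over j of (code[t-j]-1)*4^(j-1), j = 1..k
    if (k == 0L) {
      ok <- !is.na(codes)
      if (any(ok)) {
        tab <- tabulate(codes[ok], nbins = 4L)
        counts[1L, ] <- counts[1L, ] + tab
      }
      next
    }
    t <- (k + 1L):L
    idx <- rep(1L, length(t))
    valid <- !is.na(codes[t])
    for (j in seq_len(k)) {
      cj <- codes[t - j]
      valid <- valid & !is.na(cj)
      idx <- idx + ifelse(is.na(cj), 0L, (cj - 1L)) * pow[j]
    }
    if (!any(valid)) next
    flat <- (codes[t][valid] - 1L) * n_ctx + idx[valid]
    tab <- tabulate(flat, nbins = 4L * n_ctx)
    counts <- counts + matrix(tab, nrow = n_ctx, ncol = 4L)
  }
  ctx <- all_contexts(k)
  # row index above is little-endian with the *most recent* base as j=1;
  # reorder rows to match human-readable context strings (oldest first)
  if (k > 0L) {
    ord <- vapply(ctx, function(s) {
      cc <- match(strsplit(s, "")[[1]], BASES)
      as.integer(sum((rev(cc) - 1L) * pow)) + 1L
    }, integer(1))
    counts <- counts[ord, , drop = FALSE]
  }
  rownames(counts) <- ctx
  colnames(counts) <- BASES
  counts
}

#' Fit an order-k Markov background model of promoter composition
#'
#' Estimates the transition probabilities of an order-`k` Markov chain over
#' promoter sequence, pooled across the supplied promoter sets, by
#' add-pseudocount smoothing of (k-mer context, next base) counts. Windows
#' containing `N` are skipped. Lower-order conditional tables (orders
#' 0..k-1) are estimated the same way and used for the first `k` positions
#' of a word, so that word probabilities of a fixed length sum to one.
#'
#' The canonical choice in regulatory-sequence scoring is `order = 6`, but
#' a reliable sixth-order fit needs genome-scale input; a warning is issued
#' when the pooled data provide fewer than `50 * 4^order` countable windows.
#'
#' @param promoters a [promoter_set()] or list of them (pooled).
#' @param order non-negative Markov order `k` (default 6).
#' @param pseudocount added to every (context, base) count (default 0.5).
#' @return an object of class `BackgroundModel`: list with `order`,
#'   `pseudocount`, `transition` (4^k x 4 row-stochastic matrix, contexts as
#'   rownames) and `lower` (list of such matrices for orders 0..k-1).
#' @export
fit_markov_background <- function(promoters, order = 6L, pseudocount = 0.5) {
  if (inherits(promoters, "PromoterSet")) promoters <- list(promoters)
  stopifnot(length(promoters) >= 1L)
  if (order < 0L) stop("order must be >= 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  seqs <- unlist(lapply(promoters, `[[`, "sequences"), use.names = FALSE)
  if (sum(nchar(seqs)) == 0L) stop("pooled sequence length is zero")
  code_list <- lapply(seqs, encode_seq)

  norm_counts <- function(counts) {
    smoothed <- counts + pseudocount
    tot <- rowSums(smoothed)
    if (any(tot == 0))
      smoothed[tot == 0, ] <- 1      # unseen context, zero pseudocount: uniform
    smoothed / rowSums(smoothed)
  }

  top <- count_transitions(code_list, as.integer(order))
  n_windows <- sum(top)
  if (n_windows == 0L)
    stop("no countable windows at order ", order,
         "; try a lower order or provide longer sequences")
  if (n_windows < 50 * 4^order)
    warning(sprintf(paste0("only %d countable windows for order %d ",
                           "(< 50*4^k = %.0f); consider a lower order"),
                    n_windows, order, 50 * 4^order))
  lower <- lapply(seq_len(order) - 1L, function(j)
    norm_counts(count_transitions(code_list, j)))
  obj <- list(order = as.integer(order), pseudocount = pseudocount,
              transition = norm_counts(top), lower = lower)
  class(obj) <- "BackgroundModel"
  obj
}

#' @export
print.BackgroundModel <- function(x, ...) {
  cat(sprintf("BackgroundModel: order %d Markov chain, pseudocount %g\n",
              x$order, x$pseudocount))
  invisible(x)
}

## log-probability of each base given its in-word context; `codes` has no NA
word_logprob_terms <- function(model, codes) {
  w <- length(codes)
  k <- model$order
  tabs <- c(model$lower, list(model$transition))  # orders 0..k
  vapply(seq_len(w), function(j) {
    ord <- min(j - 1L, k)
    tab <- tabs[[ord + 1L]]
    if (ord == 0L) return(log(tab[1L, codes[j]]))
    ctx <- paste(BASES[codes[(j - ord):(j - 1L)]], collapse = "")
    log(tab[ctx, codes[j]])
  }, numeric(1))
}

#' Probability of a DNA word under the background model
#'
#' Chains the estimated lower-order marginals for the first `min(k, w)`
#' positions with order-`k` transition probabilities thereafter, so that for
#' any fixed length the probabilities of all `4^L` words sum to one.
#'
#' @param model a [fit_markov_background()] model.
#' @param word DNA string over `A`,`C`,`G`,`T` (no `N`).
#' @param log if `TRUE` return the natural-log probability.
#' @return probability of the word (strictly positive when the model was fit
#'   with a positive pseudocount).
#' @export
background_word_prob <- function(model, word, log = FALSE) {
  stopifnot(inherits(model, "BackgroundModel"))
  codes <- encode_seq(toupper(word))
  if (length(codes) < 1L) stop("word must have length >= 1")
  if (anyNA(codes))
    stop("word contains N; windows with N must be skipped by the caller")
  lp <- sum(word_logprob_terms(model, codes))
  if (log) lp else exp(lp)
}

## log background probability of every width-w window of an encoded
## sequence; windows containing N get NA.  Vectorized: order-k transition
## terms are shared between overlapping windows via cumulative sums.
bg_window_logprobs <- function(model, codes, w) {
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_win <- L - w + 1L
  k <- model$order
  ltrans <- log(model$transition)
  llower <- lapply(model$lower, log)
  # per-position full-context term: position t (t > k) given codes[t-k..t-1]
  full <- rep(NA_real_, L)
  if (k == 0L) {
    full <- ifelse(is.na(codes), NA_real_, ltrans[cbind(1L, codes)])
  } else if (L > k) {
    t <- (k + 1L):L
    pow <- 4L^(k - seq_len(k))          # big-endian: oldest base highest power
    idx <- rep(1L, length(t)); valid <- !is.na(codes[t])
    for (j in seq_len(k)) {
      cj <- codes[t - (k - j + 1L)]     # j-th oldest base of the context
      valid <- valid & !is.na(cj)
      idx <- idx + ifelse(is.na(cj), 0L, cj - 1L) * pow[j]
    }
    v <- rep(NA_real_, length(t))
    v[valid] <- ltrans[cbind(idx[valid], codes[t][valid])]
    full[t] <- v
  }
  out <- numeric(n_win)
  kk <- min(k, w)
  # tail part (positions kk+1..w of each window) uses full-context terms
  if (w > kk) {
    cs <- c(0, cumsum(ifelse(is.na(full), 0, full)))
    nas <- c(0L, cumsum(is.na(full)))
    starts <- seq_len(n_win)
    lo <- starts + kk; hi <- starts + w - 1L
    tail_sum <- cs[hi + 1L] - cs[lo]
    tail_na <- (nas[hi + 1L] - nas[lo]) > 0L
    out <- ifelse(tail_na, NA_real_, tail_sum)
  }
  # head part: first kk positions of each window from lower-order tables
  if (kk > 0L) {
    head_term <- matrix(0, nrow = n_win, ncol = kk)
    for (j in seq_len(kk)) {
      ord <- j - 1L
      tab <- if (ord < k) llower[[ord + 1L]] else ltrans
      pos <- seq_len(n_win) + j - 1L     # absolute position of in-word pos j
      base <- codes[pos]
      if (ord == 0L) {
        head_term[, j] <- ifelse(is.na(base), NA_real_, tab[cbind(1L, base)])
      } else {
        idx <- rep(1L, n_win); valid <- !is.na(base)
        pow <- 4L^(ord - seq_len(ord))
        for (m in seq_len(ord)) {
          cm <- codes[pos - (ord - m + 1L)]
          valid <- valid & !is.na(cm)
          idx <- idx + ifelse(is.na(cm), 0L, cm - 1L) * pow[m]
        }
        v <- rep(NA_real_, n_win)
        v[valid] <- tab[cbind(idx[valid], base[valid])]
        head_term[, j] <- v
      }
    }
    out <- out + rowSums(head_term)
  }
  out
}

#' Write / read a background model as a plain-text table
#'
#' The serialization is a whitespace-delimited table with one row per
#' context (all orders 0..k) and four probability columns, preceded by a
#' header comment carrying the order and pseudocount, so that fitted
#' backgrounds can be archived and reloaded reproducibly.
#'
#' @param model a `BackgroundModel`.
#' @param path output / input file path.
#' @return `write_background` returns `path` invisibly; `read_background`
#'   returns a `BackgroundModel`.
#' @export
write_background <- function(model, path) {
  stopifnot(inherits(model, "BackgroundModel"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# markov_background order=%d pseudocount=%.10g",
                     model$order, model$pseudocount), con)
  tabs <- c(model$lower, list(model$transition))
  for (ord in seq_along(tabs) - 1L) {
    tab <- tabs[[ord + 1L]]
    ctx <- rownames(tab)
    ctx[ctx == ""] <- "."
    writeLines(sprintf("%s %.17g %.17g %.17g %.17g",
                       ctx, tab[, 1], tab[, 2], tab[, 3], tab[, 4]), con)
  }
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr, regexec("order=(\\d+) pseudocount=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3L) stop("not a background model file: ", path)
  order <- as.integer(m[2]); ps <- as.numeric(m[3])
  body <- do.call(rbind, strsplit(lines[-1], "\\s+"))
  ctx <- body[, 1]; ctx[ctx == "."] <- ""
  probs <- matrix(as.numeric(body[, 2:5]), ncol = 4)
  colnames(probs) <- BASES
  lens <- nchar(ctx)
  tabs <- lapply(0:order, function(j) {
    sel <- lens == j
    tab <- probs[sel, , drop = FALSE]
    rownames(tab) <- ctx[sel]
    if (j == 0L) return(tab)
    tab[all_contexts(j), , drop = FALSE]
  })
  obj <- list(order = order, pseudocount = ps,
              transition = tabs[[order + 1L]],
              lower = tabs[seq_len(order)])
  class(obj) <- "BackgroundModel"
  obj
}
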