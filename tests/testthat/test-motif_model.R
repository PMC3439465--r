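test_that("PWM construction validates columns and derives the consensus", {
  pr <- matrix(c(0.7, 0.1, 0.1, 0.1,
                 0.25, 0.25, 0.25, 0.25), 4, 2)
  pw <- pwm(pr)
  expect_equal(pw$width, 2L)
  expect_identical(pw$consensus, "AA")   # tie in column 2 -> alphabetical
  expect_error(pwm(matrix(0.3, 4, 2)), "sum to 1")
  expect_error(pwm(matrix(0.5, 2, 2)), "4 rows")
  cons <- pwm_from_consensus("TTCAGGT", focus = 0.9)
  expect_identical(cons$consensus, "TTCAGGT")
  expect_equal(colSums(cons$probs), rep(1, 7))
})

test_that("matching score agrees with hand-computable cases", {
  bg0 <- suppressWarnings(fit_markov_background(
    promoter_set(c(a = "ACGTACGT")), order = 0, pseudocount = 0))
  # uniform PWM, uniform background: all ratios 1, 4 windows
  expect_equal(as.numeric(matching_score(pwm(matrix(0.25, 4, 2)),
                                         "ACGTA", bg0)), 2)
  # deterministic AAA motif on TAAAT: single window with ratio 4^3
  det <- pwm(matrix(c(1, 0, 0, 0), 4, 3, byrow = FALSE) * 0 +
               matrix(rep(c(1, 0, 0, 0), 3), 4))
  expect_equal(as.numeric(matching_score(det, "TAAAT", bg0)), 6)
})

test_that("matching score equals the brute-force window evaluator", {
  set.seed(11)
  for (i in 1:30) {
    ord <- sample(0:2, 1)
    bg <- toy_background(order = ord, seed = 100 + i)
    w <- sample(3:6, 1)
    pw <- random_pwm(w)
    sq <- paste(sample(c("A", "C", "G", "T", "N"), sample(15:40, 1),
                       replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                collapse = "")
    brute <- oracle_matching_score(pw, sq, bg)
    got <- matching_score(pw, sq, bg)
    if (is.na(brute)) expect_true(isTRUE(attr(got, "floored")))
    else expect_equal(as.numeric(got), brute, tolerance = 1e-10)
  }
})

test_that("score is floored when no valid window exists and errors on zero background", {
  bg <- toy_background(order = 1)
  pw <- random_pwm(4, seed = 5)
  s <- matching_score(pw, "ACN", bg)            # too short / N-blocked
  expect_true(isTRUE(attr(s, "floored")))
  expect_equal(as.numeric(s), log2(.Machine$double.xmin))
  bg0 <- suppressWarnings(fit_markov_background(
    promoter_set(c(a = "AAAA")), order = 1, pseudocount = 0))
  expect_error(matching_score(pw, "AACG", bg0), "background")
})

test_that("appending sequence can only increase the matching score", {
  set.seed(21)
  bg <- toy_background(order = 1)
  for (i in 1:10) {
    pw <- random_pwm(4)
    s1 <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                collapse = "")
    s2 <- paste0(s1, paste(sample(c("A", "C", "G", "T"), 10,
                                  replace = TRUE), collapse = ""))
    expect_gte(as.numeric(matching_score(pw, s2, bg)),
               as.numeric(matching_score(pw, s1, bg)))
  }
})

test_that("score matrix has the right shape, centering and warnings", {
  ps <- random_promoters(n = 3, len = 60, seed = 6)
  bg <- toy_background(order = 1)
  pwms <- list(random_pwm(4, seed = 1, id = "a"),
               random_pwm(5, seed = 2, id = "b"))
  X <- build_score_matrix(pwms, ps, bg, center = FALSE)
  expect_equal(dim(X), c(3L, 2L))
  expect_false(attr(X, "centered"))
  Xc <- build_score_matrix(pwms, ps, bg, center = TRUE)
  expect_true(all(abs(colMeans(unclass(Xc))) < 1e-9))
  # re-centering is idempotent
  Xcc <- score_matrix(unclass(Xc), center = TRUE)
  expect_equal(unclass(Xcc), unclass(Xc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(build_score_matrix(list(random_pwm(4, id = "a"),
                                       random_pwm(4, id = "a")), ps, bg),
               "duplicate motif ids")
  # a gene shorter than the motif width gets the floor with a warning
  short <- promoter_set(c(g1 = "ACGTACGTAC", g2 = "AC"), species_id = "s")
  expect_warning(Xs <- build_score_matrix(list(random_pwm(4, id = "a")),
                                          short, bg, center = FALSE),
                 "floor")
  expect_equal(unclass(Xs)["g2", 1], log2(.Machine$double.xmin))
})

test_that("seed-and-refine discovery recovers a planted consensus", {
  plant <- "TTCAGGT"
  hits <- 0L
  for (rep in 1:8) {
    set.seed(300 + rep)
    ps <- random_promoters(n = 10, len = 120, seed = 300 + rep)
    seqs <- ps$sequences
    for (g in 1:8) {
      pos <- sample(1:(120 - 7), 1)
      substr(seqs[g], pos, pos + 6) <- plant
    }
    ps <- promoter_set(seqs, species_id = "plant")
    bg <- toy_background(order = 1, seed = 300 + rep)
    cands <- discover_candidates(ps, bg, widths = 7, top_k = 5,
                                 refine_iters = 2)
    cons <- vapply(cands, `[[`, character(1), "consensus")
    dist <- vapply(cons, function(cc)
      sum(strsplit(cc, "")[[1]] != strsplit(plant, "")[[1]]), integer(1))
    if (any(dist <= 1)) hits <- hits + 1L
  }
  expect_gte(hits, 7L)                      # >= 90% recovery target
})

test_that("discovery respects top_k, dedups by consensus, validates input", {
  ps <- random_promoters(n = 6, len = 80, seed = 31)
  bg <- toy_background(order = 1)
  cands <- discover_candidates(ps, bg, widths = 5, top_k = 3)
  expect_lte(length(cands), 3L)
  cons <- vapply(cands, `[[`, character(1), "consensus")
  expect_false(anyDuplicated(cons) > 0)
  expect_error(discover_candidates(ps, bg, widths = 25), "3..20")
})

test_that("PWM and score matrix serializations round-trip", {
  pwms <- list(random_pwm(4, seed = 8, id = "mA"),
               random_pwm(6, seed = 9, id = "mB"))
  f <- tempfile()
  write_pwms(pwms, f)
  back <- read_pwms(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$probs, pwms[[1]]$probs, tolerance = 1e-9)
  expect_identical(back[[2]]$id, "mB")

  ps <- random_promoters(n = 3, len = 60, seed = 6)
  bg <- toy_background(order = 1)
  X <- build_score_matrix(pwms, ps, bg, center = TRUE)
  f2 <- tempfile()
  write_score_matrix(X, f2)
  X2 <- read_score_matrix(f2)
  expect_equal(unclass(X2), unclass(X), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(attr(X2, "centered"))
})
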