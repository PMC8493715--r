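make_training <- function(n = 12, seed = 91) {
  set.seed(seed)
  hept <- "CACAGTG"; nona <- "ACAAAAACC"
  vapply(seq_len(n), function(i) {
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }
    paste0(mut(hept, sample(0:1, 1)), rand_seq(23), mut(nona, sample(0:2, 1)))
  }, character(1))
}

test_that("the training consensus attains the model maximum", {
  model <- rss_model(make_training())
  consensus <- gsub("N", "A", rss_consensus(model))
  cmax <- score_rss(model, consensus)
  set.seed(93)
  for (i in 1:20) {
    expect_lte(score_rss(model, paste0(rand_seq(7), rand_seq(23),
                                       rand_seq(9))), cmax)
  }
  # a substitution at the most conserved heptamer position scores lower
  pos <- which.max(apply(model$heptamer, 2, max))
  best_base <- rownames(model$heptamer)[which.max(model$heptamer[, pos])]
  mutant <- consensus
  substr(mutant, pos, pos) <- setdiff(c("A", "C", "G", "T"), best_base)[1]
  expect_lt(score_rss(model, mutant), cmax)
})

test_that("training sequences outscore random sequences on average", {
  training <- make_training()
  model <- rss_model(training)
  set.seed(95)
  random <- vapply(1:30, function(i) paste0(rand_seq(39)), character(1))
  expect_gt(mean(score_rss(model, training)), mean(score_rss(model, random)))
})

test_that("scores equal a direct per-position tabulation", {
  training <- make_training()
  model <- rss_model(training, pseudocount = 0.5)
  block_score <- function(block_seqs, probe) {
    # recount the PWM from raw training counts, independent of the model code
    M <- do.call(rbind, strsplit(block_seqs, ""))
    sum(vapply(seq_len(nchar(probe)), function(p) {
      cnt <- sum(M[, p] == substr(probe, p, p)) + 0.5
      log((cnt / (length(block_seqs) + 2)) / 0.25)
    }, numeric(1)))
  }
  probe_h <- "CACAGTG"; probe_n <- "ACAAAAACC"
  manual <- block_score(substr(training, 1, 7), probe_h) +
    block_score(substr(training, 31, 39), probe_n)
  got <- score_rss(model, paste0(probe_h, strrep("A", 23), probe_n))
  expect_equal(got, manual, tolerance = 1e-9)
})

test_that("model validation rejects malformed input", {
  expect_error(rss_model("ACGT"), class = "gammarep_invalid_input")
  model <- rss_model(make_training())
  expect_error(score_rss(model, "ACGT"), class = "gammarep_invalid_input")
  expect_error(rss_model(make_training(), spacer_length = 15),
               class = "gammarep_invalid_input")
})

test_that("usage regression matches the closed-form OLS", {
  # exact line
  d <- tibble::tibble(v_id = letters[1:4], score = 1:4,
                      usage = 0.1 + 0.05 * (1:4))
  fit <- suppressWarnings(usage_regression(d))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  # constant response: R^2 = 0
  d2 <- tibble::tibble(score = 1:5, usage = rep(0.2, 5))
  expect_equal(suppressWarnings(usage_regression(d2))$r_squared, 0)
  # three-point case versus the normal equations
  d3 <- tibble::tibble(score = c(1, 2, 3), usage = c(0.1, 0.2, 0.2))
  fit3 <- usage_regression(d3)
  bf <- bf_ols(d3$score, d3$usage)
  expect_equal(fit3$slope, bf$slope, tolerance = 1e-12)
  expect_equal(fit3$intercept, bf$intercept, tolerance = 1e-12)
  expect_equal(fit3$r_squared, bf$r_squared, tolerance = 1e-12)
  expect_error(usage_regression(tibble::tibble(score = c(1, 1, 1),
                                               usage = c(0.1, 0.2, 0.3))),
               class = "gammarep_invalid_input")
  expect_error(usage_regression(d3[1:2, ]), class = "gammarep_invalid_input")
})

test_that("regression is affine-invariant in the scores and finds a planted slope", {
  set.seed(97)
  score <- rnorm(20, -55, 8)
  usage <- pmin(pmax(0.002 * (score + 70) + rnorm(20, 0, 0.002), 0), 1)
  f1 <- usage_regression(tibble::tibble(score = score, usage = usage))
  f2 <- usage_regression(tibble::tibble(score = 2 * score + 10, usage = usage))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
  expect_equal(f1$slope, 2 * f2$slope, tolerance = 1e-9)
  expect_gt(f1$slope, 0)
  # tidy/glance expose the fit in broom style
  expect_equal(nrow(tidy(f1)), 2L)
  expect_equal(glance(f1)$r_squared, f1$r_squared)
})
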