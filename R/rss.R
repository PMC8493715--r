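#' Train a position-weight RSS scoring model
#'
#' Builds per-position log-odds matrices for the heptamer (first 7 nt) and
#' nonamer (last 9 nt) of a set of recombination signal sequences
#' (heptamer + spacer + nonamer); the spacer contributes no score. This is a
#' position-weight-matrix stand-in for trained recombination-information-
#' content models: higher scores mean better signal sequences and the
#' training consensus attains the model maximum, but the absolute values are
#' not comparable to published RIC scores (externally computed scores can be
#' fed straight into [usage_regression()]).
#'
#' @param training Character vector of RSS sequences, all of length
#'   `7 + spacer_length + 9`.
#' @param spacer_length Spacer length in nt, 12 or 23 (default 23, the
#'   V-segment class).
#' @param pseudocount Added to each base count before the log-odds
#'   (default 0.5).
#' @param background Base composition under the null (default uniform).
#' @return An object of class `rss_model`.
#' @export
rss_model <- function(training, spacer_length = 23, pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!spacer_length %in% c(12, 23)) {
    abort("spacer_length must be 12 or 23", class = "gammarep_invalid_input")
  }
  training <- check_dna(training, "training RSS")
  expect_len <- 7 + spacer_length + 9
  if (any(nchar(training) != expect_len)) {
    abort(paste0("training RSS must be ", expect_len, " nt"),
          class = "gammarep_invalid_input")
  }
  pwm_of <- function(seqs) {
    M <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = nchar(seqs[1]),
                byrow = TRUE)
    counts <- apply(M, 2, function(col) {
      c(A = sum(col == "A"), C = sum(col == "C"),
        G = sum(col == "G"), T = sum(col == "T"))
    })
    freq <- sweep(counts + pseudocount, 2,
                  colSums(counts + pseudocount), "/")
    log(freq / background[rownames(freq)])
  }
  hept <- substr(training, 1, 7)
  nona <- substr(training, 7 + spacer_length + 1, expect_len)
  structure(list(heptamer = pwm_of(hept), nonamer = pwm_of(nona),
                 spacer_length = spacer_length, background = background,
                 n_training = length(training),
                 score_floor = log(pseudocount / (4 + 4 * pseudocount)) -
                   log(0.25)),
            class = "rss_model")
}

#' Score a recombination signal sequence
#'
#' Sum of per-position log-odds over the heptamer and nonamer; the spacer is
#' ignored. `N` (or other unscorable) positions contribute the model's score
#' floor with a warning.
#'
#' @param model An [rss_model()].
#' @param rss RSS sequence(s) of length `7 + spacer_length + 9`.
#' @return Numeric score(s); higher is better.
#' @export
score_rss <- function(model, rss) {
  stopifnot(inherits(model, "rss_model"))
  rss <- check_dna(rss, "rss")
  expect_len <- 7 + model$spacer_length + 9
  if (any(nchar(rss) != expect_len)) {
    abort(paste0("rss must be ", expect_len, " nt"),
          class = "gammarep_invalid_input")
  }
  score_block <- function(seqs, pwm) {
    M <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = ncol(pwm),
                byrow = TRUE)
    vapply(seq_len(nrow(M)), function(i) {
      sum(vapply(seq_len(ncol(pwm)), function(p) {
        b <- M[i, p]
        if (b %in% rownames(pwm)) pwm[b, p] else {
          warn("unscorable base in RSS; applying score floor")
          model$score_floor
        }
      }, numeric(1)))
    }, numeric(1))
  }
  hept <- substr(rss, 1, 7)
  nona <- substr(rss, 7 + model$spacer_length + 1, expect_len)
  score_block(hept, model$heptamer) + score_block(nona, model$nonamer)
}

#' @rdname rss_model
#' @param model An `rss_model`.
#' @export
rss_consensus <- function(model) {
  pick <- function(pwm) paste(rownames(pwm)[apply(pwm, 2, which.max)],
                              collapse = "")
  paste0(pick(model$heptamer), strrep("N", model$spacer_length),
         pick(model$nonamer))
}

#' Regress TRGV usage on RSS score
#'
#' Ordinary least squares of per-gene usage proportions (typically thymic,
#' the site of T cell development) on per-gene RSS scores, reporting slope,
#' intercept, R-squared and the two-sided p-value for the slope.
#'
#' @param data A data frame with columns `v_id` (or first column), `score`
#'   and `usage`; alternatively two named numeric vectors via `score` and
#'   `usage`.
#' @param score,usage Named numeric vectors keyed by V id (used when `data`
#'   is missing); names are matched.
#' @return An object of class `rss_usage_fit`; see [tidy()] / [glance()]
#'   methods, and `$slope`, `$intercept`, `$r_squared`, `$p_value`.
#' @export
usage_regression <- function(data = NULL, score = NULL, usage = NULL) {
  if (is.null(data)) {
    ids <- intersect(names(score), names(usage))
    data <- tibble(v_id = ids, score = unname(score[ids]),
                   usage = unname(usage[ids]))
  }
  stopifnot(all(c("score", "usage") %in% names(data)))
  data <- as_tibble(data) |>
    dplyr::filter(!is.na(.data$score), !is.na(.data$usage))
  if (nrow(data) < 3) {
    abort("need at least 3 paired points", class = "gammarep_invalid_input")
  }
  if (any(data$usage < 0 | data$usage > 1)) {
    abort("usage must be proportions in [0, 1]", class = "gammarep_invalid_input")
  }
  if (stats::var(data$score) == 0) {
    abort("zero variance in scores: slope undefined",
          class = "gammarep_invalid_input")
  }
  fit <- lm(usage ~ score, data = data)
  s <- summary(fit)
  structure(list(fit = fit, data = data,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = unname(s$coefficients["score", "Pr(>|t|)"])),
            class = "rss_usage_fit")
}

#' @rdname usage_regression
#' @param x An `rss_usage_fit`.
#' @param ... Unused.
#' @method tidy rss_usage_fit
#' @export
tidy.rss_usage_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std_error = s[, "Std. Error"], statistic = s[, "t value"],
         p_value = s[, "Pr(>|t|)"])
}

#' @rdname usage_regression
#' @method glance rss_usage_fit
#' @export
glance.rss_usage_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         p_value = x$p_value, n = nrow(x$data))
}

#' @export
print.rss_usage_fit <- function(x, ...) {
  cat("RSS score vs usage regression\n")
  cat(sprintf("  slope = %.4g, intercept = %.4g\n", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, p = %.4g, n = %d\n", x$r_squared, x$p_value,
              nrow(x$data)))
  invisible(x)
}
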