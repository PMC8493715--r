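#' Abundance vectors and frequency counts
#'
#' An abundance vector holds positive integer clonotype counts. `f_k` is the
#' number of clonotypes observed exactly k times; `f_1` (singletons) and
#' `f_2` (doubletons) drive the coverage estimators.
#'
#' @param x Positive integer counts (zeros are dropped).
#' @return Validated integer vector.
#' @export
as_abundance <- function(x) {
  if (length(x) == 0) abort("empty abundance vector",
                            class = "gammarep_invalid_input")
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort("abundances must be non-negative integers",
          class = "gammarep_invalid_input")
  }
  x <- as.integer(x[x > 0])
  if (length(x) == 0) abort("all abundances are zero",
                            class = "gammarep_invalid_input")
  x
}

freq_count <- function(x, k) sum(x == k)

# Good-Turing sample-coverage deficit factor A = (n-1)f1 / ((n-1)f1 + 2 f2)
coverage_A <- function(n, f1, f2) {
  if (f1 == 0) return(0)
  (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
}

#' Estimated sample coverage at a given sample size
#'
#' Sample coverage is the fraction of the community's total abundance
#' accounted for by the clonotypes present in a sample. With `m = NULL` the
#' full-sample Good-Turing estimate is returned; `m < n` gives the expected
#' coverage of a subsample of size m (rarefaction); `m > n` extrapolates.
#' Coverage is monotone non-decreasing in m.
#'
#' @param x Abundance vector.
#' @param m Target sample size, or `NULL` for the full sample.
#' @return Coverage estimate in `[0, 1]`.
#' @export
#' @examples
#' coverage_estimate(c(1, 1, 2))        # 0.625
#' coverage_estimate(c(2, 2), m = 2)    # 2/3
coverage_estimate <- function(x, m = NULL) {
  x <- as_abundance(x)
  n <- sum(x)
  f1 <- freq_count(x, 1)
  f2 <- freq_count(x, 2)
  A <- coverage_A(n, f1, f2)
  if (is.null(m) || m == n) {
    return(1 - (f1 / n) * A)
  }
  m <- as.integer(m)
  if (m <= 0) abort("m must be positive", class = "gammarep_invalid_input")
  if (m < n) {
    # 1 - sum_i (Xi/n) C(n-Xi, m) / C(n-1, m)
    num <- lchoose(n - x, m) - lchoose(n - 1, m)
    return(1 - sum((x / n) * exp(num)))
  }
  mstar <- m - n
  1 - (f1 / n) * A^(mstar + 1)
}

#' Observed Hill number of order q
#'
#' With relative abundances p_i: q = 0 gives observed richness, q = 1 the
#' exponential of Shannon entropy, q = 2 the inverse Simpson concentration;
#' general q >= 0 is supported.
#'
#' @param x Abundance vector.
#' @param q Diversity order.
#' @return Effective number of clonotypes.
#' @export
hill_observed <- function(x, q) {
  x <- as_abundance(x)
  p <- x / sum(x)
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

# expected frequency counts in a subsample of size m:
# E[f_k(m)] = sum_i C(Xi, k) C(n - Xi, m - k) / C(n, m), k = 1..m
expected_fk <- function(x, m) {
  n <- sum(x)
  k <- seq_len(m)
  lc_n_m <- lchoose(n, m)
  sapply(k, function(kk) {
    term <- lchoose(x, kk) + lchoose(n - x, m - kk) - lc_n_m
    sum(exp(term[is.finite(term)]))
  })
}

# asymptotic (Chao1-style) unseen richness
f0_hat <- function(f1, f2, n) {
  if (f1 == 0) return(0)
  if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2) else
    ((n - 1) / n) * f1 * (f1 - 1) / (2 * (f2 + 1))
}

# asymptotic exponential Shannon (entropy estimator of the
# jackknife/Good-Turing family used by coverage-based R/E packages)
hill1_asymptote <- function(x) {
  n <- sum(x)
  f1 <- freq_count(x, 1); f2 <- freq_count(x, 2)
  h <- sum((x / n) * (digamma(n) - digamma(x)))
  if (f1 > 0) {
    A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2) else
      if (f1 > 1) 2 / ((n - 1) * (f1 - 1) + 2) else 1
    if (A < 1) {
      r <- seq_len(n - 1)
      corr <- (f1 / n) * (1 - A)^(1 - n) *
        (-log(A) - sum((1 / r) * (1 - A)^r))
      if (is.finite(corr) && corr > 0) h <- h + corr
    }
  }
  exp(h)
}

hill2_asymptote <- function(x) {
  n <- sum(x)
  s <- sum(x * (x - 1)) / (n * (n - 1))
  if (s <= 0) return(hill_observed(x, 2))
  1 / s
}

#' Hill number rarefied or extrapolated to sample size m
#'
#' Interpolation (m <= n) uses the exact expected-value estimators: expected
#' richness for q = 0, expected entropy over expected frequency counts for
#' q = 1, and the unbiased Simpson-based form for q = 2. Extrapolation
#' (m > n) anchors on the asymptotic estimators (Chao1-style unseen richness
#' for q = 0; asymptotic entropy / unbiased Simpson for q = 1, 2) with a
#' relaxation that is continuous at m = n and approaches the asymptote as
#' m grows. When there are no singletons there is no evidence of unseen
#' clonotypes and the observed value is returned with a note.
#'
#' @param x Abundance vector.
#' @param m Target sample size (positive integer).
#' @param q Diversity order (0, 1 or 2 for the estimators; other q supported
#'   only at m = n).
#' @return A one-row tibble: `q`, `m`, `coverage`, `estimate`, `method`
#'   (`interpolated`, `observed`, `extrapolated`), `note`.
#' @export
hill_at_size <- function(x, m, q) {
  x <- as_abundance(x)
  n <- sum(x)
  m <- as.integer(m)
  if (m < 1) abort("m must be >= 1", class = "gammarep_invalid_input")
  note <- NA_character_

  if (m == n) {
    est <- hill_observed(x, q)
    method <- "observed"
  } else if (m < n) {
    method <- "interpolated"
    if (q == 0) {
      term <- lchoose(n - x, m) - lchoose(n, m)
      est <- length(x) - sum(exp(term[is.finite(term)]))
    } else if (q == 1) {
      k <- seq_len(m)
      efk <- expected_fk(x, m)
      est <- exp(sum(-(k / m) * log(k / m) * efk))
    } else if (q == 2) {
      est <- 1 / (1 / m + (1 - 1 / m) * sum(x * (x - 1)) / (n * (n - 1)))
    } else {
      abort("interpolation implemented for q in {0, 1, 2}",
            class = "gammarep_invalid_input")
    }
  } else {
    f1 <- freq_count(x, 1); f2 <- freq_count(x, 2)
    if (f1 == 0) {
      est <- hill_observed(x, q)
      method <- "observed"
      note <- "no singletons: no unseen mass, observed value returned"
    } else {
      method <- "extrapolated"
      f0 <- f0_hat(f1, f2, n)
      mstar <- m - n
      if (q == 0) {
        est <- length(x) +
          f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar)
      } else if (q %in% c(1, 2)) {
        obs <- hill_observed(x, q)
        asy <- max(obs, if (q == 1) hill1_asymptote(x) else hill2_asymptote(x))
        r <- 1 - f1 / (n * f0 + f1)
        est <- asy - (asy - obs) * r^mstar
      } else {
        abort("extrapolation implemented for q in {0, 1, 2}",
              class = "gammarep_invalid_input")
      }
    }
  }
  tibble(q = q, m = m, coverage = coverage_estimate(x, m),
         estimate = est, method = method, note = note)
}

# smallest m with coverage_estimate(x, m) >= target (ties toward smaller m)
coverage_to_size <- function(x, target) {
  x <- as_abundance(x)
  n <- sum(x)
  full <- coverage_estimate(x)
  if (full >= target) {
    lo <- 1L; hi <- n
    while (lo < hi) { # binary search on the monotone coverage curve
      mid <- (lo + hi) %/% 2L
      if (coverage_estimate(x, mid) >= target) hi <- mid else lo <- mid + 1L
    }
    return(lo)
  }
  f1 <- freq_count(x, 1); f2 <- freq_count(x, 2)
  A <- coverage_A(n, f1, f2)
  if (A >= 1) {
    # f2 = 0: extrapolated coverage is flat and the target is unreachable
    abort("target coverage unreachable by extrapolation",
          class = "gammarep_invalid_input")
  }
  # solve 1 - (f1/n) A^(m*+1) >= target for the smallest integer m*
  mstar <- ceiling(log((1 - target) * n / f1) / log(A)) - 1
  mstar <- max(1, mstar)
  while (coverage_estimate(x, n + mstar) < target) mstar <- mstar + 1
  n + as.integer(mstar)
}

#' Hill number standardised to a common sample coverage
#'
#' Finds the smallest sample size m whose estimated coverage reaches
#' `target_coverage` (extrapolating when the full sample falls short) and
#' returns [hill_at_size()] at that m. Standardising to a fixed, deliberately
#' low coverage (default 0.1, the level used for repertoires whose
#' rarefaction curves are far from plateau) makes samples of very different
#' depth comparable.
#'
#' @param x Abundance vector.
#' @param target_coverage Coverage level in (0, 1); default 0.1.
#' @param q Diversity orders (default `c(0, 1, 2)`).
#' @return A tibble with one row per q: `q`, `m`, `coverage`, `estimate`,
#'   `method`, `note`.
#' @export
hill_at_coverage <- function(x, target_coverage = 0.1, q = c(0, 1, 2)) {
  if (target_coverage <= 0 || target_coverage >= 1) {
    abort("target_coverage must be in (0, 1)", class = "gammarep_invalid_input")
  }
  x <- as_abundance(x)
  f1 <- freq_count(x, 1)
  f2 <- freq_count(x, 2)
  full <- coverage_estimate(x)
  if (full < target_coverage && (f1 == 0 || f2 == 0)) {
    # without both singleton and doubleton information the extrapolated
    # coverage curve is flat and cannot reach the target
    out <- bind_rows(lapply(q, function(qq) hill_at_size(x, sum(x), qq)))
    out$note <- "target coverage unreachable; observed value returned"
    return(out)
  }
  m <- coverage_to_size(x, target_coverage)
  bind_rows(lapply(q, function(qq) hill_at_size(x, m, qq)))
}

#' Coverage-standardised diversity of a clonotype table
#'
#' Pools clonotype counts within each unit (by default bird x tissue,
#' pooling a bird's reads within tissue before estimation), computes Hill
#' numbers at the target coverage, and attaches a clonotype-level multinomial
#' bootstrap confidence interval (a resampling interval, not an analytic
#' variance formula).
#'
#' @param table Clonotype tibble from [build_clonotype_table()].
#' @param by Character vector of grouping columns defining a diversity unit
#'   (default `c("line", "tissue", "bird_id")`).
#' @param target_coverage Coverage level (default 0.1).
#' @param q Diversity orders (default `c(0, 1, 2)`).
#' @param conf Logical: attach bootstrap intervals (default TRUE).
#' @param replicates Bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @param min_reads Units with fewer reads are dropped with a warning
#'   (default 100, guarding against rarefying tiny samples).
#' @return A tibble with the grouping columns, `n`, `q`, `m`, `coverage`,
#'   `estimate`, `method` and, when `conf`, `lower`/`upper`.
#' @export
repertoire_diversity <- function(table, by = c("line", "tissue", "bird_id"),
                                 target_coverage = 0.1, q = c(0, 1, 2),
                                 conf = TRUE, replicates = 200, seed = 1L,
                                 min_reads = 100) {
  stopifnot(all(by %in% names(table)))
  units <- table |>
    group_by(across(dplyr::all_of(by)), .data$v_group, .data$junction_nt) |>
    summarise(read_count = sum(.data$read_count), .groups = "drop") |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(counts = list(.data$read_count), n = sum(.data$read_count),
              .groups = "drop")
  small <- units$n < min_reads
  if (any(small)) {
    warn(sprintf("dropping %d unit(s) below %d reads", sum(small), min_reads))
    units <- units[!small, , drop = FALSE]
  }
  est_one <- function(counts) {
    hill_at_coverage(counts, target_coverage = target_coverage, q = q)
  }
  out <- units |>
    mutate(res = purrr::map(.data$counts, est_one)) |>
    select(-"counts") |>
    tidyr::unnest("res")
  if (conf) {
    ci <- purrr::map2(units$counts, seq_len(nrow(units)), function(counts, i) {
      n <- sum(counts)
      p <- counts / n
      boot <- withr::with_seed(seed + i, {
        replicate(replicates, {
          resampled <- as.integer(rmultinom(1, n, p))
          hill_at_coverage(resampled[resampled > 0],
                           target_coverage = target_coverage, q = q)$estimate
        })
      })
      boot <- matrix(boot, nrow = length(q))
      tibble(q = q,
             lower = apply(boot, 1, quantile, 0.025, names = FALSE),
             upper = apply(boot, 1, quantile, 0.975, names = FALSE))
    })
    ci_tbl <- bind_rows(lapply(seq_along(ci), function(i) {
      ci[[i]] |> mutate(.unit = i)
    }))
    out <- out |>
      group_by(across(dplyr::all_of(by))) |>
      mutate(.unit = dplyr::cur_group_id()) |>
      ungroup()
    # align unit numbering with the order units were built in
    unit_ids <- units |>
      mutate(.unit = row_number()) |>
      select(dplyr::all_of(by), ".unit")
    out <- out |>
      select(-".unit") |>
      left_join(unit_ids, by = by) |>
      left_join(ci_tbl, by = c(".unit", "q")) |>
      select(-".unit")
  }
  out
}
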