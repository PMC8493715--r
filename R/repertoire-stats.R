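#' Build a clonotype table from annotated rearrangements
#'
#' Filters rearrangements to the analysis set (default: in-frame junctions,
#' the filter the usage figures are based on; `"productive"` additionally
#' excludes junctions containing a stop codon), drops reads without a
#' junction and reads whose grouped V call is not in the retained set
#' (flag `ambiguous_v_excluded`), then counts reads per
#' (line, bird, tissue, V group, junction).
#'
#' @param rearrangements Tibble from [annotate_reads()], carrying `bird_id`,
#'   `tissue` and `line` metadata columns (join the sample sheet beforehand
#'   if needed).
#' @param filter `"in_frame"` (default) or `"productive"`.
#' @return A clonotype tibble with columns `line`, `bird_id`, `tissue`,
#'   `v_group`, `junction_nt`, `read_count`.
#' @export
build_clonotype_table <- function(rearrangements,
                                  filter = c("in_frame", "productive")) {
  filter <- match.arg(filter)
  required <- c("v_call", "junction", "vj_in_frame", "productive",
                "bird_id", "tissue", "line", "flags")
  missing <- setdiff(required, names(rearrangements))
  if (length(missing)) {
    abort(paste("rearrangements missing columns:",
                paste(missing, collapse = ", ")),
          class = "gammarep_invalid_input")
  }
  keep <- if (filter == "in_frame") rearrangements$vj_in_frame else
    rearrangements$productive
  rearrangements |>
    dplyr::filter(!is.na(.data$junction), !is.na(keep) & keep,
                  !grepl("ambiguous_v_excluded", .data$flags, fixed = TRUE),
                  !is.na(.data$bird_id) & !is.na(.data$tissue) &
                    !is.na(.data$line)) |>
    count(.data$line, .data$bird_id, .data$tissue,
          v_group = .data$v_call, junction_nt = .data$junction,
          name = "read_count") |>
    arrange(.data$line, .data$bird_id, .data$tissue, .data$v_group,
            .data$junction_nt)
}

# per bird x tissue read counts and proportions over the full v_group grid
bird_usage <- function(table) {
  grid <- table |>
    distinct(.data$line, .data$tissue) |>
    dplyr::cross_join(table |> distinct(v_group = .data$v_group)) |>
    inner_join(table |> distinct(.data$line, .data$bird_id),
               by = "line", relationship = "many-to-many")
  counts <- table |>
    group_by(.data$line, .data$bird_id, .data$tissue, .data$v_group) |>
    summarise(reads = sum(.data$read_count), .groups = "drop")
  grid |>
    left_join(counts, by = c("line", "bird_id", "tissue", "v_group")) |>
    mutate(reads = dplyr::coalesce(.data$reads, 0L)) |>
    group_by(.data$line, .data$bird_id, .data$tissue) |>
    mutate(total = sum(.data$reads),
           proportion = if_else(.data$total > 0, .data$reads / .data$total,
                                NA_real_)) |>
    ungroup() |>
    dplyr::filter(.data$total > 0)
}

# Haldane-Anscombe style continuity adjustment before the logit: +0.5 reads
# to the numerator, +1 to the denominator, applied only at 0 or 1.
adjusted_logit <- function(reads, total) {
  p <- reads / total
  boundary <- p <= 0 | p >= 1
  p[boundary] <- (reads[boundary] + 0.5) / (total[boundary] + 1)
  qlogis(p)
}

#' Bootstrap confidence interval for a mean proportion across birds
#'
#' Resamples birds with replacement, recomputes the mean of logit-transformed
#' proportions per replicate and back-transforms the 2.5/97.5 percentiles.
#' Exact zero or one proportions are continuity-adjusted (+0.5 reads /
#' +1 read) when `reads`/`totals` are supplied, or nudged by `eps` otherwise.
#'
#' @param proportions Per-bird proportions.
#' @param replicates Bootstrap replicates (default 500).
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param reads,totals Optional per-bird read counts behind the proportions,
#'   used for the continuity adjustment at 0/1.
#' @param eps Fallback nudge for boundary proportions without counts.
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @export
bootstrap_ci <- function(proportions, replicates = 500, seed = 1L,
                         reads = NULL, totals = NULL, eps = 1e-4) {
  n <- length(proportions)
  if (n == 0) abort("no proportions given", class = "gammarep_invalid_input")
  if (!is.null(reads) && !is.null(totals)) {
    lg <- adjusted_logit(reads, totals)
  } else {
    p <- pmin(pmax(proportions, eps), 1 - eps)
    lg <- qlogis(p)
  }
  if (n == 1) {
    warn("single bird: degenerate confidence interval")
    est <- plogis(lg)
    return(c(lower = est, upper = est))
  }
  means <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * replicates, replace = TRUE), nrow = n)
    colMeans(matrix(lg[idx], nrow = n))
  })
  q <- quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  c(lower = plogis(q[1]), upper = plogis(q[2]))
}

#' TRGV usage proportions per tissue with bootstrap confidence intervals
#'
#' Per bird and tissue, a V group's proportion is its reads over the bird's
#' total reads in that tissue; the tissue-level mean is the unweighted mean
#' over birds (each bird counts once, mirroring a bird-level random effect).
#' 95% intervals come from a hierarchical bird-level bootstrap of the
#' logit-transformed proportions ([bootstrap_ci()]).
#'
#' @param table Clonotype tibble from [build_clonotype_table()].
#' @param replicates Bootstrap replicates (default 500).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble of class `trgv_usage` with columns `line`, `tissue`,
#'   `v_group`, `n_birds`, `mean_prop`, `lower`, `upper`.
#' @export
usage_proportions <- function(table, replicates = 500, seed = 1L) {
  per_bird <- bird_usage(table)
  if (nrow(per_bird) == 0) {
    warn("no tissues with reads")
    return(structure(tibble(), class = c("trgv_usage", "tbl_df", "tbl", "data.frame")))
  }
  out <- per_bird |>
    group_by(.data$line, .data$tissue, .data$v_group) |>
    summarise(
      n_birds = n(),
      mean_prop = mean(.data$proportion),
      ci = list(bootstrap_ci(.data$proportion, replicates = replicates,
                             seed = seed, reads = .data$reads,
                             totals = .data$total)),
      .groups = "drop"
    ) |>
    mutate(lower = vapply(.data$ci, `[[`, numeric(1), "lower"),
           upper = vapply(.data$ci, `[[`, numeric(1), "upper")) |>
    select(-"ci")
  attr(out, "per_bird") <- per_bird
  class(out) <- c("trgv_usage", class(out))
  out
}

#' Bootstrap contrast between two sets of per-bird proportions
#'
#' Difference of logit-scale means under a bird-level bootstrap; the p-value
#' is the two-sided bootstrap tail probability of the difference crossing
#' zero (a bootstrap p-value, not a mixed-model Wald/Satterthwaite p).
#'
#' @param prop_a,prop_b Per-bird proportions for the two groups.
#' @param replicates Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return A tibble with `estimate` (difference of back-transformed means),
#'   `lower`, `upper` (95% interval of the difference on the proportion
#'   scale difference of means), and `p_value`.
#' @export
bootstrap_contrast <- function(prop_a, prop_b, replicates = 500, seed = 1L) {
  eps <- 1e-4
  la <- qlogis(pmin(pmax(prop_a, eps), 1 - eps))
  lb <- qlogis(pmin(pmax(prop_b, eps), 1 - eps))
  diffs <- withr::with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      mean(plogis(sample(la, length(la), replace = TRUE))) -
        mean(plogis(sample(lb, length(lb), replace = TRUE)))
    }, numeric(1))
  })
  est <- mean(plogis(la)) - mean(plogis(lb))
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  tibble(estimate = est,
         lower = quantile(diffs, 0.025, names = FALSE),
         upper = quantile(diffs, 0.975, names = FALSE),
         p_value = min(1, max(p, 1 / replicates)))
}

#' @export
generics::tidy

#' @export
generics::glance

#' @rdname usage_proportions
#' @param x A `trgv_usage` object.
#' @param ... Unused.
#' @method tidy trgv_usage
#' @export
tidy.trgv_usage <- function(x, ...) {
  as_tibble(unclass(x))
}
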