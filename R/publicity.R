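#' Classify clonotypes as private or public across birds
#'
#' A clonotype's penetrance is the fraction of the line's birds in which it
#' is detected, pooling all of a bird's tissues at any read frequency. Bins
#' are half-open: `p100` at penetrance 1, `p80` in \[0.8, 1), `p60` in
#' \[0.6, 0.8), otherwise `private`. Every clonotype appears exactly once.
#'
#' @param table Clonotype tibble from [build_clonotype_table()].
#' @param line Line to analyse (default: the single line present).
#' @param thresholds Penetrance thresholds (default `c(0.6, 0.8, 1.0)`).
#' @return A tibble with `v_group`, `junction_nt`, `n_birds_present`,
#'   `penetrance`, `bin`, `read_count` (total reads of the clone in the
#'   line).
#' @export
compute_publicity <- function(table, line = NULL,
                              thresholds = c(0.6, 0.8, 1.0)) {
  stopifnot(length(thresholds) == 3)
  if (is.null(line)) {
    lines <- unique(table$line)
    if (length(lines) != 1) {
      abort("table contains several lines; pick one", class = "gammarep_invalid_input")
    }
    line <- lines
  }
  tab <- table |> dplyr::filter(.data$line == !!line)
  n_birds <- dplyr::n_distinct(tab$bird_id)
  if (n_birds < 2) {
    abort("publicity undefined for a single-bird line",
          class = "gammarep_invalid_input")
  }
  tab |>
    group_by(.data$v_group, .data$junction_nt) |>
    summarise(n_birds_present = dplyr::n_distinct(.data$bird_id),
              read_count = sum(.data$read_count), .groups = "drop") |>
    mutate(penetrance = .data$n_birds_present / n_birds,
           bin = dplyr::case_when(
             .data$penetrance >= thresholds[3] ~ "p100",
             .data$penetrance >= thresholds[2] ~ "p80",
             .data$penetrance >= thresholds[1] ~ "p60",
             TRUE ~ "private"
           ))
}

publicity_bins <- c("private", "p60", "p80", "p100")

#' Read-weighted publicity bin shares per V group
#'
#' For each V group, the share of the group's reads falling in each publicity
#' bin; shares sum to 1 over the four bins.
#'
#' @param records Publicity records from [compute_publicity()].
#' @return A tibble with `v_group`, `bin`, `reads`, `share` (all four bins
#'   present per V group).
#' @export
public_fraction_by_v <- function(records) {
  records |>
    group_by(.data$v_group, .data$bin) |>
    summarise(reads = sum(.data$read_count), .groups = "drop") |>
    tidyr::complete(v_group = unique(records$v_group),
                    bin = publicity_bins, fill = list(reads = 0)) |>
    group_by(.data$v_group) |>
    mutate(share = .data$reads / sum(.data$reads)) |>
    ungroup() |>
    mutate(bin = factor(.data$bin, levels = publicity_bins)) |>
    arrange(.data$v_group, .data$bin)
}

bin_rank <- function(bin) match(bin, publicity_bins) - 1L  # private = 0

#' Shared public repertoire between two lines
#'
#' A clone public at level L in one line counts as shared when it attains
#' level L or higher in the other line (levels are cumulative:
#' p100 > p80 > p60). In `weighted` mode each clone contributes its read
#' share of the line's public repertoire at that level; in `unweighted` mode
#' clones count equally.
#'
#' @param records_a,records_b Publicity records of the two lines
#'   ([compute_publicity()]), sharing the clonotype key.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return A tibble with `level`, `line` (`"a"`/`"b"`), `n_public`,
#'   `shared_prop` (`NA` when a line has no public clones at that level).
#' @export
cross_line_sharing <- function(records_a, records_b,
                               mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  one_direction <- function(from, to, level, lab) {
    lv <- bin_rank(level)
    pub <- from |> dplyr::filter(bin_rank(.data$bin) >= lv)
    if (nrow(pub) == 0) {
      return(tibble(level = level, line = lab, n_public = 0L,
                    shared_prop = NA_real_))
    }
    other <- to |>
      dplyr::filter(bin_rank(.data$bin) >= lv) |>
      select("v_group", "junction_nt")
    pub <- pub |>
      mutate(shared = paste(.data$v_group, .data$junction_nt) %in%
               paste(other$v_group, other$junction_nt))
    prop <- if (mode == "weighted") {
      sum(pub$read_count[pub$shared]) / sum(pub$read_count)
    } else {
      mean(pub$shared)
    }
    tibble(level = level, line = lab, n_public = nrow(pub),
           shared_prop = prop)
  }
  bind_rows(lapply(c("p60", "p80", "p100"), function(lv) {
    bind_rows(one_direction(records_a, records_b, lv, "a"),
              one_direction(records_b, records_a, lv, "b"))
  })) |>
    mutate(mode = mode)
}

#' Down-sample a line to a fixed number of birds
#'
#' Uniform random subset of birds without replacement; all reads of the
#' chosen birds are retained. Used to compare lines with unequal bird counts
#' (e.g. down-sampling eight birds to five).
#'
#' @param table Clonotype tibble.
#' @param line Line to down-sample.
#' @param n_target Number of birds to keep.
#' @param seed Integer seed (reproducible given the seed).
#' @return The clonotype tibble restricted to the sampled birds (other lines
#'   untouched).
#' @export
downsample_birds <- function(table, line, n_target, seed = 1L) {
  birds <- unique(table$bird_id[table$line == line])
  if (n_target > length(birds)) {
    abort("n_target exceeds the number of birds", class = "gammarep_invalid_input")
  }
  keep <- withr::with_seed(seed, sample(birds, n_target))
  table |>
    dplyr::filter(.data$line != !!line | .data$bird_id %in% keep)
}

#' Compare fully-public repertoire shares between two lines
#'
#' Per V group present in both lines, computes the read share of
#' fully-public (`p100`) clones in each line and compares the paired-by-gene
#' shares with a rank-sum test (`stats::wilcox.test`, unpaired two-sample
#' form), optionally Benjamini-Hochberg corrected per-gene tests.
#'
#' @param records_a,records_b Publicity records of the two lines.
#' @param bin Publicity bin to compare (default `"p100"`).
#' @return A list with `by_v` (per-V shares for both lines), `summary`
#'   (mean and SD of shares per line) and `test` (the rank-sum test result).
#' @export
publicity_line_test <- function(records_a, records_b, bin = "p100") {
  share_of <- function(records, lab) {
    public_fraction_by_v(records) |>
      dplyr::filter(.data$bin == !!bin) |>
      select("v_group", "share") |>
      mutate(line = lab)
  }
  by_v <- bind_rows(share_of(records_a, "a"), share_of(records_b, "b")) |>
    tidyr::pivot_wider(names_from = "line", values_from = "share") |>
    dplyr::filter(complete.cases(.data$a, .data$b))
  summary <- tibble(line = c("a", "b"),
                    mean_share = c(mean(by_v$a), mean(by_v$b)),
                    sd_share = c(stats::sd(by_v$a), stats::sd(by_v$b)))
  test <- wilcox.test(by_v$a, by_v$b, exact = FALSE)
  list(by_v = by_v, summary = summary, test = test)
}
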