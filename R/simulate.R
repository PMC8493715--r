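#' Configuration for the repertoire simulator
#'
#' Defines a multi-bird, multi-tissue TCR gamma repertoire and the 5'RACE
#' read structure built from it. The defaults emulate the study conditions
#' the pipeline targets: eight birds of one line across thymus, spleen and
#' gut tissues, a per-TRGV usage distribution dominated by one gene (35% of
#' the repertoire), junctions built from trimmed V tails, random N-region
#' insertions and trimmed J heads, optional public clones planted across
#' birds at a set penetrance, and per-base substitution sequencing errors.
#'
#' @param seed Integer seed; the same seed reproduces the simulation
#'   byte-for-byte.
#' @param lines Named list: line label -> number of birds (default
#'   `list(ISA_Brown = 8)`).
#' @param tissues Tissue labels (default the seven-tissue panel).
#' @param reads_per_sample Reads per bird x tissue sample (default 5000).
#' @param clones_per_bird Private clonotypes per bird (default 300).
#' @param v_usage Named per-V usage probabilities (default
#'   [default_v_usage()]: the dominant gene at 0.35).
#' @param j_usage Named per-J probabilities (default uniform).
#' @param trim_v_prob,trim_j_prob Geometric per-base continuation
#'   probabilities for exonuclease trimming of the V tail / J head (means
#'   about 1 nt and 2 nt).
#' @param trim_v_max,trim_j_max Trim caps so the junction anchors survive.
#' @param n_insert_mean Mean Poisson length of the untemplated N insertion
#'   (default 8).
#' @param insert_base_probs Base composition of insertions (default
#'   uniform).
#' @param in_frame_only Adjust insertion lengths so every clone's junction
#'   is in frame (default TRUE; the analysed repertoire is the in-frame
#'   one).
#' @param public_pool List of public clone specs, each a list with `v_id`,
#'   `penetrance`, `expansion_factor` (weight of the clone relative to one
#'   private clone of the same gene) and optional `junction_nt`.
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param barcode_length Sample barcode length (default 12).
#' @param adapter 5' universal adapter placed after the barcode.
#' @param c_head Length of the constant-region fragment kept at the 3' end.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              lines = list(ISA_Brown = 8L),
                              tissues = c("thymus", "spleen", "duodenum",
                                          "jejunum", "ileum", "caecum",
                                          "colon"),
                              reads_per_sample = 5000L,
                              clones_per_bird = 300L,
                              v_usage = NULL,
                              j_usage = NULL,
                              trim_v_prob = 0.5, trim_v_max = 3L,
                              trim_j_prob = 0.4, trim_j_max = 10L,
                              n_insert_mean = 8, insert_base_probs =
                                c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                              in_frame_only = TRUE,
                              public_pool = list(),
                              error_rate = 0.001,
                              barcode_length = 12L,
                              adapter = "AAGCAGTGGTATCAACGCAGAGT",
                              c_head = 30L) {
  cfg <- list(seed = as.integer(seed), lines = lines, tissues = tissues,
              reads_per_sample = as.integer(reads_per_sample),
              clones_per_bird = as.integer(clones_per_bird),
              v_usage = v_usage, j_usage = j_usage,
              trim_v_prob = trim_v_prob, trim_v_max = as.integer(trim_v_max),
              trim_j_prob = trim_j_prob, trim_j_max = as.integer(trim_j_max),
              n_insert_mean = n_insert_mean,
              insert_base_probs = insert_base_probs,
              in_frame_only = isTRUE(in_frame_only),
              public_pool = public_pool,
              error_rate = error_rate,
              barcode_length = as.integer(barcode_length),
              adapter = adapter, c_head = as.integer(c_head))
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    abort("error_rate must be in [0, 1)", class = "gammarep_config_error")
  }
  if (abs(sum(insert_base_probs) - 1) > 1e-9) {
    abort("insert_base_probs must sum to 1", class = "gammarep_config_error")
  }
  for (p in public_pool) {
    if (is.null(p$v_id) || is.null(p$penetrance) || is.null(p$expansion_factor)) {
      abort("public_pool entries need v_id, penetrance, expansion_factor",
            class = "gammarep_config_error")
    }
    if (p$penetrance <= 0 || p$penetrance > 1) {
      abort("penetrance must be in (0, 1]", class = "gammarep_config_error")
    }
    if (p$expansion_factor < 1) {
      abort("expansion_factor must be >= 1", class = "gammarep_config_error")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Default per-TRGV usage distribution for simulations
#'
#' A usage profile over the expressed V genes of a reference in which a
#' single dominant gene (default TRGV3.3) takes `dominant_usage` of the
#' repertoire and the remainder is spread geometrically over the other
#' expressed genes -- the dominance structure characteristic of the chicken
#' TRG repertoire.
#'
#' @param reference Reference tibble ([trg_reference()]).
#' @param dominant Dominant V id (default `"TRGV3.3"`).
#' @param dominant_usage Its usage share (default 0.35).
#' @return Named probability vector over expressed V ids.
#' @export
default_v_usage <- function(reference, dominant = "TRGV3.3",
                            dominant_usage = 0.35) {
  expressed <- reference |>
    dplyr::filter(.data$segment_type == "V",
                  .data$functional_status == "functional") |>
    pull(.data$id)
  stopifnot(dominant %in% expressed)
  others <- setdiff(expressed, dominant)
  w <- 0.85^seq_along(others)
  w <- (1 - dominant_usage) * w / sum(w)
  u <- c(setNames(dominant_usage, dominant), setNames(w, others))
  u[order(names(u))]
}

rand_bases <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  if (n <= 0) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# geometric trim capped; p is the stop probability parameterisation of rgeom
draw_trim <- function(n, prob, cap) pmin(rgeom(n, prob), cap)

make_barcodes <- function(n, len, min_dist = 3L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- rand_bases(len)
    ok <- all(vapply(out, function(b) {
      sum(strsplit(cand, "")[[1]] != strsplit(b, "")[[1]]) >= min_dist
    }, logical(1)))
    if (ok) out <- c(out, cand)
  }
  out
}

# junction and read parts of one clone; anchors are always retained
build_clone_seq <- function(vrow, jrow, trim_v, trim_j, insert, cfg) {
  v_seq <- vrow$sequence
  v_len <- nchar(v_seq)
  v_part <- substr(v_seq, 1, v_len - trim_v)             # read's V portion
  v_tail <- substr(v_seq, vrow$anchor_offset + 1, v_len - trim_v)
  j_seq <- jrow$sequence
  j_head <- substr(j_seq, trim_j + 1, jrow$anchor_offset + 3)
  j_rest <- substr(j_seq, jrow$anchor_offset + 4, nchar(j_seq))
  junction <- paste0(v_tail, insert, j_head)
  list(junction = junction,
       insert = insert,
       body = paste0(substr(v_seq, 1, vrow$anchor_offset), junction, j_rest))
}

#' Simulate a ground-truthed multi-bird repertoire
#'
#' Per bird, draws private clonotypes with V genes following `v_usage` and
#' junctions built as trimmed V tail + random insertion + trimmed J head
#' (anchors always preserved); public-pool clones are planted, with a shared
#' junction, in `ceiling(penetrance * n_birds)` randomly chosen birds per
#' line. Within each V gene, a bird's reads are split between its clones
#' with private clones weighted 1 and public clones weighted by
#' `expansion_factor`; across V genes read totals follow `v_usage`, so
#' planting public clones does not distort usage. Each bird x tissue sample
#' holds exactly `reads_per_sample` reads (multinomial allocation over the
#' bird's clones).
#'
#' @param config A [simulation_config()].
#' @param reference Reference tibble ([trg_reference()]).
#' @return A list with `clonotypes` (truth tibble: `line`, `bird_id`,
#'   `tissue`, `v_group` (true V id), `junction_nt`, `read_count`,
#'   `clone_id`, `is_public`), `clones` (per-clone definitions incl. the
#'   full read body), and `sample_sheet`.
#' @export
simulate_repertoire <- function(config, reference = trg_reference()) {
  stopifnot(inherits(config, "sim_config"))
  validate_reference(reference)
  withr::with_seed(config$seed, simulate_repertoire_impl(config, reference))
}

simulate_repertoire_impl <- function(cfg, reference) {
  vref <- reference |>
    dplyr::filter(.data$segment_type == "V",
                  .data$functional_status != "pseudogene")
  jref <- reference |> dplyr::filter(.data$segment_type == "J")
  v_usage <- cfg$v_usage %||% default_v_usage(reference)
  if (abs(sum(v_usage) - 1) > 1e-9) {
    abort("v_usage must sum to 1", class = "gammarep_config_error")
  }
  if (!all(names(v_usage) %in% vref$id)) {
    abort("v_usage names not in reference", class = "gammarep_config_error")
  }
  for (p in cfg$public_pool) {
    if (!p$v_id %in% names(v_usage)) {
      abort(paste0("public clone v_id not in v_usage: ", p$v_id),
            class = "gammarep_config_error")
    }
  }
  j_usage <- cfg$j_usage %||%
    setNames(rep(1 / nrow(jref), nrow(jref)), jref$id)

  draw_insert_len <- function(junction_len_wo_insert) {
    len <- rpois(1, cfg$n_insert_mean)
    if (cfg$in_frame_only) {
      # stretch to the nearest length putting the junction in frame
      r <- (junction_len_wo_insert + len) %% 3
      if (r != 0) len <- len + (3 - r)
    }
    len
  }

  new_clone <- function(v_id, j_id, junction_nt = NULL) {
    vrow <- vref[vref$id == v_id, ]
    jrow <- jref[jref$id == j_id, ]
    if (!is.null(junction_nt)) {
      # rebuild the body around a prescribed junction
      body <- paste0(substr(vrow$sequence, 1, vrow$anchor_offset), junction_nt,
                     substr(jrow$sequence, jrow$anchor_offset + 4,
                            nchar(jrow$sequence)))
      return(list(v_id = v_id, j_id = j_id, junction = junction_nt, body = body))
    }
    trim_v <- draw_trim(1, cfg$trim_v_prob, cfg$trim_v_max)
    trim_j <- draw_trim(1, cfg$trim_j_prob, cfg$trim_j_max)
    base_len <- (nchar(vrow$sequence) - vrow$anchor_offset - trim_v) +
      (jrow$anchor_offset + 3 - trim_j)
    ins <- rand_bases(draw_insert_len(base_len), cfg$insert_base_probs)
    parts <- build_clone_seq(vrow, jrow, trim_v, trim_j, ins, cfg)
    list(v_id = v_id, j_id = j_id, junction = parts$junction,
         body = parts$body)
  }

  clones <- list()
  assignments <- list()   # per line: clone_id x bird presence + weight
  clone_id <- 0L

  for (line in names(cfg$lines)) {
    n_birds <- cfg$lines[[line]]
    birds <- sprintf("%s_bird%02d", line, seq_len(n_birds))

    # public clones of this line: planted in a random subset of birds
    pub_defs <- list()
    for (p in cfg$public_pool) {
      clone_id <- clone_id + 1L
      j_id <- p$j_id %||% sample(names(j_usage), 1, prob = j_usage)
      cl <- new_clone(p$v_id, j_id, junction_nt = p$junction_nt)
      in_birds <- sample(birds, ceiling(p$penetrance * n_birds))
      clones[[clone_id]] <- tibble(
        clone_id = clone_id, line = line, v_id = cl$v_id, j_id = cl$j_id,
        junction_nt = cl$junction, body = cl$body, is_public = TRUE,
        weight = p$expansion_factor)
      pub_defs[[length(pub_defs) + 1]] <-
        tibble(clone_id = clone_id, bird_id = in_birds,
               v_id = cl$v_id, weight = p$expansion_factor)
    }

    # private clones: per bird, V genes allocated near-exactly by usage
    for (b in birds) {
      n_per_v <- floor(cfg$clones_per_bird * v_usage)
      short <- cfg$clones_per_bird - sum(n_per_v)
      if (short > 0) {
        extra <- sample(names(v_usage), short, replace = TRUE, prob = v_usage)
        for (e in extra) n_per_v[e] <- n_per_v[e] + 1
      }
      for (v_id in names(n_per_v)) {
        k <- n_per_v[[v_id]]
        if (k == 0) next
        for (i in seq_len(k)) {
          clone_id <- clone_id + 1L
          j_id <- sample(names(j_usage), 1, prob = j_usage)
          cl <- new_clone(v_id, j_id)
          clones[[clone_id]] <- tibble(
            clone_id = clone_id, line = line, v_id = cl$v_id, j_id = cl$j_id,
            junction_nt = cl$junction, body = cl$body, is_public = FALSE,
            weight = 1)
          assignments[[length(assignments) + 1]] <-
            tibble(clone_id = clone_id, bird_id = b, v_id = v_id, weight = 1)
        }
      }
    }
    assignments <- c(assignments, pub_defs)
  }

  clones <- bind_rows(clones)
  assign_tbl <- bind_rows(assignments) |>
    left_join(clones |> select("clone_id", "line"), by = "clone_id")

  # reads: per bird x tissue, multinomial over the bird's clones with
  # per-V totals following v_usage and within-V weights as configured
  allocate_bird <- function(line, bird, tissue) {
    cl <- assign_tbl |>
      dplyr::filter(.data$line == !!line, .data$bird_id == !!bird)
    # normalise weights within V, then scale by the V's usage share
    cl <- cl |>
      group_by(.data$v_id) |>
      mutate(p = .data$weight / sum(.data$weight) *
               v_usage[.data$v_id[1]]) |>
      ungroup()
    p <- cl$p / sum(cl$p)
    counts <- as.integer(rmultinom(1, cfg$reads_per_sample, p))
    tibble(line = line, bird_id = bird, tissue = tissue,
           clone_id = cl$clone_id, read_count = counts) |>
      dplyr::filter(.data$read_count > 0)
  }

  truth <- list()
  for (line in names(cfg$lines)) {
    birds <- sprintf("%s_bird%02d", line, seq_len(cfg$lines[[line]]))
    for (b in birds) {
      for (ts in cfg$tissues) {
        truth[[length(truth) + 1]] <- allocate_bird(line, b, ts)
      }
    }
  }
  truth <- bind_rows(truth) |>
    left_join(clones |>
                select("clone_id", v_group = "v_id", junction_nt = "junction_nt",
                       "is_public"),
              by = "clone_id") |>
    select("line", "bird_id", "tissue", "v_group", "junction_nt",
           "read_count", "clone_id", "is_public")

  samples <- truth |> distinct(.data$line, .data$bird_id, .data$tissue)
  sheet <- samples |>
    mutate(sample_id = paste(.data$bird_id, .data$tissue, sep = "_"),
           barcode = make_barcodes(nrow(samples), cfg$barcode_length)) |>
    select("sample_id", "barcode", "bird_id", "tissue", "line")

  list(clonotypes = truth, clones = clones, sample_sheet = sheet)
}

#' Assemble 5'RACE-style reads from a simulated repertoire
#'
#' Each read is barcode + universal adapter + the clone's rearranged body
#' (V through junction and J) + a constant-region head, with per-base
#' substitution errors at `error_rate`. At error rate 0 the demultiplex ->
#' annotate pipeline recovers sample, V call, J call and junction exactly
#' for every read whose V is unique in the reference (reads from
#' germline-identical V groups yield the grouped call).
#'
#' @param repertoire Result of [simulate_repertoire()].
#' @param config The same [simulation_config()].
#' @param reference Reference tibble.
#' @return A tibble of reads with truth columns: `read_id`, `sequence`,
#'   `quality`, `sample_id`, `line`, `bird_id`, `tissue`, `true_v`,
#'   `true_j`, `true_junction`, `junction_start`/`junction_end` (0-based
#'   half-open junction interval within the read, valid regardless of
#'   substitution errors), `clone_id`, `is_public`.
#' @export
simulate_reads <- function(repertoire, config, reference = trg_reference()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L,
                   simulate_reads_impl(repertoire, config, reference))
}

simulate_reads_impl <- function(rep, cfg, reference) {
  cref <- reference |> dplyr::filter(.data$segment_type == "C")
  c_part <- substr(cref$sequence[1], 1, cfg$c_head)

  vref <- reference |> dplyr::filter(.data$segment_type == "V")
  truth <- rep$clonotypes |>
    left_join(rep$clones |> select("clone_id", "body", j_id = "j_id"),
              by = "clone_id") |>
    left_join(rep$sample_sheet |> select("sample_id", "barcode", "bird_id",
                                         "tissue"),
              by = c("bird_id", "tissue")) |>
    left_join(vref |> select(v_group = "id", "anchor_offset"), by = "v_group")

  reads <- truth |>
    tidyr::uncount(.data$read_count) |>
    mutate(read_id = sprintf("read%07d", row_number()),
           sequence = paste0(.data$barcode, cfg$adapter, .data$body, c_part),
           # 0-based junction interval within the read (fixed even when
           # substitution errors later change the bases inside it)
           junction_start = nchar(.data$barcode) + nchar(cfg$adapter) +
             .data$anchor_offset,
           junction_end = .data$junction_start + nchar(.data$junction_nt))

  if (cfg$error_rate > 0) {
    lens <- nchar(reads$sequence)
    n_err <- rbinom(nrow(reads), lens, cfg$error_rate)
    idx <- which(n_err > 0)
    if (length(idx)) {
      bases <- c("A", "C", "G", "T")
      reads$sequence[idx] <- vapply(idx, function(i) {
        s <- strsplit(reads$sequence[i], "")[[1]]
        pos <- sample(length(s), n_err[i])
        s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1),
                         character(1))
        paste(s, collapse = "")
      }, character(1))
    }
  }

  reads |>
    mutate(quality = strrep("I", nchar(.data$sequence))) |>
    select("read_id", "sequence", "quality", "sample_id", "line",
           "bird_id", "tissue", true_v = "v_group",
           true_j = "j_id", true_junction = "junction_nt",
           "junction_start", "junction_end", "clone_id", "is_public")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
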