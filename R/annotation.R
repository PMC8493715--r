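#' Smith-Waterman local alignment
#'
#' Optimal local alignment under linear gap penalty. Default scoring is
#' match +5 / mismatch -4 (the classic EDNAFULL-style nucleotide weights) with
#' gap -8. Ties between equally scoring alignments resolve deterministically:
#' smallest reference start, then smallest query start, then shortest
#' alignment. `N` bases never match.
#'
#' @param query,ref Nucleotide strings.
#' @param match,mismatch,gap Scoring parameters.
#' @return A list with `score`, `q_start`, `q_end`, `r_start`, `r_end`
#'   (0-based half-open intervals) and a `cigar` string (`M`/`I`/`D`, `I` =
#'   extra query base). A score of 0 means no positive-scoring local
#'   alignment exists; the interval fields are then empty (0,0).
#' @export
#' @examples
#' smith_waterman("AAA", "AAA")$score  # 15
smith_waterman <- function(query, ref, match = 5L, mismatch = -4L, gap = -8L) {
  query <- check_dna(query, "query")
  ref <- check_dna(ref, "ref")
  sw_align_cpp(query, ref, as.integer(match), as.integer(mismatch),
               as.integer(gap))
}

#' Assign a gene segment to a read by exhaustive local alignment
#'
#' Aligns the read, in both orientations, against every functional reference
#' segment and reports the top-scoring segment. When two or more references
#' tie at the top score the call is the grouped id joining them in locus
#' order (e.g. `"TRGV2.7/2.18"`); when the top score falls below `min_score`
#' the call is `NA` with a `no_v`/`no_j` flag.
#'
#' @param read Nucleotide string.
#' @param refs Reference tibble rows of a single `segment_type`, ordered by
#'   locus position; pseudogenes are ignored.
#' @param min_score Minimum acceptable alignment score (default 60).
#' @param match,mismatch,gap Scoring parameters, as in [smith_waterman()].
#' @return A list with `call` (id, grouped id, or `NA`), `ids` (the tied
#'   segment ids), `strand` (+1/-1), `alignment` (of the oriented read against
#'   the first tied reference) and `flag` (`NA`, `"no_v"` or `"no_j"`).
#' @export
assign_segment <- function(read, refs, min_score = 60L, match = 5L,
                           mismatch = -4L, gap = -8L) {
  read <- check_dna(read, "read")
  stopifnot(is.data.frame(refs), nrow(refs) > 0)
  if (length(unique(refs$segment_type)) != 1) {
    abort("refs must share one segment_type", class = "gammarep_config_error")
  }
  type <- refs$segment_type[1]
  refs <- refs |>
    filter(.data$functional_status != "pseudogene") |>
    arrange(.data$locus_start)
  res <- assign_batch_cpp(read, toupper(refs$sequence), as.integer(match),
                          as.integer(mismatch), as.integer(gap),
                          as.integer(min_score), 0L, TRUE)
  ties <- res$ties[[1]]
  if (length(ties) == 0) {
    return(list(call = NA_character_, ids = character(0), strand = 1L,
                alignment = NULL,
                flag = if (type == "V") "no_v" else "no_j",
                score = res$score[1]))
  }
  ids <- refs$id[ties + 1L]
  list(call = group_label(ids), ids = ids, strand = res$strand[1],
       alignment = list(score = res$score[1], q_start = res$q_start[1],
                        q_end = res$q_end[1], r_start = res$r_start[1],
                        r_end = res$r_end[1], cigar = as.character(res$cigar[1])),
       flag = NA_character_, score = res$score[1])
}

#' Extract the CDR3 junction from an annotated read
#'
#' Maps the V segment's junction anchor (conserved Cys codon) and the J
#' segment's anchor end (conserved Phe codon, inclusive) through the two
#' alignments onto the read and returns the anchor-inclusive junction
#' nucleotide sequence, or `NA` when an anchor falls outside its alignment's
#' reference span or the mapped interval is empty.
#'
#' @param read Oriented read sequence (the strand the alignments were
#'   computed on).
#' @param v,j Reference rows (single segments) carrying `anchor_offset`.
#' @param v_aln,j_aln Alignments as returned by [smith_waterman()] /
#'   [assign_segment()].
#' @return Junction nucleotide string or `NA_character_`.
#' @export
extract_junction <- function(read, v, j, v_aln, j_aln) {
  if (is.na(v$anchor_offset) || is.na(j$anchor_offset)) return(NA_character_)
  start <- cigar_map_cpp(v_aln$cigar, v_aln$q_start, v_aln$r_start,
                         v_aln$r_end, as.integer(v$anchor_offset))
  jend <- cigar_map_cpp(j_aln$cigar, j_aln$q_start, j_aln$r_start,
                        j_aln$r_end, as.integer(j$anchor_offset + 2L))
  if (start < 0 || jend < 0) return(NA_character_)
  end <- jend + 1L
  if (start >= end) return(NA_character_)
  substr(read, start + 1L, end)
}

#' Classify a junction as in-frame / stop-free / productive
#'
#' A junction is in frame when its length is divisible by 3; stop codons
#' (TAA/TAG/TGA) are sought in frame 0; productive means in frame with no
#' stop codon.
#'
#' @param junction_nt Character vector of junction nucleotide sequences
#'   (`NA` allowed; propagates).
#' @return A tibble with logical columns `in_frame`, `has_stop`,
#'   `productive`.
#' @export
classify_productive <- function(junction_nt) {
  n <- length(junction_nt)
  in_frame <- !is.na(junction_nt) & nchar(junction_nt) %% 3 == 0 &
    nchar(junction_nt) > 0
  has_stop <- rep(FALSE, n)
  idx <- which(!is.na(junction_nt) & nchar(junction_nt) >= 3)
  if (length(idx)) {
    has_stop[idx] <- vapply(junction_nt[idx], function(s) {
      codons <- substring(s, seq(1, nchar(s) - 2, by = 3),
                          seq(3, nchar(s), by = 3))
      any(codons %in% c("TAA", "TAG", "TGA"))
    }, logical(1), USE.NAMES = FALSE)
  }
  tibble(in_frame = in_frame, has_stop = has_stop,
         productive = in_frame & !has_stop)
}

translate_junctions <- function(junction_nt, in_frame) {
  out <- rep(NA_character_, length(junction_nt))
  idx <- which(in_frame & !is.na(junction_nt) & !grepl("N", junction_nt))
  if (length(idx)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(junction_nt[idx]),
                                no.init.codon = TRUE)
    out[idx] <- as.character(aa)
  }
  out
}

#' Annotate demultiplexed reads against a germline reference
#'
#' The core annotation stage: per read, assign the V and J segment by
#' exhaustive local alignment of both orientations against every functional
#' reference segment, extract the anchor-inclusive CDR3 junction by mapping
#' the conserved anchors through the alignments, and classify productivity.
#' Grouped (ambiguous) V calls listed in `retained_groups` are kept and
#' flagged `ambiguous_v_retained`; any other grouped call is flagged
#' `ambiguous_v_excluded` and skipped by downstream tables while remaining in
#' the rearrangement output.
#'
#' @param reads Tibble with `read_id`, `sequence` and (typically after
#'   [demultiplex()]) `sample_id`; extra metadata columns are carried
#'   through.
#' @param reference Reference tibble from [trg_reference()].
#' @param min_score_v,min_score_j Minimum alignment scores (default 60).
#' @param match,mismatch,gap Alignment scoring.
#' @param kmer Length of the exact k-mer prescreen used to shortlist
#'   candidate references before alignment (a speed path that does not change
#'   calls at these reference sizes); 0 disables it.
#' @param retained_groups Grouped V calls retained for analysis, as lists of
#'   member ids (default [trg_ambiguous_groups()]).
#' @return A tibble in AIRR-flavoured layout: `sequence_id`, `v_call`,
#'   `j_call`, `junction`, `junction_aa`, `vj_in_frame`, `stop_codon`,
#'   `productive`, `v_score`, `j_score`, `flags` plus carried-through
#'   metadata. An attribute `"summary"` holds counts that partition the
#'   input.
#' @export
annotate_reads <- function(reads, reference, min_score_v = 60L,
                           min_score_j = 60L, match = 5L, mismatch = -4L,
                           gap = -8L, kmer = 12L,
                           retained_groups = trg_ambiguous_groups()) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  validate_reference(reference)
  reads <- as_tibble(reads)
  n <- nrow(reads)

  vrefs <- reference |>
    filter(.data$segment_type == "V",
           .data$functional_status != "pseudogene") |>
    arrange(.data$locus_start)
  jrefs <- reference |>
    filter(.data$segment_type == "J",
           .data$functional_status != "pseudogene") |>
    arrange(.data$locus_start)
  if (nrow(vrefs) == 0 || nrow(jrefs) == 0) {
    abort("reference must contain functional V and J segments",
          class = "gammarep_config_error")
  }

  seqs <- toupper(reads$sequence)
  vres <- assign_batch_cpp(seqs, toupper(vrefs$sequence), as.integer(match),
                           as.integer(mismatch), as.integer(gap),
                           as.integer(min_score_v), as.integer(kmer), TRUE)
  # orient reads by the V hit, then align J on the oriented strand only
  oriented <- seqs
  flipped <- which(vres$strand == -1L)
  if (length(flipped)) oriented[flipped] <- revcomp(seqs[flipped])
  jres <- assign_batch_cpp(oriented, toupper(jrefs$sequence), as.integer(match),
                           as.integer(mismatch), as.integer(gap),
                           as.integer(min_score_j), as.integer(kmer), FALSE)

  v_first <- vapply(vres$ties, function(t) if (length(t)) t[1] + 1L else NA_integer_,
                    integer(1))
  j_first <- vapply(jres$ties, function(t) if (length(t)) t[1] + 1L else NA_integer_,
                    integer(1))
  v_call <- vapply(vres$ties, function(t) {
    if (length(t) == 0) NA_character_ else group_label(vrefs$id[t + 1L])
  }, character(1))
  j_call <- vapply(jres$ties, function(t) {
    if (length(t) == 0) NA_character_ else group_label(jrefs$id[t + 1L])
  }, character(1))

  no_v <- is.na(v_call)
  no_j <- is.na(j_call)
  retained_labels <- vapply(retained_groups, group_label, character(1))
  grouped <- !no_v & grepl("/", v_call, fixed = TRUE)
  amb_retained <- grouped & v_call %in% retained_labels
  amb_excluded <- grouped & !v_call %in% retained_labels

  v_anchor <- vrefs$anchor_offset[v_first]
  j_anchor <- jrefs$anchor_offset[j_first]
  start <- cigar_map_cpp(vres$cigar, vres$q_start, vres$r_start, vres$r_end,
                         as.integer(v_anchor))
  jend <- cigar_map_cpp(jres$cigar, jres$q_start, jres$r_start, jres$r_end,
                        as.integer(j_anchor + 2L))
  ok <- !no_v & !no_j & start >= 0 & jend >= 0 & (start < jend + 1L)
  junction <- rep(NA_character_, n)
  junction[ok] <- substr(oriented[ok], start[ok] + 1L, jend[ok] + 1L)
  no_junction <- !no_v & !no_j & !ok

  prod <- classify_productive(junction)
  flags <- character(n)
  add_flag <- function(flags, which, flag) {
    flags[which] <- if_else(flags[which] == "", flag,
                            paste(flags[which], flag, sep = ","))
    flags
  }
  flags <- add_flag(flags, no_v, "no_v")
  flags <- add_flag(flags, no_j, "no_j")
  flags <- add_flag(flags, no_junction, "no_junction")
  flags <- add_flag(flags, amb_retained, "ambiguous_v_retained")
  flags <- add_flag(flags, amb_excluded, "ambiguous_v_excluded")

  meta <- reads |> select(-dplyr::any_of(c("sequence", "quality")))
  out <- meta |>
    rename(sequence_id = "read_id") |>
    mutate(v_call = v_call, j_call = j_call,
           junction = junction,
           junction_aa = translate_junctions(junction, prod$in_frame),
           vj_in_frame = if_else(is.na(junction), NA, prod$in_frame),
           stop_codon = if_else(is.na(junction), NA, prod$has_stop),
           productive = if_else(is.na(junction), NA, prod$productive),
           v_score = if_else(no_v, NA_integer_, vres$score),
           j_score = if_else(no_j, NA_integer_, jres$score),
           flags = flags)

  summary <- tibble(
    category = c("total", "no_v", "no_j", "no_junction",
                 "ambiguous_v_retained", "ambiguous_v_excluded", "annotated"),
    n_reads = c(n, sum(no_v), sum(!no_v & no_j), sum(no_junction),
                sum(amb_retained & ok), sum(amb_excluded & ok),
                sum(ok & !grouped))
  )
  attr(out, "summary") <- summary
  attr(out, "junction_convention") <- "anchor-inclusive (IMGT junction)"
  out
}
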