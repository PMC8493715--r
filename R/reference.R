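#' Load a TRG germline reference bundle
#'
#' Reads a germline segment bundle (FASTA sequences plus a TSV metadata table)
#' into a tibble with one row per gene segment. The packaged bundle models the
#' chicken TRG locus: 40 TRGV genes in four families (TRGV1-TRGV4, sizes
#' 6/22/7/5, of which 13 are pseudogenes), three TRGJ genes and a single TRGC,
#' numbered within each family from distal to proximal with respect to TRGC.
#' The packaged segment sequences are synthetic placeholders (the counts,
#' names, family structure and expression status follow the published locus
#' map); high-identity gene groups (TRGV2.7/2.18 and TRGV2.4/2.8/2.14/2.19)
#' are sequence-identical so that assignment ambiguity is faithfully
#' reproduced.
#'
#' @param fasta Path to the segment FASTA. Defaults to the packaged bundle.
#' @param metadata Path to the segment metadata TSV (columns `id`,
#'   `segment_type`, `family`, `family_index`, `functional_status`,
#'   `anchor_offset`, `rss`, `locus_start`, `locus_end`, `motif_block`,
#'   `note`). Coordinates are 0-based half-open on the plus strand.
#' @return A tibble with the metadata columns plus `sequence`, ordered by
#'   `locus_start`.
#' @export
#' @examples
#' ref <- trg_reference()
#' locus_summary(ref)
trg_reference <- function(fasta = NULL, metadata = NULL) {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "trg_synthetic_reference.fasta",
                         package = "gammarep", mustWork = TRUE)
  }
  if (is.null(metadata)) {
    metadata <- system.file("extdata", "trg_synthetic_reference.tsv",
                            package = "gammarep", mustWork = TRUE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- readr::read_tsv(metadata, show_col_types = FALSE,
                          col_types = readr::cols(
                            id = "c", segment_type = "c", family = "c",
                            family_index = "i", functional_status = "c",
                            anchor_offset = "i", rss = "c",
                            locus_start = "i", locus_end = "i",
                            motif_block = "c", note = "c"))
  if (!all(meta$id %in% names(seqs))) {
    abort("metadata ids missing from FASTA", class = "gammarep_invalid_input")
  }
  ref <- meta |>
    mutate(sequence = as.character(seqs[.data$id])) |>
    arrange(.data$locus_start)
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  stopifnot(is.data.frame(ref))
  required <- c("id", "segment_type", "family", "family_index",
                "functional_status", "anchor_offset", "locus_start",
                "locus_end", "sequence")
  missing <- setdiff(required, names(ref))
  if (length(missing)) {
    abort(paste("reference missing columns:", paste(missing, collapse = ", ")),
          class = "gammarep_invalid_input")
  }
  if (anyDuplicated(ref$id)) {
    abort("segment ids must be unique", class = "gammarep_invalid_input")
  }
  if (any(ref$locus_start >= ref$locus_end)) {
    abort("locus_start must be < locus_end", class = "gammarep_invalid_input")
  }
  srt <- ref[order(ref$locus_start), ]
  if (any(head(srt$locus_end, -1) > srt$locus_start[-1])) {
    abort("segments must not overlap", class = "gammarep_invalid_input")
  }
  anc <- !is.na(ref$anchor_offset)
  if (any(ref$anchor_offset[anc] >= nchar(ref$sequence[anc]) - 2)) {
    abort("anchor_offset must leave room for a full codon",
          class = "gammarep_invalid_input")
  }
  isv <- ref$segment_type == "V"
  expected <- paste0(ref$family[isv], ".", ref$family_index[isv])
  if (any(ref$id[isv] != expected)) {
    abort("V ids must equal family '.' family_index",
          class = "gammarep_invalid_input")
  }
  invisible(ref)
}

#' Percent sequence identity between two nucleotide sequences
#'
#' Identity is `100 * identical_positions / length_of_shorter_sequence`,
#' with identical positions counted on an end-gap-free global (overlap)
#' alignment scored match +1, mismatch -1, gap -2. Counting matched positions
#' of such an alignment keeps the value in `[0, 100]` by construction, and
#' aligning the lexicographically smaller sequence first makes the measure
#' exactly symmetric even when several alignments are optimal.
#'
#' @param a,b Nucleotide strings (A/C/G/T/N).
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' sequence_identity("ACGT", "ACGA")  # 75
sequence_identity <- function(a, b) {
  a <- check_dna(a, "a"); b <- check_dna(b, "b")
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  100 * Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Assign a query sequence to a gene family
#'
#' Applies the IMGT-style subgroup rule: the query joins the family of its
#' closest exemplar provided the identity reaches `threshold` percent
#' (default 75), otherwise it is `"unassigned"`. Ties between families at the
#' maximal identity resolve to the lexicographically first family, with a
#' warning.
#'
#' @param query Nucleotide string.
#' @param family_exemplars Named list: family label -> character vector of
#'   exemplar sequences.
#' @param threshold Minimum percent identity (default 75).
#' @return A single family label, or `"unassigned"`.
#' @export
assign_family <- function(query, family_exemplars, threshold = 75) {
  if (!is.list(family_exemplars) || length(family_exemplars) == 0 ||
      is.null(names(family_exemplars))) {
    abort("family_exemplars must be a non-empty named list",
          class = "gammarep_invalid_input")
  }
  best <- vapply(family_exemplars, function(ex) {
    max(vapply(ex, function(s) sequence_identity(query, s), numeric(1)))
  }, numeric(1))
  top <- max(best)
  if (top < threshold) return("unassigned")
  winners <- sort(names(best)[best == top])
  if (length(winners) > 1) {
    warn(paste0("family tie at identity ", signif(top, 4), ": ",
                paste(winners, collapse = ", "),
                "; returning the lexicographically first"))
  }
  winners[1]
}

#' Number gene segments within families by locus position
#'
#' Assigns `family_index` 1..k within each family in order of increasing
#' distance from the locus end distal to the single C segment, and rewrites V
#' ids as `family.index`. Idempotent: renaming already-named segments leaves
#' them unchanged.
#'
#' @param segments Reference tibble with `family`, `segment_type`,
#'   `locus_start`, `locus_end` columns.
#' @return The tibble with `family_index` (and V `id`s) rewritten.
#' @export
name_segments <- function(segments) {
  stopifnot(is.data.frame(segments))
  cs <- which(segments$segment_type == "C")
  if (length(cs) != 1) {
    abort("exactly one C segment required", class = "gammarep_structure_error")
  }
  c_mid <- (segments$locus_start[cs] + segments$locus_end[cs]) / 2
  span <- range(c(segments$locus_start, segments$locus_end))
  # the distal end is the locus end farther from C
  distal <- if (abs(span[1] - c_mid) >= abs(span[2] - c_mid)) span[1] else span[2]
  segments |>
    mutate(.dist = abs(.data$locus_start - distal)) |>
    group_by(.data$family) |>
    mutate(family_index = if_else(is.na(.data$family), .data$family_index,
                                  rank(.dist, ties.method = "first"))) |>
    ungroup() |>
    mutate(id = if_else(.data$segment_type == "V",
                        paste0(.data$family, ".", .data$family_index),
                        .data$id)) |>
    select(-".dist")
}

#' Summarise a locus annotation by gene family
#'
#' Per-family totals of V segments split into pseudogenes and expressed genes
#' (functional genes detected as expressed), plus a locus-wide total row that
#' also counts J and C segments.
#'
#' @param reference Reference tibble as returned by [trg_reference()].
#' @return A tibble with columns `family`, `total`, `pseudogenes`,
#'   `not_detected`, `expressed`; the final row (`family == "all_V"`) sums the
#'   families, followed by `J` and `C` rows.
#' @export
locus_summary <- function(reference) {
  validate_reference(reference)
  v <- reference |> filter(.data$segment_type == "V")
  fam <- v |>
    group_by(family = .data$family) |>
    summarise(
      total = n(),
      pseudogenes = sum(.data$functional_status == "pseudogene"),
      not_detected = sum(.data$functional_status == "not_detected_expressed"),
      expressed = sum(.data$functional_status == "functional"),
      .groups = "drop"
    ) |>
    arrange(.data$family)
  all_v <- fam |>
    summarise(family = "all_V", total = sum(.data$total),
              pseudogenes = sum(.data$pseudogenes),
              not_detected = sum(.data$not_detected),
              expressed = sum(.data$expressed))
  jc <- reference |>
    filter(.data$segment_type %in% c("J", "C")) |>
    group_by(family = .data$segment_type) |>
    summarise(total = n(), pseudogenes = 0L, not_detected = 0L,
              expressed = sum(.data$functional_status == "functional"),
              .groups = "drop")
  bind_rows(fam, all_v, jc)
}

#' Collapse a V gene id to its reporting group
#'
#' Gene segments that cannot be distinguished at the read level are reported
#' as grouped calls. The default groups are the two germline-identical sets in
#' the packaged reference, reported as `"TRGV2.7/2.18"` and
#' `"TRGV2.4/2.8/2.14/2.19"`.
#'
#' @param v_id Character vector of V ids (single genes).
#' @param groups List of character vectors of ids that form reporting groups.
#' @return Character vector of group labels (ids not in any group unchanged).
#' @export
v_call_group <- function(v_id, groups = trg_ambiguous_groups()) {
  out <- v_id
  for (g in groups) {
    out[out %in% g] <- group_label(g)
  }
  out
}

#' @rdname v_call_group
#' @export
trg_ambiguous_groups <- function() {
  list(c("TRGV2.7", "TRGV2.18"),
       c("TRGV2.4", "TRGV2.8", "TRGV2.14", "TRGV2.19"))
}

# "TRGV2.7/2.18"-style label: full first id, later ids without the TRGV prefix
group_label <- function(ids) {
  if (length(ids) == 1) return(ids)
  paste(c(ids[1], sub("^TRGV", "", ids[-1])), collapse = "/")
}
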