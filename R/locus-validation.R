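#' Restriction enzyme specification
#'
#' @param name Enzyme name.
#' @param recognition Recognition site as an IUPAC nucleotide pattern.
#' @param cut_offset 0-based offset of the top-strand cut within the pattern
#'   (0 = before the first base, up to pattern length = after the last).
#' @return A list of class `enzyme_spec`.
#' @export
#' @examples
#' drdi_enzyme()
enzyme_spec <- function(name, recognition, cut_offset) {
  recognition <- check_dna(recognition, "recognition pattern", allow_iupac = TRUE)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    abort("cut_offset must lie within the recognition pattern",
          class = "gammarep_invalid_input")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme_spec")
}

#' @rdname enzyme_spec
#' @details `drdi_enzyme()` returns DrdI with its standard REBASE definition,
#'   GACNNNN^NNGTC (cut after position 7 on the top strand). The pattern is
#'   its own reverse complement up to the ambiguity codes, so only the top
#'   strand is scanned during digestion.
#' @export
drdi_enzyme <- function() enzyme_spec("DrdI", "GACNNNNNNGTC", 7L)

#' Predict PCR amplicons from a template
#'
#' Finds all primer site pairs on the template (both strands are scanned, so
#' amplicons are reported regardless of which strand the forward primer
#' anneals to) and returns every amplicon below the length cap. Each amplicon
#' begins with a site matching the forward primer and ends with the reverse
#' complement of the reverse primer, each within `max_mismatches`.
#'
#' @param template Template nucleotide string.
#' @param forward,reverse Primer sequences, each written 5'->3' on its own
#'   strand.
#' @param max_mismatches Mismatches tolerated per primer site (default 0).
#' @param max_length Length cap for reported amplicons (default 20000).
#' @return A tibble with columns `start`, `end` (1-based inclusive template
#'   coordinates of the amplicon on the reported strand), `strand`, `length`,
#'   `sequence`, ordered by start then end. Zero rows when no site pair
#'   exists.
#' @export
in_silico_pcr <- function(template, forward, reverse, max_mismatches = 0,
                          max_length = 20000) {
  template <- check_dna(template, "template", allow_iupac = TRUE)
  forward <- check_dna(forward, "forward primer")
  reverse <- check_dna(reverse, "reverse primer")
  if (nchar(forward) < 12 || nchar(reverse) < 12) {
    abort("primers must be at least 12 nt", class = "gammarep_invalid_input")
  }

  scan_strand <- function(tmpl, strand) {
    subj <- Biostrings::DNAString(tmpl)
    f_hits <- Biostrings::matchPattern(forward, subj,
                                       max.mismatch = max_mismatches)
    r_hits <- Biostrings::matchPattern(revcomp(reverse), subj,
                                       max.mismatch = max_mismatches)
    if (length(f_hits) == 0 || length(r_hits) == 0) return(NULL)
    grid <- expand.grid(f = seq_along(f_hits), r = seq_along(r_hits))
    starts <- Biostrings::start(f_hits)[grid$f]
    ends <- Biostrings::end(r_hits)[grid$r]
    keep <- starts < ends & (ends - starts + 1) <= max_length &
      starts + nchar(forward) - 1 < ends - nchar(reverse) + 1
    if (!any(keep)) return(NULL)
    tibble(start = starts[keep], end = ends[keep], strand = strand,
           length = ends[keep] - starts[keep] + 1L,
           sequence = substring(tmpl, starts[keep], ends[keep]))
  }

  out <- bind_rows(scan_strand(template, "+"),
                   scan_strand(revcomp(template), "-"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(start = integer(0), end = integer(0),
                  strand = character(0), length = integer(0),
                  sequence = character(0)))
  }
  out |>
    distinct(.data$sequence, .keep_all = TRUE) |>
    arrange(.data$start, .data$end, .data$strand)
}

#' Digest an amplicon with a restriction enzyme
#'
#' Matches the enzyme's IUPAC recognition pattern exactly (ambiguity codes
#' expand, but no mismatches are tolerated: enzymes do not cut near-sites)
#' and cuts at `site_start + cut_offset` on a linear molecule.
#'
#' @param amplicon Nucleotide string.
#' @param enzyme An [enzyme_spec()].
#' @return Sorted integer vector of fragment lengths; the lengths always sum
#'   to the amplicon length, and a site-free (or too-short) amplicon returns
#'   its own length.
#' @export
#' @examples
#' digest_fragments(strrep("A", 50), drdi_enzyme())
digest_fragments <- function(amplicon, enzyme) {
  amplicon <- check_dna(amplicon, "amplicon")
  stopifnot(inherits(enzyme, "enzyme_spec"))
  len <- nchar(amplicon)
  if (nchar(enzyme$recognition) > len) return(len)
  hits <- Biostrings::matchPattern(enzyme$recognition,
                                   Biostrings::DNAString(amplicon),
                                   fixed = FALSE)
  cuts <- sort(unique(Biostrings::start(hits) - 1L + enzyme$cut_offset))
  cuts <- cuts[cuts > 0 & cuts < len]
  sort(diff(c(0L, cuts, len)))
}

#' Classify an observed fragment pattern against candidate locus structures
#'
#' Compares the observed fragment-length multiset to each candidate's expected
#' multiset, fragment by fragment after sorting, within `tolerance`
#' nucleotides. The unique matching candidate's label is returned;
#' `"ambiguous"` when none or several candidates match.
#'
#' @param observed Numeric vector of observed fragment lengths.
#' @param candidates Named list: structure label -> expected fragment lengths.
#' @param tolerance Per-fragment tolerance in nucleotides (default 0).
#' @return A structure label or `"ambiguous"`.
#' @export
classify_structure <- function(observed, candidates, tolerance = 0) {
  if (length(observed) == 0) {
    abort("empty fragment observation", class = "gammarep_invalid_input")
  }
  if (!is.list(candidates) || length(candidates) < 2 || is.null(names(candidates))) {
    abort("need at least two named candidate structures",
          class = "gammarep_invalid_input")
  }
  obs <- sort(observed)
  hit <- vapply(candidates, function(exp) {
    exp <- sort(exp)
    length(exp) == length(obs) && all(abs(exp - obs) <= tolerance)
  }, logical(1))
  if (sum(hit) == 1) names(candidates)[hit] else "ambiguous"
}
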