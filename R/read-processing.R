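#' Read and write FASTQ/FASTA as tibbles
#'
#' Thin wrappers around Biostrings IO (gzip-transparent) returning a tibble
#' with `read_id`, `sequence` and, for FASTQ, `quality`.
#'
#' @param path File path.
#' @return A tibble of reads.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)),
         quality = unname(as.character(Biostrings::quality(x))))
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- if ("quality" %in% names(reads) && !all(is.na(reads$quality))) {
    reads$quality
  } else {
    strrep("I", nchar(reads$sequence))
  }
  qx <- Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(qx, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `barcode`, `bird_id`, `tissue`,
#'   `line`.
#' @return A validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(readr::read_tsv(path, show_col_types = FALSE,
                                        col_types = readr::cols(.default = "c")))
}

validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "barcode", "bird_id", "tissue", "line")
  missing <- setdiff(required, names(sheet))
  if (length(missing)) {
    abort(paste("sample sheet missing columns:", paste(missing, collapse = ", ")),
          class = "gammarep_config_error")
  }
  if (anyDuplicated(sheet$barcode)) {
    abort("duplicate barcodes in sample sheet", class = "gammarep_config_error")
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort("duplicate sample ids in sample sheet", class = "gammarep_config_error")
  }
  if (length(unique(nchar(sheet$barcode))) != 1) {
    abort("all barcodes must have the same length", class = "gammarep_config_error")
  }
  if (any(is.na(sheet$tissue) | sheet$tissue == "") ||
      any(is.na(sheet$line) | sheet$line == "")) {
    abort("tissue and line must be non-empty", class = "gammarep_config_error")
  }
  check_dna(sheet$barcode, "barcode")
  as_tibble(sheet)
}

# Hamming distances between the fixed-offset substring of each read and each
# barcode; returns an n_reads x n_barcodes integer matrix.
barcode_mismatches <- function(subseq, barcodes) {
  blen <- nchar(barcodes[1])
  M <- matrix(unlist(strsplit(subseq, "", fixed = TRUE), use.names = FALSE),
              ncol = blen, byrow = TRUE)
  out <- matrix(0L, nrow = length(subseq), ncol = length(barcodes))
  for (b in seq_along(barcodes)) {
    bc <- strsplit(barcodes[b], "", fixed = TRUE)[[1]]
    mm <- integer(length(subseq))
    for (p in seq_len(blen)) mm <- mm + (M[, p] != bc[p])
    out[, b] <- mm
  }
  out
}

#' Demultiplex pooled reads by barcode
#'
#' Assigns each read to the unique sample whose barcode matches at
#' `barcode_offset` within `max_mismatches`, checking the read as given and
#' its reverse complement; matched reads are re-oriented so the barcode lies
#' on the given strand. Reads matching zero or two-plus barcodes (or too short
#' to contain the barcode) are routed to `"undetermined"` with a reason. No
#' read is dropped or duplicated.
#'
#' @param reads Tibble with `read_id`, `sequence`, optional `quality`.
#' @param sheet Sample sheet tibble (see [read_sample_sheet()]).
#' @param max_mismatches Barcode mismatches tolerated (default 0).
#' @param barcode_offset 0-based position of the barcode within the read
#'   (default 0).
#' @return A list with `reads` (input tibble plus `sample_id` --
#'   `"undetermined"` where unassigned -- and `reason`) and `counts` (tibble
#'   of per-sample read counts, including undetermined).
#' @export
demultiplex <- function(reads, sheet, max_mismatches = 0, barcode_offset = 0) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  reads <- as_tibble(reads)
  n <- nrow(reads)
  blen <- nchar(sheet$barcode[1])
  need <- barcode_offset + blen

  sample_id <- rep("undetermined", n)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    too_short <- nchar(reads$sequence) < need
    reason[too_short] <- "too_short"
    ok <- which(!too_short)
    if (length(ok)) {
      fwd_sub <- toupper(substr(reads$sequence[ok], barcode_offset + 1, need))
      rev_seq <- revcomp(reads$sequence[ok])
      rev_sub <- toupper(substr(rev_seq, barcode_offset + 1, need))
      mm_f <- barcode_mismatches(fwd_sub, sheet$barcode)
      mm_r <- barcode_mismatches(rev_sub, sheet$barcode)
      mm <- pmin(mm_f, mm_r)
      hit <- mm <= max_mismatches
      nhit <- rowSums(hit)
      assigned <- nhit == 1
      which_bc <- max.col(-mm, ties.method = "first")
      sample_id[ok[assigned]] <- sheet$sample_id[which_bc[assigned]]
      reason[ok[!assigned]] <- if_else(nhit[!assigned] == 0, "no_barcode",
                                       "multiple_barcodes")
      # re-orient reads whose barcode matched on the reverse complement only
      flip <- assigned &
        (mm_r[cbind(seq_along(ok), which_bc)] <
           mm_f[cbind(seq_along(ok), which_bc)])
      if (any(flip)) {
        idx <- ok[flip]
        reads$sequence[idx] <- rev_seq[flip]
        if ("quality" %in% names(reads)) {
          reads$quality[idx] <- vapply(strsplit(reads$quality[idx], "", fixed = TRUE),
                                       function(q) paste(rev(q), collapse = ""),
                                       character(1))
        }
      }
    }
  }
  out <- reads |> mutate(sample_id = sample_id, reason = reason)
  counts <- out |>
    count(.data$sample_id, name = "n_reads") |>
    arrange(.data$sample_id)
  # samples with zero reads still appear in the counts
  zero <- setdiff(sheet$sample_id, counts$sample_id)
  if (length(zero)) {
    counts <- bind_rows(counts, tibble(sample_id = zero, n_reads = 0L)) |>
      arrange(.data$sample_id)
  }
  list(reads = out, counts = counts)
}
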