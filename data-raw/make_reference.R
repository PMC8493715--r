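# Builds the packaged synthetic TRG germline reference bundle:
#   inst/extdata/trg_synthetic_reference.fasta
#   inst/extdata/trg_synthetic_reference.tsv
#
# Segment counts, names, families, pseudogene/expression status and the
# distal->proximal numbering follow the published chicken TRG locus map
# (40 TRGV in four families of 6/22/7/5 with 2/8/0/3 pseudogenes, 3 TRGJ,
# 1 TRGC). The nucleotide sequences themselves are synthetic placeholders,
# constructed so that the family structure holds under the package's own
# identity rule: >= 75% identity within a family, < 75% between families,
# and with the two high-identity gene groups (TRGV2.7/2.18 and
# TRGV2.4/2.8/2.14/2.19) sequence-identical so that read assignment is
# genuinely ambiguous for them.
#
# Run from the package root: Rscript data-raw/make_reference.R

suppressPackageStartupMessages({
  library(Biostrings)
  library(tibble)
  library(dplyr)
})

set.seed(20211006L)

V_LEN <- 120L
V_ANCHOR <- 114L              # 0-based offset of the conserved Cys codon (TGT)
J_LEN <- 60L
J_ANCHOR <- 39L               # 0-based offset of the conserved Phe codon (TTT)
C_LEN <- 150L
N_MUT <- 10L                  # per-member substitutions from the family base

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

put <- function(seq, at0, what) {
  # write `what` into seq at 0-based offset at0
  paste0(substr(seq, 1, at0), what, substr(seq, at0 + nchar(what) + 1, nchar(seq)))
}

mutate_seq <- function(seq, n_mut, protect = integer(0)) {
  pos <- setdiff(seq_len(nchar(seq)), protect)
  pos <- sample(pos, n_mut)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# protect the anchor codon and the codon frame near it from mutation
v_protect <- (V_ANCHOR + 1):(V_ANCHOR + 3)

make_family_base <- function() {
  s <- rand_dna(V_LEN)
  put(s, V_ANCHOR, "TGT")
}

plant_stop <- function(seq) {
  # in-frame premature stop to mark a pseudogene; keeps length
  put(seq, 60L, "TAA")
}

rand_rss <- function(n_hept_mut, n_nona_mut) {
  hept <- "CACAGTG"
  nona <- "ACAAAAACC"
  mut <- function(s, k) if (k == 0) s else mutate_seq(s, k)
  paste0(mut(hept, n_hept_mut), rand_dna(23), mut(nona, n_nona_mut))
}

families <- list(
  TRGV1 = list(n = 6, pseudo = c(1, 4), not_detected = 2),
  TRGV2 = list(n = 22, pseudo = c(2, 3, 5, 6, 10, 16, 17, 21), not_detected = 9),
  TRGV3 = list(n = 7, pseudo = integer(0), not_detected = integer(0)),
  TRGV4 = list(n = 5, pseudo = c(1, 3, 5), not_detected = integer(0))
)
identical_groups <- list(TRGV2 = list(c(7, 18), c(4, 8, 14, 19)))

seg <- list()
for (fam in names(families)) {
  info <- families[[fam]]
  base <- make_family_base()
  member_seq <- character(info$n)
  groups <- identical_groups[[fam]]
  done <- logical(info$n)
  if (!is.null(groups)) {
    for (g in groups) {
      s <- mutate_seq(base, N_MUT, protect = v_protect)
      for (i in g) { member_seq[i] <- s; done[i] <- TRUE }
    }
  }
  for (i in seq_len(info$n)) {
    if (!done[i]) member_seq[i] <- mutate_seq(base, N_MUT, protect = v_protect)
  }
  for (i in seq_len(info$n)) {
    is_pseudo <- i %in% info$pseudo
    status <- if (is_pseudo) "pseudogene"
              else if (i %in% info$not_detected) "not_detected_expressed"
              else "functional"
    s <- member_seq[i]
    if (is_pseudo) s <- plant_stop(s)
    note <- NA_character_
    if ((fam == "TRGV1" && i == 4) || (fam == "TRGV2" && i == 10)) {
      note <- "deletion-bearing pseudogene; family assigned from sequence upstream of the deletion only (synthetic placeholder sequence)"
    }
    seg[[paste0(fam, ".", i)]] <- tibble(
      id = paste0(fam, ".", i),
      segment_type = "V",
      family = fam,
      family_index = i,
      functional_status = status,
      anchor_offset = if (is_pseudo) NA_integer_ else V_ANCHOR,
      rss = if (is_pseudo) NA_character_
            else rand_rss(sample(0:1, 1), sample(0:2, 1)),
      sequence = s,
      note = note
    )
  }
}

for (j in 1:3) {
  s <- put(rand_dna(J_LEN), J_ANCHOR, "TTT")
  seg[[paste0("TRGJ", j)]] <- tibble(
    id = paste0("TRGJ", j), segment_type = "J", family = NA_character_,
    family_index = NA_integer_, functional_status = "functional",
    anchor_offset = J_ANCHOR,
    rss = rand_rss(sample(0:1, 1), sample(0:1, 1)),
    sequence = s, note = NA_character_
  )
}
seg[["TRGC"]] <- tibble(
  id = "TRGC", segment_type = "C", family = NA_character_,
  family_index = NA_integer_, functional_status = "functional",
  anchor_offset = NA_integer_, rss = NA_character_,
  sequence = rand_dna(C_LEN), note = NA_character_
)

segments <- bind_rows(seg)

# Locus layout: repeated blocks, each holding one member of TRGV4/1/3 and up
# to four TRGV2 members, laid distal -> proximal; J and C segments at the
# proximal end. Numbering is therefore monotone with position in each family.
block_of <- list()
for (m in 1:7) {
  ids <- c()
  if (m <= 5) ids <- c(ids, paste0("TRGV4.", m))
  if (m <= 6) ids <- c(ids, paste0("TRGV1.", m))
  ids <- c(ids, paste0("TRGV3.", m))
  v2 <- (4 * (m - 1) + 1):(4 * m)
  v2 <- v2[v2 <= 22]
  if (m <= 6) ids <- c(ids, paste0("TRGV2.", v2))
  block_of[[m]] <- ids
}
order_ids <- c(unlist(block_of), "TRGJ1", "TRGJ2", "TRGJ3", "TRGC")
stopifnot(setequal(order_ids, segments$id), !anyDuplicated(order_ids))

gap <- 400L
pos <- 0L
coords <- list()
for (k in seq_along(order_ids)) {
  id <- order_ids[k]
  len <- nchar(segments$sequence[segments$id == id])
  blk <- which(vapply(block_of, function(b) id %in% b, logical(1)))
  coords[[id]] <- tibble(id = id, locus_start = pos, locus_end = pos + len,
                         motif_block = if (length(blk)) paste0("M", blk) else NA_character_)
  pos <- pos + len + gap
}
segments <- segments |>
  left_join(bind_rows(coords), by = "id") |>
  arrange(locus_start)

# ---- sanity checks against the identity rule -------------------------------
identity_pct <- function(a, b) {
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "overlap",
                           substitutionMatrix = nucleotideSubstitutionMatrix(1, -1),
                           gapOpening = 0, gapExtension = 2)
  100 * nmatch(aln) / min(nchar(a), nchar(b))
}
v <- segments |> filter(segment_type == "V")
within_min <- Inf; cross_max <- -Inf
for (i in seq_len(nrow(v) - 1)) {
  for (j in (i + 1):nrow(v)) {
    idn <- identity_pct(v$sequence[i], v$sequence[j])
    if (v$family[i] == v$family[j]) within_min <- min(within_min, idn)
    else cross_max <- max(cross_max, idn)
  }
}
cat(sprintf("within-family min identity: %.1f, cross-family max: %.1f\n",
            within_min, cross_max))
stopifnot(within_min >= 75, cross_max < 75)
stopifnot(sum(v$functional_status == "pseudogene") == 13, nrow(v) == 40)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
fa <- DNAStringSet(setNames(segments$sequence, segments$id))
writeXStringSet(fa, "inst/extdata/trg_synthetic_reference.fasta", width = 80)
readr::write_tsv(segments |> select(-sequence),
                 "inst/extdata/trg_synthetic_reference.tsv")
cat("wrote", nrow(segments), "segments\n")
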