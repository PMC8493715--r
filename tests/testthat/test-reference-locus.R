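test_that("sequence identity follows the shorter-sequence formula", {
  expect_equal(sequence_identity("ACGT", "ACGT"), 100)
  expect_equal(sequence_identity("ACGT", "ACGA"), 75)
  # one overhanging base is an end gap: 4 matches over the shorter length 4
  expect_equal(sequence_identity("AACGT", "ACGT"), 100)
  expect_error(sequence_identity("", "ACGT"), class = "gammarep_invalid_input")
  expect_error(sequence_identity("ACGT", "ACXT"),
               class = "gammarep_invalid_alphabet")
})

test_that("sequence identity is symmetric and capped at 100", {
  set.seed(11)
  for (i in 1:25) {
    a <- rand_seq(sample(10:40, 1))
    b <- rand_seq(sample(10:40, 1))
    ab <- sequence_identity(a, b)
    expect_identical(ab, sequence_identity(b, a))
    expect_lte(ab, 100)
    expect_gte(ab, 0)
  }
  # 100 iff one sequence aligns into the other without mismatch
  inner <- rand_seq(15)
  expect_equal(sequence_identity(paste0("AC", inner, "GG"), inner), 100)
})

test_that("family assignment applies the 75% subgroup rule", {
  ref <- trg_reference()
  v <- ref[ref$segment_type == "V", ]
  exemplars <- split(v$sequence, v$family)
  # an exact family member comes back with its own family
  expect_equal(assign_family(v$sequence[v$id == "TRGV3.3"], exemplars), "TRGV3")
  # a query mutated 20% away from one exemplar stays in that family
  set.seed(21)
  ex <- v$sequence[v$id == "TRGV2.20"]
  ch <- strsplit(ex, "")[[1]]
  pos <- sample(length(ch), round(0.2 * length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  query <- paste(ch, collapse = "")
  expect_gte(sequence_identity(query, ex), 75)
  expect_equal(assign_family(query, exemplars), "TRGV2")
  # far-from-everything query is unassigned
  expect_equal(assign_family(strrep("ACGT", 30), exemplars, threshold = 99),
               "unassigned")
  expect_error(assign_family("ACGT", list()), class = "gammarep_invalid_input")
})

test_that("every packaged V sequence recovers its recorded family", {
  ref <- trg_reference()
  v <- ref[ref$segment_type == "V", ]
  exemplars <- split(v$sequence, v$family)
  got <- vapply(seq_len(nrow(v)),
                function(i) assign_family(v$sequence[i], exemplars),
                character(1))
  expect_identical(got, v$family)
})

test_that("family ties resolve to the lexicographically first family", {
  ex <- list(FB = "ACGTACGTAC", FA = "ACGTACGTAC")
  expect_warning(out <- assign_family("ACGTACGTAC", ex), "tie")
  expect_equal(out, "FA")
})

test_that("segment numbering runs distal to proximal relative to C", {
  seg <- tibble::tibble(
    id = c("TRGV3.9", "TRGV3.8", "TRGV3.7", "TRGC"),
    segment_type = c("V", "V", "V", "C"),
    family = c("TRGV3", "TRGV3", "TRGV3", NA),
    family_index = c(9L, 8L, 7L, NA),
    locus_start = c(10L, 200L, 500L, 10000L),
    locus_end = c(100L, 300L, 600L, 10100L)
  )
  named <- name_segments(seg)
  expect_equal(named$id[1:3], c("TRGV3.1", "TRGV3.2", "TRGV3.3"))
  # C at the other end flips the numbering
  seg2 <- seg
  seg2$locus_start[4] <- 0L; seg2$locus_end[4] <- 5L
  seg2$locus_start[1:3] <- c(100L, 300L, 600L)
  seg2$locus_end[1:3] <- c(200L, 400L, 700L)
  named2 <- name_segments(seg2)
  expect_equal(named2$id[1:3], c("TRGV3.3", "TRGV3.2", "TRGV3.1"))
  # idempotent and single-member families get index 1
  expect_identical(name_segments(named), named)
  single <- seg[c(1, 4), ]
  expect_equal(name_segments(single)$family_index[1], 1L)
  expect_error(name_segments(seg[1:3, ]), class = "gammarep_structure_error")
})

test_that("the packaged locus reproduces the published family table", {
  smry <- locus_summary(trg_reference())
  fam <- smry[smry$family %in% paste0("TRGV", 1:4), ]
  expect_equal(fam$total, c(6L, 22L, 7L, 5L))
  expect_equal(fam$pseudogenes, c(2L, 8L, 0L, 3L))
  allv <- smry[smry$family == "all_V", ]
  expect_equal(allv$total, 40L)
  expect_equal(allv$pseudogenes, 13L)
  expect_equal(smry$total[smry$family == "J"], 3L)
  expect_equal(smry$total[smry$family == "C"], 1L)
})

test_that("grouped V calls use the published composite labels", {
  expect_equal(v_call_group(c("TRGV2.7", "TRGV2.18", "TRGV3.3")),
               c("TRGV2.7/2.18", "TRGV2.7/2.18", "TRGV3.3"))
  expect_equal(v_call_group("TRGV2.14"), "TRGV2.4/2.8/2.14/2.19")
})
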