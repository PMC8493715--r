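test_that("smith_waterman matches direct scoring on canonical cases", {
  expect_equal(smith_waterman("AAA", "AAA")$score, 15L)
  zero <- smith_waterman("AAA", "TTT")
  expect_equal(zero$score, 0L)
  expect_equal(zero$q_end - zero$q_start, 0L)
  expect_error(smith_waterman("", "AAA"), class = "gammarep_invalid_input")
})

test_that("smith_waterman equals a brute-force DP oracle on random pairs", {
  set.seed(41)
  for (i in 1:60) {
    q <- rand_seq(sample(5:30, 1))
    r <- rand_seq(sample(5:30, 1))
    expect_equal(smith_waterman(q, r)$score, bf_sw_score(q, r))
  }
  # spot-check an asymmetric-length pair too
  expect_equal(smith_waterman("GGTTGACTA", "TGTTACGG")$score,
               bf_sw_score("GGTTGACTA", "TGTTACGG"))
})

test_that("segment assignment finds unique hits and groups exact ties", {
  ref <- tiny_reference()
  vrefs <- ref[ref$segment_type == "V", ]
  # read containing an exact substring of VA.1 only
  read <- paste0("GGGG", substr(vrefs$sequence[1], 1, 40), "CCCC")
  out <- assign_segment(read, vrefs, min_score = 60)
  expect_equal(out$call, "VA.1")
  # VA.2 and VA.3 are germline-identical: the call is grouped in locus order
  read2 <- paste0("TT", substr(vrefs$sequence[2], 5, 55), "AA")
  out2 <- assign_segment(read2, vrefs, min_score = 60)
  expect_equal(out2$call, "VA.2/VA.3")
  expect_equal(out2$ids, c("VA.2", "VA.3"))
  # a reverse-complemented read is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out3 <- assign_segment(rc, vrefs, min_score = 60)
  expect_equal(out3$call, "VA.1")
  expect_equal(out3$strand, -1L)
})

test_that("low-scoring reads yield no call with the right flag", {
  ref <- tiny_reference()
  vrefs <- ref[ref$segment_type == "V", ]
  set.seed(43)
  for (i in 1:5) {
    read <- rand_seq(40)
    top <- max(vapply(vrefs$sequence[vrefs$functional_status != "pseudogene"],
                      function(s) bf_sw_score(read, s), numeric(1)))
    out <- assign_segment(read, vrefs, min_score = 100)
    if (top < 100) {
      expect_true(is.na(out$call))
      expect_equal(out$flag, "no_v")
    }
  }
  jrefs <- ref[ref$segment_type == "J", ]
  out <- assign_segment("ACGTACGTACGTACGT", jrefs, min_score = 100)
  expect_equal(out$flag, "no_j")
  expect_error(assign_segment("ACGT", ref), class = "gammarep_config_error")
})

test_that("junction extraction recovers planted junctions exactly", {
  ref <- tiny_reference()
  v <- ref[ref$id == "VA.1", ]
  j <- ref[ref$id == "J1", ]
  # assemble a read: V (full) + insert + J head onward, zero trimming
  insert <- "GGCCAA"
  v_tail <- substr(v$sequence, v$anchor_offset + 1, nchar(v$sequence))
  j_head <- substr(j$sequence, 1, j$anchor_offset + 3)
  junction_truth <- paste0(v_tail, insert, j_head)
  read <- paste0(v$sequence, insert, j$sequence)
  v_aln <- smith_waterman(read, v$sequence)
  j_aln <- smith_waterman(read, j$sequence)
  expect_equal(extract_junction(read, v, j, v_aln, j_aln), junction_truth)
})

test_that("junctions are refused when an anchor is outside the alignment", {
  ref <- tiny_reference()
  v <- ref[ref$id == "VA.1", ]
  j <- ref[ref$id == "J1", ]
  # read stops 10 nt before the V anchor
  read <- paste0(substr(v$sequence, 1, v$anchor_offset - 10), j$sequence)
  v_aln <- smith_waterman(read, v$sequence)
  j_aln <- smith_waterman(read, j$sequence)
  expect_true(is.na(extract_junction(read, v, j, v_aln, j_aln)))
})

test_that("productivity follows frame and stop-codon rules", {
  out <- classify_productive(c("TGTGCCTTT", "TGTGCCTT", "TGTTAATTT", NA))
  expect_equal(out$in_frame, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$has_stop, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$productive, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("error-free synthetic reads are annotated perfectly end to end", {
  cfg <- simulation_config(seed = 17, lines = list(L = 2),
                           tissues = "thymus", reads_per_sample = 250,
                           clones_per_bird = 40, error_rate = 0)
  ref <- trg_reference()
  rep <- simulate_repertoire(cfg, ref)
  rd <- simulate_reads(rep, cfg, ref)
  ann <- annotate_reads(rd[, c("read_id", "sequence")], ref)
  joined <- dplyr::inner_join(
    ann, rd[, c("read_id", "true_v", "true_j", "true_junction")],
    by = c(sequence_id = "read_id"))
  expect_equal(mean(v_call_group(joined$true_v) == joined$v_call), 1)
  expect_equal(mean(joined$true_j == joined$j_call), 1)
  expect_equal(mean(joined$true_junction == joined$junction), 1)
  # summary counts partition the input
  smry <- attr(ann, "summary")
  n <- smry$n_reads[smry$category == "total"]
  expect_equal(sum(smry$n_reads[smry$category != "total"]), n)
})

test_that("reads from germline-identical genes keep the grouped call", {
  ref <- trg_reference()
  v <- ref[ref$id == "TRGV2.7", ]
  j <- ref[ref$id == "TRGJ1", ]
  read <- paste0(v$sequence, "GGG", j$sequence)
  ann <- annotate_reads(tibble::tibble(read_id = "r", sequence = read), ref)
  expect_equal(ann$v_call, "TRGV2.7/2.18")
  expect_match(ann$flags, "ambiguous_v_retained")
})

test_that("all-N reads produce no V call", {
  ref <- trg_reference()
  ann <- annotate_reads(tibble::tibble(read_id = c("n1", "n2"),
                                       sequence = strrep("N", 150)), ref)
  expect_true(all(is.na(ann$v_call)))
  expect_true(all(grepl("no_v", ann$flags)))
})

test_that("the k-mer prescreen does not change calls", {
  cfg <- simulation_config(seed = 23, lines = list(L = 1),
                           tissues = "spleen", reads_per_sample = 120,
                           clones_per_bird = 30, error_rate = 0.01)
  ref <- trg_reference()
  rep <- simulate_repertoire(cfg, ref)
  rd <- simulate_reads(rep, cfg, ref)
  full <- annotate_reads(rd[, c("read_id", "sequence")], ref, kmer = 0)
  pre <- annotate_reads(rd[, c("read_id", "sequence")], ref, kmer = 12)
  expect_identical(full$v_call, pre$v_call)
  expect_identical(full$j_call, pre$j_call)
  expect_identical(full$junction, pre$junction)
})

test_that("junction recovery stays high at 1% substitution error", {
  # recovery = the extracted junction equals the read's true junction
  # interval (errors inside the junction change its bases, not its location)
  ref <- trg_reference()
  rates <- vapply(1:3, function(s) {
    cfg <- simulation_config(seed = 100 + s, lines = list(L = 1),
                             tissues = "thymus", reads_per_sample = 400,
                             clones_per_bird = 40, error_rate = 0.01)
    rep <- simulate_repertoire(cfg, ref)
    rd <- simulate_reads(rep, cfg, ref)
    ann <- annotate_reads(rd[, c("read_id", "sequence")], ref)
    joined <- dplyr::inner_join(
      ann, rd[, c("read_id", "sequence", "junction_start", "junction_end")],
      by = c(sequence_id = "read_id"))
    truth_region <- substr(joined$sequence, joined$junction_start + 1,
                           joined$junction_end)
    mean(!is.na(joined$junction) & joined$junction == truth_region)
  }, numeric(1))
  expect_gte(mean(rates), 0.95)
})
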