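# a small clonotype table with known penetrance structure over 8 birds
publicity_fixture <- function() {
  birds <- paste0("b", 1:8)
  rows <- list(
    tibble::tibble(bird_id = birds, v_group = "Va", junction_nt = "AAA",
                   read_count = 10L),                        # 8/8 -> p100
    tibble::tibble(bird_id = birds[1:7], v_group = "Va", junction_nt = "CCC",
                   read_count = 5L),                         # 7/8 -> p80
    tibble::tibble(bird_id = birds[1:5], v_group = "Vb", junction_nt = "GGG",
                   read_count = 4L),                         # 5/8 -> p60
    tibble::tibble(bird_id = birds[1:4], v_group = "Vb", junction_nt = "TTT",
                   read_count = 2L),                         # 4/8 -> private
    tibble::tibble(bird_id = birds[1], v_group = "Vb", junction_nt = "ATA",
                   read_count = 1L)                          # 1/8 -> private
  )
  dplyr::bind_rows(rows) |>
    dplyr::mutate(line = "L", tissue = "spleen") |>
    dplyr::select(line, bird_id, tissue, v_group, junction_nt, read_count)
}

test_that("penetrance bins follow the half-open thresholds", {
  rec <- compute_publicity(publicity_fixture())
  bin_of <- function(j) rec$bin[rec$junction_nt == j]
  expect_equal(bin_of("AAA"), "p100")
  expect_equal(bin_of("CCC"), "p80")    # 7/8 = 0.875
  expect_equal(bin_of("GGG"), "p60")    # 5/8 = 0.625
  expect_equal(bin_of("TTT"), "private") # 4/8 = 0.5
  expect_equal(nrow(rec), 5L)            # each clonotype exactly once
  expect_error(compute_publicity(publicity_fixture()[1, ]),
               class = "gammarep_invalid_input")
})

test_that("publicity bins planted by the simulator are recovered exactly", {
  ref <- trg_reference()
  pool <- list(
    list(v_id = "TRGV2.20", penetrance = 1.0, expansion_factor = 5),
    list(v_id = "TRGV1.3", penetrance = 0.8, expansion_factor = 5),
    list(v_id = "TRGV3.1", penetrance = 0.5, expansion_factor = 5)
  )
  cfg <- simulation_config(seed = 81, lines = list(L = 8), tissues = "spleen",
                           reads_per_sample = 3000, clones_per_bird = 60,
                           public_pool = pool, error_rate = 0)
  rep <- simulate_repertoire(cfg, ref)
  rec <- compute_publicity(rep$clonotypes)
  planted <- rep$clones |> dplyr::filter(is_public)
  bins <- rec$bin[match(planted$junction_nt, rec$junction_nt)]
  # ceiling(0.8 * 8) = 7 of 8 birds -> p80; 0.5 -> 4/8 -> private
  expect_equal(bins, c("p100", "p80", "private"))
})

test_that("bin shares per V are read-weighted and sum to one", {
  shares <- public_fraction_by_v(compute_publicity(publicity_fixture()))
  tot <- shares |>
    dplyr::group_by(v_group) |>
    dplyr::summarise(s = sum(share))
  expect_true(all(abs(tot$s - 1) < 1e-9))
  # Va: 80 reads p100, 35 reads p80
  va <- shares[shares$v_group == "Va", ]
  expect_equal(va$share[va$bin == "p100"], 80 / 115)
  expect_equal(va$share[va$bin == "private"], 0)
})

test_that("cross-line sharing honours the level-or-higher rule", {
  rec <- compute_publicity(publicity_fixture())
  # identical repertoires share fully at every level in both modes
  for (mode in c("weighted", "unweighted")) {
    sh <- cross_line_sharing(rec, rec, mode = mode)
    expect_true(all(sh$shared_prop[!is.na(sh$shared_prop)] == 1))
  }
  # disjoint repertoires share nothing
  other <- rec |> dplyr::mutate(junction_nt = paste0(junction_nt, "X"))
  sh0 <- cross_line_sharing(rec, other)
  expect_true(all(sh0$shared_prop[!is.na(sh0$shared_prop)] == 0))
  # p80 in A counts as shared when the clone is p100 in B
  a <- tibble::tibble(v_group = "Va", junction_nt = "AAA",
                      n_birds_present = 7L, read_count = 10L,
                      penetrance = 7 / 8, bin = "p80")
  b <- a |> dplyr::mutate(bin = "p100", penetrance = 1)
  sh <- cross_line_sharing(a, b)
  expect_equal(sh$shared_prop[sh$level == "p80" & sh$line == "a"], 1)
})

test_that("down-sampling birds is reproducible and cannot promote a clone", {
  tab <- publicity_fixture()
  d1 <- downsample_birds(tab, "L", 5, seed = 9)
  d2 <- downsample_birds(tab, "L", 5, seed = 9)
  expect_identical(d1, d2)
  expect_equal(dplyr::n_distinct(d1$bird_id), 5L)
  expect_identical(downsample_birds(tab, "L", 8, seed = 1) |> dplyr::arrange(bird_id, junction_nt),
                   tab |> dplyr::arrange(bird_id, junction_nt))
  expect_error(downsample_birds(tab, "L", 9), class = "gammarep_invalid_input")
  # clones present in every bird stay fully public after any down-sample,
  # and no bin can exceed p100
  rec5 <- compute_publicity(d1)
  expect_equal(rec5$bin[rec5$junction_nt == "AAA"], "p100")
  expect_true(all(rec5$penetrance <= 1))
})

test_that("between-line comparison reports shares and a rank test", {
  set.seed(85)
  recA <- compute_publicity(publicity_fixture())
  tabB <- publicity_fixture() |>
    dplyr::mutate(read_count = pmax(1L, read_count - 2L))
  recB <- compute_publicity(tabB)
  out <- publicity_line_test(recA, recB)
  expect_s3_class(out$by_v, "tbl_df")
  expect_true(all(c("mean_share", "sd_share") %in% names(out$summary)))
  expect_s3_class(out$test, "htest")
})
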