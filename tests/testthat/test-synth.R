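# The seeded simulator: determinism, bookkeeping, noiseless exactness,
# and digestion-sample generation.

test_that("the same config and seed reproduce the run exactly", {
  cfg <- simulation_config(fractions = c(`K27me3-K36me2` = 0.75,
                                         `K27me2-K36me3` = 0.25), seed = 7)
  s1 <- simulate_run(cfg)
  s2 <- simulate_run(cfg)
  expect_identical(s1$run, s2$run)
  expect_identical(s1$truth$expected_percentages, s2$truth$expected_percentages)
  # and a different seed changes the realization
  s3 <- simulate_run(simulation_config(
    fractions = c(`K27me3-K36me2` = 0.75, `K27me2-K36me3` = 0.25), seed = 8))
  expect_false(identical(s1$run, s3$run))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- stats::runif(1)
  set.seed(123)
  invisible(simulate_run(simulation_config(seed = 5)))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("invalid mixing fractions are rejected", {
  expect_error(simulation_config(fractions = c(`K27me3-K36me2` = 0.7,
                                               `K27me2-K36me3` = 0.7)),
               "sum to 1")
  expect_error(simulation_config(fractions = c(bad_name = 1, other = 0)),
               "isoform ids")
})

test_that("a pure mixture without noise writes no ions of the other isoform", {
  cfg <- noiseless_config(c(`K27me3-K36me2` = 1, `K27me2-K36me3` = 0))
  sim <- simulate_run(cfg)
  b_specific <- specific_ions(cfg$group, series = c("b", "y"), charges = 1:2)
  b_mz <- b_specific$mz[b_specific$isoform_id == "K27me2-K36me3"]
  ms2 <- sim$run[sim$run$ms_level == 2, ]
  hits <- purrr::map_int(ms2$peaks, function(pk) {
    sum(vapply(b_mz, function(t) any(abs(ppm_error(pk$mz, t)) < 1), logical(1)))
  })
  expect_identical(sum(hits), 0L)
})

test_that("ground-truth bookkeeping matches the written scans exactly", {
  cfg <- noiseless_config(c(`K27me3-K36me2` = 0.6, `K27me2-K36me3` = 0.4))
  sim <- simulate_run(cfg)
  spec <- specific_ions(cfg$group, series = "y", charges = 2)
  ms2 <- sim$run[sim$run$ms_level == 2, ]
  recounted <- purrr::map(seq_len(nrow(ms2)), function(i) {
    pk <- ms2$peaks[[i]]
    purrr::map_dbl(split(spec$mz, spec$isoform_id), function(mzs) {
      sum(purrr::map_dbl(mzs, function(t) {
        j <- which(abs(pk$mz - t) < 1e-9)
        if (length(j)) pk$intensity[j] else 0
      }))
    })
  })
  recount_total <- Reduce(`+`, recounted)
  expect_equal(recount_total[names(sim$truth$specific_y2_totals)],
               sim$truth$specific_y2_totals, tolerance = 1e-9)
  # per-isoform totals also equal the per-scan table's sums
  per_scan_sums <- tapply(sim$truth$per_scan$intensity,
                          sim$truth$per_scan$isoform_id, sum)
  expect_equal(as.numeric(per_scan_sums[names(sim$truth$specific_y2_totals)]),
               as.numeric(sim$truth$specific_y2_totals))
})

test_that("noiseless recovery is exact to 0.1 percentage point", {
  for (fa in c(1, 6 / 7, 0.5, 0.25)) {
    cfg <- noiseless_config(c(`K27me3-K36me2` = fa, `K27me2-K36me3` = 1 - fa))
    sim <- simulate_run(cfg)
    q <- simc_quantify(sim$run, cfg$group)
    got <- q$percentages$percentage[q$percentages$isoform_id == "K27me3-K36me2"]
    expect_equal(got, 100 * fa, tolerance = 0.1 / 100)
  }
})

test_that("MS1 bookkeeping lets SIC recover injected areas within 1%", {
  cfg <- noiseless_config(c(`K27me3-K36me2` = 0.5, `K27me2-K36me3` = 0.5))
  sim <- simulate_run(cfg)
  s <- sic(sim$run, cfg$group$isoforms[[1]], charges = 1:4)
  expect_equal(s$total, sim$truth$ms1_total_area, tolerance = 0.01)
  merged <- dplyr::left_join(s$per_charge, sim$truth$ms1_areas,
                             by = "charge", suffix = c("", "_truth"))
  expect_equal(merged$area, merged$area_truth, tolerance = 0.01)
})

test_that("y2+ ions dominate the written fragment spectra", {
  cfg <- noiseless_config(c(`K27me3-K36me2` = 0.5, `K27me2-K36me3` = 0.5))
  sim <- simulate_run(cfg)
  grp <- cfg$group
  frag_a <- fragment_ions(grp$isoforms[[1]], max_charge = 2)
  apex_scan <- sim$run |>
    dplyr::filter(ms_level == 2) |>
    dplyr::slice(which.min(abs(rt - cfg$rt_center)))
  pk <- apex_scan$peaks[[1]]
  int_of <- function(series_, charge_) {
    mzs <- frag_a$mz[frag_a$series == series_ & frag_a$charge == charge_]
    sum(purrr::map_dbl(mzs, function(t) {
      j <- which(abs(pk$mz - t) < 1e-6)
      if (length(j)) pk$intensity[j] else 0
    }))
  }
  expect_gt(int_of("y", 2), 5 * int_of("y", 1))
  expect_gt(int_of("y", 2), 5 * int_of("b", 2))
})

test_that("digestion sampling recovers mixing, with closed-form skew shift", {
  long <- list(
    `K27me3-K36me2` = peptide("LATKAARKSAPATGGVKKPHRYRPGTVALREIR", 20,
                              c("27:methyl:3", "36:methyl:2")),
    `K27me2-K36me3` = peptide("LATKAARKSAPATGGVKKPHRYRPGTVALREIR", 20,
                              c("27:methyl:2", "36:methyl:3")))
  fr <- c(`K27me3-K36me2` = 0.5, `K27me2-K36me3` = 0.5)
  cfg <- noiseless_config(fr)
  sim <- simulate_digest_sample(long, fr, cfg)
  # products are the K27-R40 pair
  expect_equal(sim$truth$fractions,
               c(`K27me3-K36me2` = 0.5, `K27me2-K36me3` = 0.5))
  q <- simc_quantify(sim$run, h3_pair())
  expect_equal(sort(q$percentages$percentage), c(50, 50), tolerance = 1e-3)

  # a 0.95 digestion-efficiency skew moves the balance to 0.95/1.95
  simk <- simulate_digest_sample(long, fr, cfg,
                                 digestion_skew = c(`K27me3-K36me2` = 0.95,
                                                    `K27me2-K36me3` = 1))
  qk <- simc_quantify(simk$run, h3_pair())
  got <- qk$percentages$percentage[qk$percentages$isoform_id == "K27me3-K36me2"]
  expect_equal(got, 100 * 0.95 / 1.95, tolerance = 1e-3)
})

test_that("digestion yields the quantifiable product only when K27 blocks trypsin", {
  p_me3 <- peptide("LATKAARKSAPATGGVKKPHRYRPGTVALREIR", 20,
                   c("27:methyl:3", "36:methyl:2"))
  d <- digest(p_me3)
  expect_true(any(d$start == 27 & d$end == 40))
  p_me1 <- peptide("LATKAARKSAPATGGVKKPHRYRPGTVALREIR", 20,
                   c("27:methyl:1", "36:methyl:2"))
  d1 <- digest(p_me1)
  expect_false(any(d1$start == 27 & d1$end == 40))
})
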