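# SIMC core on hand-assembled spectra, plus SIC, relative abundance and
# replicate summaries.

grp <- h3_pair()
y2 <- specific_ions(grp, series = "y", charges = 2)
y13a <- y2$mz[y2$isoform_id == "K27me3-K36me2" & y2$index == 13]
y13b <- y2$mz[y2$isoform_id == "K27me2-K36me3" & y2$index == 13]
y11a <- y2$mz[y2$isoform_id == "K27me3-K36me2" & y2$index == 11]

test_that("match_ions picks the smallest |mass error| with no intensity gate", {
  pk <- tibble::tibble(mz = c(667.3890, 667.3950), intensity = c(1e5, 5e4))
  m <- match_ions(pk, tibble::tibble(mz = 667.3886), tol = 10, tol_mode = "ppm")
  expect_equal(nrow(m), 1L)
  expect_equal(m$observed_mz, 667.3890)  # +0.60 ppm beats +9.6 ppm
  expect_equal(m$mass_error, 0.60, tolerance = 0.01)

  # weaker but closer peak still wins (no signal-to-noise threshold)
  pk2 <- tibble::tibble(mz = c(667.3890, 667.3930), intensity = c(10, 1e8))
  m2 <- match_ions(pk2, tibble::tibble(mz = 667.3886))
  expect_equal(m2$observed_mz, 667.3890)

  # nothing within 0.4 Da -> no match
  m3 <- match_ions(tibble::tibble(mz = 300, intensity = 1),
                   tibble::tibble(mz = 667.3886), tol = 0.4, tol_mode = "Da")
  expect_equal(nrow(m3), 0L)

  # exact |error| tie -> higher intensity
  m4 <- match_ions(
    tibble::tibble(mz = c(667.3880, 667.3900), intensity = c(5, 9)),
    tibble::tibble(mz = 667.3890), tol = 0.4, tol_mode = "Da")
  expect_equal(m4$observed_mz, 667.3900)
})

test_that("simc equals a hand-computed tally on a tiny run", {
  # three scans, intensities chosen for a closed-form trapezoid
  runs <- tiny_run(
    list(
      list(mz = sort(c(y13a, y13b)), intensity = c(100, 300)[order(c(y13a, y13b))]),
      list(mz = sort(c(y13a, y13b)), intensity = c(200, 200)[order(c(y13a, y13b))]),
      list(mz = y13a, intensity = 100)
    ),
    rts = c(10, 11, 12)
  )
  expect_warning(q <- simc_quantify(runs, grp), "fewer than 6")
  # hand trapezoid over rt 10,11,12: A = .5(100+200)+.5(200+100) = 300
  #                                  B = .5(300+200)+.5(200+0)  = 350
  areas <- tibble::deframe(q$percentages[, c("isoform_id", "area")])
  expect_equal(areas[["K27me3-K36me2"]], 300)
  expect_equal(areas[["K27me2-K36me3"]], 350)
  expect_equal(q$percentages$percentage[q$percentages$isoform_id == "K27me3-K36me2"],
               300 / 650 * 100, tolerance = 1e-9)
  expect_equal(sum(q$percentages$percentage), 100, tolerance = 1e-9)
  # the per-scan tally mode
  expect_warning(qs <- simc_quantify(runs, grp, integration = "sum"))
  areas_s <- tibble::deframe(qs$percentages[, c("isoform_id", "area")])
  expect_equal(areas_s[["K27me3-K36me2"]], 400)
  expect_equal(areas_s[["K27me2-K36me3"]], 500)
  # ledger mirrors the matched ions
  expect_equal(nrow(q$ledger), 5L)
  expect_named(q$ledger, c("isoform_id", "series", "index", "charge",
                           "scan_id", "rt", "theoretical_mz", "observed_mz",
                           "intensity", "mass_error"))
})

test_that("pure and symmetric mixtures give 100:0 and 50:50", {
  pure <- tiny_run(lapply(1:6, function(i) list(mz = y13a, intensity = 50 * i)))
  qp <- simc_quantify(pure, grp)
  expect_equal(sort(qp$percentages$percentage), c(0, 100))
  expect_equal(
    qp$percentages$percentage[qp$percentages$isoform_id == "K27me3-K36me2"], 100)

  both <- tiny_run(lapply(1:6, function(i) {
    list(mz = sort(c(y13a, y13b)), intensity = c(70, 70))
  }))
  qb <- simc_quantify(both, grp)
  expect_equal(qb$percentages$percentage, c(50, 50))
})

test_that("zero observed intensity flags undefined percentages, not 0/0", {
  blank <- tiny_run(lapply(1:6, function(i) list(mz = 400.123, intensity = 5)))
  expect_warning(q <- simc_quantify(blank, grp), "undefined")
  expect_true(q$undefined)
  expect_true(all(is.na(q$percentages$percentage)))
  expect_identical(nrow(q$ledger), 0L)
})

test_that("few contributing scans trigger the stability warning", {
  r <- tiny_run(list(list(mz = y13a, intensity = 10),
                     list(mz = y13a, intensity = 10)))
  expect_warning(simc_quantify(r, grp), "fewer than 6")
})

test_that("tidy, glance, ledger export and autoplot expose the result", {
  r <- tiny_run(lapply(1:6, function(i) {
    list(mz = sort(c(y13a, y11a)), intensity = c(10, 20))
  }))
  q <- simc_quantify(r, grp)
  td <- tidy(q)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("isoform_id", "area", "percentage"))
  gl <- glance(q)
  expect_equal(gl$n_ms2, 6L)
  expect_equal(gl$n_matched_ions, 12L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(q, path)
  led <- utils::read.csv(path)
  expect_named(led, c("isoform", "ion", "scan", "rt_min", "intensity",
                      "mz", "mass_error"))
  expect_true(all(grepl("^y\\d+\\^2\\+$", led$ion)))
  expect_s3_class(ggplot2::autoplot(q), "ggplot")
})

test_that("sic extracts per-charge areas and sums them", {
  p <- grp$isoforms[[1]]
  mz3 <- precursor_mz(p, 3)
  run <- tiny_run(
    list(list(mz = y13a, intensity = 1)),
    rts = 2.5,
    ms1_peaks = lapply(c(10, 40, 10), function(h) list(mz = mz3, intensity = h)),
    ms1_rts = c(1, 2, 3)
  )
  expect_warning(s <- sic(run, p, charges = 1:4), "fewer than 22")
  # trapezoid over (1,2,3) x (10,40,10): 0.5*50 + 0.5*50 = 50
  expect_equal(s$per_charge$area[s$per_charge$charge == 3], 50)
  expect_equal(s$per_charge$area[s$per_charge$charge != 3], rep(0, 3))
  expect_equal(s$total, 50)
  expect_equal(s$total, sum(s$per_charge$area))  # total = sum over charges

  # linearity: doubling all MS1 intensities doubles the total
  run2 <- run
  run2$peaks <- purrr::map2(run2$peaks, run2$ms_level, function(pk, lvl) {
    if (lvl == 1) dplyr::mutate(pk, intensity = intensity * 2) else pk
  })
  run2 <- ms_run(run2)
  expect_warning(s2 <- sic(run2, p, charges = 1:4))
  expect_equal(s2$total, 2 * s$total)

  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(glance(s)$total_area, 50)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")

  ms2_only <- tiny_run(list(list(mz = y13a, intensity = 1)))
  expect_error(sic(ms2_only, p), "no MS1")
})

test_that("relative abundance is the SIC-scaled percentage split", {
  r <- tiny_run(lapply(1:6, function(i) {
    list(mz = sort(c(y13a, y13b)), intensity = c(85, 15)[order(c(y13a, y13b))])
  }))
  q <- simc_quantify(r, grp)
  fake_sic <- function(total) structure(list(total = total), class = "simc_sic")
  ab <- relative_abundance(q, fake_sic(10), fake_sic(100))
  expect_equal(sort(ab$abundance), c(0.015, 0.085), tolerance = 1e-9)
  # scaling the normalizer by c divides all abundances by c
  ab2 <- relative_abundance(q, fake_sic(10), fake_sic(300))
  expect_equal(ab2$abundance * 3, ab$abundance, tolerance = 1e-12)
  expect_error(relative_abundance(q, fake_sic(10), fake_sic(0)), "zero")
})

test_that("replicate summaries use the sample standard deviation", {
  mk_quant <- function(pcts) {
    structure(list(
      percentages = tibble::tibble(isoform_id = names(pcts),
                                   area = unname(pcts),
                                   percentage = unname(pcts))),
      class = "simc_quant")
  }
  reps <- lapply(c(40, 50, 60), function(x) {
    mk_quant(c(A = x, B = 100 - x))
  })
  s <- replicate_summary(reps)
  expect_equal(s$mean[s$isoform_id == "A"], 50)
  expect_equal(s$sd[s$isoform_id == "A"], 10)    # sample SD of {40,50,60}
  same <- replicate_summary(list(reps[[2]], reps[[2]]))
  expect_equal(same$sd, c(0, 0))
  expect_error(replicate_summary(reps[1]), ">= 2")
  expect_error(replicate_summary(list(reps[[1]], mk_quant(c(A = 1, C = 99)))),
               "different isoform sets")
})
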