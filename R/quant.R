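# The quantification core: match isoform-specific fragment ions in MS/MS
# scans, accumulate per-isoform chromatograms (SIMC), compute constituent
# percentages; MS1 selected-ion chromatograms (SIC) and normalized relative
# abundance.

# trapezoidal area of a trace; "sum" is the per-scan tally alternative
.trace_area <- function(rt, intensity, integration = "trapezoid") {
  if (integration == "sum" || length(rt) < 2) return(sum(intensity))
  pracma::trapz(rt, intensity)
}

#' Match theoretical fragment ions against one spectrum
#'
#' For every target ion, peaks within the mass tolerance are candidates and
#' the one with the smallest absolute mass error is selected — deliberately
#' with no signal-to-noise threshold. Ties on |error| go to the
#' higher-intensity peak. Targets with no candidate peak are absent from the
#' output.
#'
#' @param peaks A data frame with `mz` and `intensity` (one scan's peak list).
#' @param targets A data frame of theoretical ions with at least an `mz`
#'   column (e.g. from [fragment_ions()] or [specific_ions()]); all its
#'   columns are carried through.
#' @param tol Tolerance value: ppm for `tol_mode = "ppm"` (high-resolution
#'   data, default 10), Da for `tol_mode = "Da"` (ion-trap data, e.g. 0.4).
#' @param tol_mode `"ppm"` or `"Da"`.
#' @return A tibble: the matched targets plus `observed_mz`, `intensity`,
#'   `mass_error` (signed, in the tolerance's unit).
#' @examples
#' pk <- tibble::tibble(mz = c(667.3890, 667.3950), intensity = c(1e5, 5e4))
#' match_ions(pk, tibble::tibble(mz = 667.3886))
#' @export
match_ions <- function(peaks, targets, tol = 10, tol_mode = c("ppm", "Da")) {
  tol_mode <- match.arg(tol_mode)
  if (tol <= 0) abort("tolerance must be > 0")
  peaks <- as_tibble(peaks)
  targets <- as_tibble(targets)
  if (!nrow(peaks) || !nrow(targets)) {
    return(mutate(targets[0, ], observed_mz = numeric(0),
                  intensity = numeric(0), mass_error = numeric(0)))
  }
  hits <- map(seq_len(nrow(targets)), function(i) {
    th <- targets$mz[i]
    err <- if (tol_mode == "ppm") ppm_error(peaks$mz, th) else peaks$mz - th
    in_win <- which(abs(err) <= tol)
    if (!length(in_win)) return(NULL)
    # smallest |mass error|; ties broken toward the stronger peak
    ord <- in_win[order(abs(err[in_win]), -peaks$intensity[in_win])]
    best <- ord[1]
    mutate(targets[i, ], observed_mz = peaks$mz[best],
           intensity = peaks$intensity[best], mass_error = err[best])
  })
  list_rbind(keep(hits, Negate(is.null)))
}

#' Quantify isobaric isoforms by specific-ion chromatograms (SIMC)
#'
#' The core method. MS2 scans acquired on the group's shared precursor are
#' selected; in each scan the intensities of every matched isoform-specific
#' ion (by default the y2+ series, the dominant fragments of a 3+ precursor)
#' are summed per isoform, giving one chromatogram point per scan. Each
#' isoform's cumulative signal is the peak area of its chromatogram over
#' retention time, and constituent percentages are the areas normalized to
#' 100. All matching MS2 scans across the run contribute — the whole elution
#' profile, with no RT gating and no signal-to-noise threshold.
#'
#' @param run A [ms_run()].
#' @param group An [isobaric_group()].
#' @param precursor_charge Precursor charge state targeted (default 3).
#' @param iso_window Full isolation-window width in Th (default 2.0).
#' @param series Fragment series used for quantification (default `"y"`).
#' @param fragment_charges Fragment charges used (default 2).
#' @param tol,tol_mode Mass tolerance for ion matching (default 10 ppm; use
#'   `tol = 0.4, tol_mode = "Da"` for ion-trap MS/MS).
#' @param integration `"trapezoid"` (peak area over RT, default) or `"sum"`
#'   (plain per-scan tally).
#' @param include_unknown_charge Passed to [select_ms2()].
#' @param min_scans Emit a warning when fewer contributing MS2 scans than
#'   this are found (default 6; stable quantification wants more than six
#'   spectra along the elution profile).
#' @return An object of class `simc_quant`: see [tidy.simc_quant()],
#'   [glance.simc_quant()], [autoplot.simc_quant()]. Fields: `percentages`
#'   (tibble: `isoform_id`, `area`, `percentage`), `traces` (per-scan
#'   summed specific-ion intensity per isoform), `ledger` (every matched ion:
#'   isoform, series/index/charge, scan, RT, m/z, intensity, mass error),
#'   `n_ms2`, `undefined` (TRUE when no specific-ion intensity was observed
#'   at all, in which case percentages are `NA`), `warnings`.
#' @export
simc_quantify <- function(run, group, precursor_charge = 3L, iso_window = 2,
                          series = "y", fragment_charges = 2L,
                          tol = 10, tol_mode = c("ppm", "Da"),
                          integration = c("trapezoid", "sum"),
                          include_unknown_charge = FALSE, min_scans = 6L) {
  tol_mode <- match.arg(tol_mode)
  integration <- match.arg(integration)
  stopifnot(inherits(run, "simc_run"), inherits(group, "simc_isobaric_group"))

  targets <- specific_ions(group, series = series, charges = fragment_charges)
  if (!nrow(targets)) {
    abort("no specific ions for the requested series/charges; isoforms are indistinguishable there")
  }
  ids <- names(group$isoforms)
  target_mz <- group_precursor_mz(group, precursor_charge)
  ms2 <- select_ms2(run, target_mz, precursor_charge, iso_window,
                    include_unknown_charge)

  warnings <- character()
  if (nrow(ms2) < min_scans) {
    msg <- sprintf("only %d contributing MS/MS scan(s) (fewer than %d); quantification may be unstable",
                   nrow(ms2), min_scans)
    warnings <- c(warnings, msg)
    warn(msg)
  }

  ledger <- map(seq_len(nrow(ms2)), function(i) {
    m <- match_ions(ms2$peaks[[i]], targets, tol = tol, tol_mode = tol_mode)
    if (!nrow(m)) return(NULL)
    mutate(m, scan_id = ms2$scan_id[i], rt = ms2$rt[i])
  }) |> keep(Negate(is.null)) |> list_rbind()
  if (!nrow(ledger)) {
    ledger <- tibble(isoform_id = character(), series = character(),
                     index = integer(), charge = integer(), neutral = numeric(),
                     mz = numeric(), observed_mz = numeric(),
                     intensity = numeric(), mass_error = numeric(),
                     scan_id = character(), rt = numeric())
  }

  # one trace point per selected scan per isoform; unmatched scans are zero
  grid <- tidyr::crossing(
    tibble(scan_id = ms2$scan_id, rt = ms2$rt),
    isoform_id = ids
  )
  traces <- ledger |>
    group_by(.data$isoform_id, .data$scan_id) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    right_join2(grid) |>
    mutate(intensity = ifelse(is.na(.data$intensity), 0, .data$intensity)) |>
    arrange(.data$isoform_id, .data$rt)

  areas <- traces |>
    group_by(.data$isoform_id) |>
    summarise(area = .trace_area(.data$rt, .data$intensity, integration),
              total_intensity = sum(.data$intensity), .groups = "drop")
  # a single-scan trace has zero trapezoid area; fall back to the tally so
  # observed signal never reads as "no signal"
  if (sum(areas$area) <= 0 && sum(areas$total_intensity) > 0) {
    areas$area <- areas$total_intensity
    warnings <- c(warnings,
                  "trace too short for peak-area integration; used per-scan sum")
  }

  undefined <- sum(areas$area) <= 0
  if (undefined) {
    msg <- "no specific-ion intensity observed; percentages undefined"
    warnings <- c(warnings, msg)
    warn(msg)
    areas$percentage <- NA_real_
  } else {
    areas$percentage <- areas$area / sum(areas$area) * 100
  }

  structure(
    list(
      percentages = select(areas, "isoform_id", "area", "percentage"),
      traces = traces,
      ledger = if (nrow(ledger)) {
        select(ledger, "isoform_id", "series", "index", "charge",
               "scan_id", "rt", theoretical_mz = "mz", "observed_mz",
               "intensity", "mass_error")
      } else {
        tibble(isoform_id = character(), series = character(), index = integer(),
               charge = integer(), scan_id = character(), rt = numeric(),
               theoretical_mz = numeric(), observed_mz = numeric(),
               intensity = numeric(), mass_error = numeric())
      },
      n_ms2 = nrow(ms2), undefined = undefined,
      settings = list(precursor_charge = precursor_charge,
                      iso_window = iso_window, series = series,
                      fragment_charges = fragment_charges, tol = tol,
                      tol_mode = tol_mode, integration = integration),
      warnings = warnings
    ),
    class = "simc_quant"
  )
}

# right_join with a quiet by-clause (both frames share isoform_id/scan_id/rt
# semantics; rt lives only in the grid)
right_join2 <- function(x, grid) {
  dplyr::right_join(x, grid, by = c("isoform_id", "scan_id"))
}

#' @export
print.simc_quant <- function(x, ...) {
  cat(sprintf("<simc_quant> %d MS/MS scans, %d matched ions\n",
              x$n_ms2, nrow(x$ledger)))
  if (x$undefined) {
    cat("  percentages undefined (no specific-ion intensity observed)\n")
  } else {
    for (i in seq_len(nrow(x$percentages))) {
      cat(sprintf("  %-24s %6.2f %%\n", x$percentages$isoform_id[i],
                  x$percentages$percentage[i]))
    }
  }
  invisible(x)
}

#' @rdname simc_quantify
#' @param x A `simc_quant` object.
#' @param ... Unused.
#' @method tidy simc_quant
#' @export
tidy.simc_quant <- function(x, ...) {
  x$percentages
}

#' @rdname simc_quantify
#' @method glance simc_quant
#' @export
glance.simc_quant <- function(x, ...) {
  tibble(n_ms2 = x$n_ms2, n_matched_ions = nrow(x$ledger),
         total_area = sum(x$percentages$area), undefined = x$undefined,
         n_warnings = length(x$warnings))
}

#' Write the matched-ion ledger as CSV
#'
#' One row per selected ion: matched isoform (type of isobaric modification),
#' MS/MS scan number, retention time, intensity, m/z value and mass error.
#'
#' @param x A `simc_quant` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(x, path) {
  stopifnot(inherits(x, "simc_quant"))
  led <- x$ledger |>
    mutate(ion = paste0(.data$series, .data$index,
                        ifelse(.data$charge > 1, paste0("^", .data$charge, "+"), "+"))) |>
    select(isoform = "isoform_id", "ion", scan = "scan_id", rt_min = "rt",
           "intensity", mz = "observed_mz", "mass_error")
  write.csv(led, path, row.names = FALSE)
  invisible(path)
}

#' Selected-ion chromatogram (SIC) quantification at MS1
#'
#' For each charge state, an extracted trace of the best-matching (smallest
#' mass error) MS1 peak within tolerance of the peptide's precursor m/z is
#' built across all MS1 scans; its peak area over RT is the per-charge SIC
#' value and the total is the sum over charge states (1-4+ for the
#' pentamethylated K27-R40 peptide, 1-2+ for the constitutive D123-R128
#' normalization peptide).
#'
#' @param run A [ms_run()] containing MS1 scans.
#' @param p A [peptide()].
#' @param charges Charge states to extract (default 1:4).
#' @param tol,tol_mode Mass tolerance (default 10 ppm).
#' @param mode `"best"` (single smallest-error peak per scan, default) or
#'   `"sum"` (sum of all in-window peaks per scan).
#' @param integration `"trapezoid"` or `"sum"` as in [simc_quantify()].
#' @param min_scans Warn when fewer MS1 points than this trace the peptide
#'   (default 22, the scan count that gives a stable chromatogram outline).
#' @return An object of class `simc_sic` with `per_charge` (tibble: `charge`,
#'   `mz`, `area`, `n_points`), `traces`, and `total` (sum of areas).
#' @export
sic <- function(run, p, charges = 1:4, tol = 10, tol_mode = c("ppm", "Da"),
                mode = c("best", "sum"), integration = c("trapezoid", "sum"),
                min_scans = 22L) {
  tol_mode <- match.arg(tol_mode)
  mode <- match.arg(mode)
  integration <- match.arg(integration)
  stopifnot(inherits(run, "simc_run"), inherits(p, "simc_peptide"))
  ms1 <- run[run$ms_level == 1, ]
  if (!nrow(ms1)) abort("run contains no MS1 scans; SIC needs the survey level")

  traces <- map(charges, function(z) {
    th <- precursor_mz(p, z)
    ints <- map_dbl(ms1$peaks, function(pk) {
      if (!nrow(pk)) return(0)
      err <- if (tol_mode == "ppm") ppm_error(pk$mz, th) else pk$mz - th
      inw <- which(abs(err) <= tol)
      if (!length(inw)) return(0)
      if (mode == "sum") return(sum(pk$intensity[inw]))
      best <- inw[order(abs(err[inw]), -pk$intensity[inw])][1]
      pk$intensity[best]
    })
    tibble(charge = z, mz = th, scan_id = ms1$scan_id, rt = ms1$rt,
           intensity = ints)
  }) |> list_rbind()

  per_charge <- traces |>
    group_by(.data$charge, .data$mz) |>
    summarise(area = .trace_area(.data$rt, .data$intensity, integration),
              n_points = sum(.data$intensity > 0), .groups = "drop")
  if (all(per_charge$n_points < min_scans)) {
    warn(sprintf("SIC traced from fewer than %d MS1 points at every charge; chromatogram outline may be unstable",
                 min_scans))
  }
  structure(
    list(peptide = p, per_charge = per_charge, traces = traces,
         total = sum(per_charge$area),
         settings = list(charges = charges, tol = tol, tol_mode = tol_mode,
                         mode = mode, integration = integration)),
    class = "simc_sic"
  )
}

#' @export
print.simc_sic <- function(x, ...) {
  cat(sprintf("<simc_sic> %s%d-%s%d, charges %s, total area %.4g\n",
              x$peptide$residues[1], x$peptide$start,
              x$peptide$residues[length(x$peptide$residues)], x$peptide$end,
              paste(x$per_charge$charge, collapse = ","), x$total))
  invisible(x)
}

#' @rdname sic
#' @param x A `simc_sic` object.
#' @param ... Unused.
#' @method tidy simc_sic
#' @export
tidy.simc_sic <- function(x, ...) {
  x$per_charge
}

#' @rdname sic
#' @method glance simc_sic
#' @export
glance.simc_sic <- function(x, ...) {
  tibble(total_area = x$total, n_charges = nrow(x$per_charge),
         n_points = sum(x$per_charge$n_points))
}

#' Normalized relative abundance of each isoform
#'
#' Multiplies the total amount of the target peptide (its summed-over-charges
#' SIC) by each isoform's constituent percentage, then normalizes to the SIC
#' of a constitutive reference peptide:
#' `abundance(i) = target_total * percentage(i)/100 / norm_total`.
#'
#' @param quant A `simc_quant` result with defined percentages.
#' @param target_sic SIC of the quantified (target) peptide.
#' @param norm_sic SIC of the normalization peptide; its total must be > 0.
#' @return A tibble: `isoform_id`, `percentage`, `abundance`.
#' @export
relative_abundance <- function(quant, target_sic, norm_sic) {
  stopifnot(inherits(quant, "simc_quant"), inherits(target_sic, "simc_sic"),
            inherits(norm_sic, "simc_sic"))
  if (quant$undefined) abort("quantification has undefined percentages")
  if (norm_sic$total <= 0) abort("normalization peptide SIC total is zero")
  quant$percentages |>
    mutate(abundance = target_sic$total * .data$percentage / 100 / norm_sic$total) |>
    select("isoform_id", "percentage", "abundance")
}

#' Summarize replicate quantifications
#'
#' @param results A list of >= 2 `simc_quant` objects over the same isoform
#'   set (technical or biological replicates).
#' @return A tibble: `isoform_id`, `mean`, `sd` (sample SD), `n`.
#' @export
replicate_summary <- function(results) {
  stopifnot(is.list(results), all(map_lgl(results, inherits, "simc_quant")))
  if (length(results) < 2) abort("need >= 2 replicates to summarise")
  sets <- map(results, function(r) sort(r$percentages$isoform_id))
  if (!all(map_lgl(sets[-1], identical, sets[[1]]))) {
    abort("replicates quantify different isoform sets")
  }
  map(results, tidy) |>
    list_rbind() |>
    group_by(.data$isoform_id) |>
    summarise(mean = mean(.data$percentage), sd = sd(.data$percentage),
              n = n(), .groups = "drop")
}

#' Plot SIMC chromatograms
#'
#' Per-isoform summed specific-ion intensity against retention time.
#'
#' @param object A `simc_quant` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot simc_quant
#' @export
autoplot.simc_quant <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$rt, y = .data$intensity,
                               colour = .data$isoform_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "retention time (min)",
                  y = "summed specific-ion intensity",
                  colour = "isoform", title = "SIMC profile") +
    ggplot2::theme_minimal()
}

#' Plot selected-ion chromatograms
#'
#' @param object A `simc_sic` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot simc_sic
#' @export
autoplot.simc_sic <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$rt, y = .data$intensity,
                               colour = factor(.data$charge))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity",
                  colour = "charge", title = "Selected-ion chromatogram") +
    ggplot2::theme_minimal()
}
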