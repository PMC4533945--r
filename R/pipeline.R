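# End-to-end analysis: declarative YAML config -> select -> match -> SIMC ->
# SIC -> relative abundance -> replicate summary, with JSON + CSV outputs.

#' Read and validate an analysis configuration
#'
#' A single declarative YAML file describing one analysis:
#' \preformatted{
#' runs: [rep1.mzML, rep2.mzML, rep3.mzML]
#' isoforms:
#'   sequence: KSAPATGGVKKPHR
#'   start: 27
#'   isoforms:
#'     K27me3-K36me2: ["27:methyl:3", "36:methyl:2"]
#'     K27me2-K36me3: ["27:methyl:2", "36:methyl:3"]
#' tolerance: {value: 10, mode: ppm}
#' series: y
#' fragment_charges: [2]
#' precursor_charge: 3
#' iso_window: 2.0
#' sic_charges: [1, 2, 3, 4]
#' normalization:            # optional; omit to skip relative abundance
#'   sequence: DIQLAR
#'   start: 123
#'   charges: [1, 2]
#' output: {json: results.json, ledger: ledger.csv}
#' }
#' Validation (tolerance mode, file existence) happens before any I/O.
#'
#' @param path Path to the YAML file.
#' @return A validated config list of class `simc_analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(f) {
    ifelse(file.exists(f), f, file.path(base, f))
  }

  if (is.null(raw$runs) || !length(raw$runs)) abort("config: no 'runs' listed")
  if (is.null(raw$isoforms)) abort("config: no 'isoforms' block")
  tol <- raw$tolerance %||% list(value = 10, mode = "ppm")
  if (!tol$mode %in% c("ppm", "Da")) {
    abort(paste0("config: unknown tolerance mode '", tol$mode,
                 "' (must be 'ppm' or 'Da')"))
  }
  runs <- resolve(unlist(raw$runs))
  missing_runs <- runs[!file.exists(runs)]
  if (length(missing_runs)) {
    abort(paste0("config: run file(s) not found: ",
                 paste(missing_runs, collapse = ", ")))
  }

  iso <- raw$isoforms
  group <- isobaric_group(imap(iso$isoforms, function(mods, id) {
    peptide(iso$sequence, start = iso$start %||% 1L,
            mods = unlist(mods), id = id)
  }))
  target_peptide <- group$isoforms[[1]]

  norm <- NULL
  if (!is.null(raw$normalization)) {
    norm <- list(
      peptide = peptide(raw$normalization$sequence,
                        start = raw$normalization$start %||% 1L,
                        id = "normalization"),
      charges = unlist(raw$normalization$charges %||% list(1L, 2L))
    )
  }

  structure(
    list(runs = runs, group = group, target_peptide = target_peptide,
         tol = tol$value, tol_mode = tol$mode,
         series = raw$series %||% "y",
         fragment_charges = unlist(raw$fragment_charges %||% list(2L)),
         precursor_charge = raw$precursor_charge %||% 3L,
         iso_window = raw$iso_window %||% 2.0,
         sic_charges = unlist(raw$sic_charges %||% list(1L, 2L, 3L, 4L)),
         normalization = norm,
         output = raw$output %||% list(),
         log_level = raw$log_level %||% "info"),
    class = "simc_analysis_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full quantification pipeline
#'
#' For each replicate run: select MS2 scans on the shared precursor, match
#' specific ions, compute SIMC percentages, extract the target peptide's SIC
#' over all configured charge states and (when a normalization peptide is
#' configured) the normalization SIC, then the relative abundance of each
#' isoform; finally summarize percentages across replicates. Writes a JSON
#' report and a CSV matched-ion ledger when output paths are configured.
#' Warnings are logged when an SIC trace has fewer than 22 MS1 points or a
#' SIMC is built from fewer than 6 MS/MS scans.
#'
#' @param cfg A [read_analysis_config()] result (or a compatible list).
#' @return A report list of class `simc_report`: per-replicate results
#'   (`quant`, `sic_target`, `sic_norm`, `abundance`), `summary` (replicate
#'   mean/SD per isoform), `settings`, `warnings`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "simc_analysis_config"))
  all_warnings <- character()
  note <- function(w) all_warnings <<- c(all_warnings, w)

  replicates <- map(seq_along(cfg$runs), function(i) {
    path <- cfg$runs[i]
    run <- .stage(paste0("read_run[", path, "]"), read_run(path))
    q <- .stage(paste0("simc[", path, "]"), withCallingHandlers(
      simc_quantify(run, cfg$group,
                    precursor_charge = cfg$precursor_charge,
                    iso_window = cfg$iso_window, series = cfg$series,
                    fragment_charges = cfg$fragment_charges,
                    tol = cfg$tol, tol_mode = cfg$tol_mode),
      warning = function(w) {
        note(paste0(path, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }))
    s_target <- .stage(paste0("sic_target[", path, "]"), withCallingHandlers(
      sic(run, cfg$target_peptide, charges = cfg$sic_charges,
          tol = cfg$tol, tol_mode = cfg$tol_mode),
      warning = function(w) {
        note(paste0(path, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }))
    s_norm <- NULL
    ab <- NULL
    if (!is.null(cfg$normalization)) {
      s_norm <- .stage(paste0("sic_norm[", path, "]"), withCallingHandlers(
        sic(run, cfg$normalization$peptide,
            charges = cfg$normalization$charges,
            tol = cfg$tol, tol_mode = cfg$tol_mode),
        warning = function(w) {
          note(paste0(path, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }))
      if (s_norm$total <= 0) {
        abort(paste0("pipeline stage 'sic_norm[", path, "]' failed: ",
                     "no signal for normalization peptide ",
                     cfg$normalization$peptide$sequence))
      }
      ab <- .stage(paste0("relative_abundance[", path, "]"),
                   relative_abundance(q, s_target, s_norm))
    }
    list(run = path, quant = q, sic_target = s_target, sic_norm = s_norm,
         abundance = ab)
  })

  summary <- if (length(replicates) >= 2) {
    replicate_summary(map(replicates, "quant"))
  } else {
    tidy(replicates[[1]]$quant) |>
      select("isoform_id", mean = "percentage") |>
      mutate(sd = NA_real_, n = 1L)
  }

  report <- structure(
    list(replicates = replicates, summary = summary,
         settings = cfg[setdiff(names(cfg), c("group", "target_peptide",
                                              "normalization"))],
         warnings = all_warnings),
    class = "simc_report"
  )

  if (!is.null(cfg$output$json)) write_report_json(report, cfg$output$json)
  if (!is.null(cfg$output$ledger) && length(replicates)) {
    write_ledger(replicates[[1]]$quant, cfg$output$ledger)
  }
  report
}

#' Serialize a pipeline report as JSON
#'
#' Deterministic (no timestamps): re-running on identical input and config
#' produces byte-identical output.
#'
#' @param report A `simc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    schema = "simc-report/1",
    settings = report$settings,
    replicates = map(report$replicates, function(r) {
      list(run = r$run,
           percentages = r$quant$percentages,
           n_ms2 = r$quant$n_ms2,
           undefined = r$quant$undefined,
           sic_target_total = r$sic_target$total,
           sic_norm_total = if (!is.null(r$sic_norm)) r$sic_norm$total,
           abundance = r$abundance)
    }),
    summary = report$summary,
    warnings = report$warnings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @export
print.simc_report <- function(x, ...) {
  cat(sprintf("<simc_report> %d replicate(s)\n", length(x$replicates)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-24s mean %6.2f %%  SD %s  (n=%d)\n", s$isoform_id[i],
                s$mean[i],
                if (is.na(s$sd[i])) "  --" else sprintf("%5.2f", s$sd[i]),
                s$n[i]))
  }
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s); first: %s\n", length(x$warnings),
                x$warnings[1]))
  }
  invisible(x)
}
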