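# Uniform in-memory model of an LC-MS/MS run plus mzML / MGF readers and
# writers. A run is a tibble with one row per scan and a `peaks` list-column;
# retention times are always minutes, whatever the file dialect used.

#' Construct an MS run from a scan table
#'
#' @param scans A data frame with columns `scan_id` (character), `ms_level`
#'   (1 or 2), `rt` (minutes, >= 0), `precursor_mz`, `precursor_charge`
#'   (both `NA` for MS1 scans; `NA` charge on an MS2 scan means unknown) and
#'   `peaks` (list of data frames with `mz`, `intensity`). Peak lists are
#'   sorted to strictly increasing m/z; scans are sorted by RT (with a
#'   warning if the input was unsorted).
#' @param metadata Optional named list (source file, instrument notes, ...).
#' @return A tibble of class `simc_run`.
#' @export
ms_run <- function(scans, metadata = list()) {
  scans <- as_tibble(scans)
  need <- c("scan_id", "ms_level", "rt", "precursor_mz", "precursor_charge", "peaks")
  missing_cols <- setdiff(need, names(scans))
  if (length(missing_cols)) {
    abort(paste0("scan table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(scans)) abort("a run must contain at least one scan")
  if (any(scans$rt < 0)) abort("retention times must be >= 0")
  if (!all(scans$ms_level %in% 1:2)) abort("ms_level must be 1 or 2")
  if (is.unsorted(scans$rt)) {
    warn("scans were not RT-ordered; sorting by retention time")
    scans <- arrange(scans, .data$rt)
  }
  scans$peaks <- map(scans$peaks, function(pk) {
    pk <- as_tibble(pk)[, c("mz", "intensity")]
    if (any(pk$intensity < 0)) abort("negative peak intensity")
    if (is.unsorted(pk$mz, strictly = TRUE)) {
      pk <- arrange(pk, .data$mz)
      # collapse exact duplicates so m/z stays strictly increasing
      if (anyDuplicated(pk$mz)) {
        pk <- summarise(group_by(pk, .data$mz),
                        intensity = sum(.data$intensity), .groups = "drop")
      }
    }
    pk
  })
  structure(scans[, need], class = c("simc_run", class(tibble())),
            metadata = metadata)
}

#' @export
print.simc_run <- function(x, ...) {
  cat(sprintf("<simc_run> %d scans (%d MS1, %d MS2), RT %.2f-%.2f min\n",
              nrow(x), sum(x$ms_level == 1), sum(x$ms_level == 2),
              min(x$rt), max(x$rt)))
  NextMethod()
}

#' Read an LC-MS/MS run
#'
#' Reads centroided mzML (via the proteomics standard parser in \pkg{mzR})
#' or MGF. MGF files carry only MS2 scans, so the resulting run has no MS1
#' scans; MGF entries without a CHARGE line get an unknown (`NA`) precursor
#' charge.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mzml"` or `"mgf"`.
#' @return A [ms_run()] tibble.
#' @export
read_run <- function(path, format = c("auto", "mzml", "mgf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mzml = "mzml", mgf = "mgf",
                     abort(paste0("cannot infer format from extension: ", path)))
  }
  if (file.size(path) == 0) abort(paste0("empty file: ", path))
  switch(format, mzml = .read_mzml(path), mgf = .read_mgf(path))
}

#' Write an LC-MS/MS run
#'
#' @param run A [ms_run()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"mzml"` or `"mgf"`. Writing MGF
#'   drops MS1 scans (the format holds only fragmentation spectra).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, format = c("auto", "mzml", "mgf")) {
  stopifnot(inherits(run, "simc_run"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mzml = "mzml", mgf = "mgf",
                     abort(paste0("cannot infer format from extension: ", path)))
  }
  switch(format, mzml = .write_mzml(run, path), mgf = .write_mgf(run, path))
  invisible(path)
}

.read_mzml <- function(path) {
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) abort(paste0("failed to parse mzML '",
                                                      path, "': ", conditionMessage(e))))
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (!nrow(hdr)) abort(paste0("no spectra in ", path))
  pks <- mzR::peaks(handle)
  if (is.matrix(pks)) pks <- list(pks)
  unknown_charge <- hdr$msLevel == 2 &
    (is.na(hdr$precursorCharge) | hdr$precursorCharge == 0)
  if (any(unknown_charge)) {
    warn(sprintf("%d MS2 scan(s) lack precursor charge; recorded as unknown",
                 sum(unknown_charge)))
  }
  scans <- tibble(
    scan_id = as.character(hdr$acquisitionNum),
    ms_level = as.integer(hdr$msLevel),
    rt = hdr$retentionTime / 60,          # mzR reports seconds
    precursor_mz = ifelse(hdr$msLevel == 2, hdr$precursorMZ, NA_real_),
    precursor_charge = ifelse(hdr$msLevel == 2 & !unknown_charge,
                              hdr$precursorCharge, NA_integer_),
    peaks = map(pks, function(m) tibble(mz = m[, 1], intensity = m[, 2]))
  )
  ms_run(scans, metadata = list(source = path, format = "mzml"))
}

.write_mzml <- function(run, path) {
  n <- nrow(run)
  pk_mats <- map(run$peaks, function(pk) cbind(mz = pk$mz, intensity = pk$intensity))
  npk <- map_dbl(run$peaks, nrow)
  tic <- map_dbl(run$peaks, function(pk) sum(pk$intensity))
  bp <- map(run$peaks, function(pk) {
    if (!nrow(pk)) return(c(NA_real_, NA_real_))
    i <- which.max(pk$intensity); c(pk$mz[i], pk$intensity[i])
  })
  is2 <- run$ms_level == 2
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(run$ms_level), polarity = 1L,
    peaksCount = as.integer(npk), totIonCurrent = tic,
    retentionTime = run$rt * 60,
    basePeakMZ = map_dbl(bp, 1), basePeakIntensity = map_dbl(bp, 2),
    collisionEnergy = ifelse(is2, 35, NA_real_), ionisationEnergy = 0,
    lowMZ = map_dbl(run$peaks, function(pk) if (nrow(pk)) min(pk$mz) else NA_real_),
    highMZ = map_dbl(run$peaks, function(pk) if (nrow(pk)) max(pk$mz) else NA_real_),
    precursorScanNum = NA_integer_,
    precursorMZ = ifelse(is2, run$precursor_mz, NA_real_),
    precursorCharge = ifelse(is2, as.integer(run$precursor_charge), NA_integer_),
    precursorIntensity = ifelse(is2, 0, NA_real_),
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is2, run$precursor_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(is2, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(is2, 1, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(pk_mats, file = path, header = hdr, outformat = "mzml")
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (!length(begins) || length(begins) != length(ends)) {
    abort(paste0("malformed MGF '", path, "': unbalanced BEGIN/END IONS"))
  }
  scans <- map2(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    meta <- setNames(vals, keys)
    pk_lines <- block[!kv & nzchar(trimws(block))]
    pk <- if (length(pk_lines)) {
      m <- do.call(rbind, strsplit(trimws(pk_lines), "[ \t]+"))
      tibble(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
    } else {
      tibble(mz = numeric(), intensity = numeric())
    }
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", meta[["CHARGE"]]))
    } else NA_integer_
    tibble(
      scan_id = if ("TITLE" %in% keys) meta[["TITLE"]] else NA_character_,
      ms_level = 2L,
      rt = if ("RTINSECONDS" %in% keys) as.numeric(meta[["RTINSECONDS"]]) / 60 else NA_real_,
      precursor_mz = if ("PEPMASS" %in% keys) {
        as.numeric(strsplit(meta[["PEPMASS"]], "[ \t]+")[[1]][1])
      } else NA_real_,
      precursor_charge = charge,
      peaks = list(pk)
    )
  }) |> list_rbind()
  if (any(is.na(scans$scan_id))) {
    scans$scan_id[is.na(scans$scan_id)] <-
      paste0("index=", which(is.na(scans$scan_id)))
  }
  if (any(is.na(scans$rt))) abort(paste0("MGF scans lack RTINSECONDS: ", path))
  if (any(is.na(scans$precursor_charge))) {
    warn(sprintf("%d MGF scan(s) lack CHARGE; precursor charge recorded as unknown",
                 sum(is.na(scans$precursor_charge))))
  }
  ms_run(scans, metadata = list(source = path, format = "mgf"))
}

.write_mgf <- function(run, path) {
  ms2 <- run[run$ms_level == 2, ]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ms2))) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", ms2$scan_id[i]),
      paste0("RTINSECONDS=", format(ms2$rt[i] * 60, digits = 10)),
      paste0("PEPMASS=", sprintf("%.6f", ms2$precursor_mz[i])),
      if (!is.na(ms2$precursor_charge[i])) {
        paste0("CHARGE=", ms2$precursor_charge[i], "+")
      },
      sprintf("%.6f %.6g", ms2$peaks[[i]]$mz, ms2$peaks[[i]]$intensity),
      "END IONS", ""
    ), con)
  }
}

#' Select MS2 scans by precursor
#'
#' Keeps MS2 scans whose recorded precursor m/z lies within half the
#' isolation window of `target_mz` and whose precursor charge matches.
#' Scans with unknown precursor charge are excluded unless
#' `include_unknown_charge = TRUE`, since the method targets one charge
#' state. Input order (RT order) is preserved.
#'
#' @param run A [ms_run()].
#' @param target_mz Precursor m/z to select around.
#' @param charge Required precursor charge.
#' @param iso_window Full isolation-window width in Th (default 2.0,
#'   i.e. +/- 1.0).
#' @param include_unknown_charge Accept scans with unknown charge.
#' @return A tibble of the selected MS2 scans (possibly empty).
#' @export
select_ms2 <- function(run, target_mz, charge, iso_window = 2,
                       include_unknown_charge = FALSE) {
  stopifnot(inherits(run, "simc_run"))
  if (iso_window <= 0) abort("iso_window must be > 0")
  keep <- run$ms_level == 2 &
    !is.na(run$precursor_mz) &
    abs(run$precursor_mz - target_mz) <= iso_window / 2 &
    (ifelse(is.na(run$precursor_charge), include_unknown_charge,
            run$precursor_charge == charge))
  as_tibble(run[keep, ])
}

#' Centroid a profile-mode spectrum (minimal)
#'
#' Simple local-maximum picker: a peak is any point strictly higher than its
#' two neighbours. Provided for convenience with profile input; the
#' validated workflow assumes instrument-centroided data.
#'
#' @param mz,intensity Profile arrays (equal length, mz increasing).
#' @return A tibble with centroided `mz`, `intensity`.
#' @export
centroid_spectrum <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  n <- length(mz)
  if (n < 3) return(tibble(mz = mz, intensity = intensity))
  i <- 2:(n - 1)
  keep <- i[intensity[i] > intensity[i - 1] & intensity[i] > intensity[i + 1]]
  tibble(mz = mz[keep], intensity = intensity[keep])
}
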