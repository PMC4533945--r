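# Independent oracles and fixture builders used across the suite.

# --- elemental-composition mass oracle -------------------------------------
# Residue elemental formulas (C,H,N,O,S) and monoisotopic element masses,
# summed independently of the package's residue table.
.elem_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)
# methyl = +CH2 per unit; acetyl = +C2H2O; phospho = +HPO3; oxidation = +O
.mod_formula_mass <- c(
  methyl = 12 + 2 * .elem_mass[["H"]],
  acetyl = 2 * 12 + 2 * .elem_mass[["H"]] + .elem_mass[["O"]],
  oxidation = .elem_mass[["O"]],
  phospho = .elem_mass[["H"]] + 30.97376151 + 3 * .elem_mass[["O"]]
)

oracle_peptide_mass <- function(seq, mod_kinds = character(),
                                mod_mult = numeric()) {
  counts <- Reduce(`+`, lapply(strsplit(seq, "")[[1]],
                               function(r) .residue_formula[[r]]))
  counts <- counts + c(0, 2, 0, 1, 0)  # water
  m <- sum(counts * .elem_mass[c("C", "H", "N", "O", "S")])
  if (length(mod_kinds)) {
    m <- m + sum(.mod_formula_mass[mod_kinds] * mod_mult)
  }
  m
}

# --- brute-force specific-ion window oracle --------------------------------
# A (series, index) slot is specific iff the residue window it covers holds
# an unequal total modification delta across the isoforms.
oracle_specific_slots <- function(isoforms) {
  p1 <- isoforms[[1]]
  n <- nchar(p1$sequence)
  window_delta <- function(p, sites) {
    sum(p$mods$delta[p$mods$site %in% sites])
  }
  out <- list()
  for (i in seq_len(n - 1)) {
    b_sites <- p1$start + seq_len(i) - 1L
    y_sites <- p1$start + (n - i):(n - 1)
    for (series in c("b", "y")) {
      sites <- if (series == "b") b_sites else y_sites
      deltas <- vapply(isoforms, window_delta, numeric(1), sites = sites)
      if (diff(range(deltas)) > 1e-9) {
        out[[length(out) + 1L]] <- data.frame(series = series, index = i)
      }
    }
  }
  if (!length(out)) return(data.frame(series = character(), index = integer()))
  do.call(rbind, out)
}

# --- exhaustive bitmask digestion oracle -----------------------------------
# Enumerate all subsets of permitted cleavage sites; collect every product
# whose flanks are cut and internal sites uncut, with <= max_missed internal
# sites. Returns sorted (start, end, n_missed) rows.
oracle_digest <- function(p, rule = cleavage_rule(), max_missed = 0L) {
  sites <- simcquant:::.cleavage_sites(p, rule)
  bounds_all <- c(p$start - 1L, sites, p$end)
  prods <- list()
  n <- length(sites)
  for (mask in 0:(2^n - 1)) {
    on <- if (n) sites[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0] else integer()
    cuts <- c(p$start - 1L, on, p$end)
    for (k in seq_len(length(cuts) - 1)) {
      s <- cuts[k] + 1L; e <- cuts[k + 1]
      nm <- sum(sites > cuts[k] & sites < e)
      if (nm <= max_missed) {
        prods[[paste(s, e)]] <- data.frame(start = s, end = e, n_missed = nm)
      }
    }
  }
  out <- unique(do.call(rbind, prods))
  out[order(out$start, out$end), , drop = FALSE]
}

# --- fixture builders -------------------------------------------------------
h3_pair <- function() h3_k27r40me5_group()

random_peptide <- function(min_len = 5, max_len = 20, with_mods = FALSE) {
  aas <- residue_masses()$residue
  n <- sample(min_len:max_len, 1)
  seq <- paste(sample(aas, n, replace = TRUE), collapse = "")
  mods <- NULL
  if (with_mods) {
    res <- strsplit(seq, "")[[1]]
    k_sites <- which(res == "K")
    if (length(k_sites)) {
      site <- k_sites[sample.int(length(k_sites), 1)]
      mods <- sprintf("%d:methyl:%d", site, sample(1:3, 1))
    }
  }
  peptide(seq, start = 1L, mods = mods)
}

# a minimal hand-assembled run: MS2 scans holding given peak lists at the
# shared 3+ precursor of the pentamethyl pair, plus optional MS1 scans
tiny_run <- function(ms2_peaks, rts = NULL, ms1_peaks = NULL, ms1_rts = NULL) {
  prec <- group_precursor_mz(h3_pair(), 3)
  if (is.null(rts)) rts <- seq_along(ms2_peaks)
  scans <- tibble::tibble(
    scan_id = paste0("ms2_", seq_along(ms2_peaks)),
    ms_level = 2L, rt = rts,
    precursor_mz = prec, precursor_charge = 3L,
    peaks = lapply(ms2_peaks, function(m) {
      tibble::tibble(mz = m$mz, intensity = m$intensity)
    })
  )
  if (!is.null(ms1_peaks)) {
    scans <- dplyr::bind_rows(
      tibble::tibble(
        scan_id = paste0("ms1_", seq_along(ms1_peaks)),
        ms_level = 1L, rt = ms1_rts,
        precursor_mz = NA_real_, precursor_charge = NA_integer_,
        peaks = lapply(ms1_peaks, function(m) {
          tibble::tibble(mz = m$mz, intensity = m$intensity)
        })
      ), scans)
    scans <- scans[order(scans$rt), ]
  }
  ms_run(scans)
}

# noiseless, jitter-free simulation config (deterministic fragmentation)
noiseless_config <- function(fractions, seed = 1L, ...) {
  simulation_config(
    fractions = fractions, jitter_sigma = 0, noise_peaks = 0,
    mz_sigma_ppm = 0, seed = seed, ...)
}
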