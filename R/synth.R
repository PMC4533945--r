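# Seeded simulator of LC-MS/MS runs with coeluting isobaric isoform
# mixtures. Emulates the measurement situation the method was built for: two
# pentamethylated K27-R40 isoforms eluting as one Gaussian peak around
# 13.5 min, a 1-4+ precursor charge envelope dominated by 3+/4+, MS2 scans
# triggered on the 3+ precursor in which y2+ fragments dominate, per-scan
# fragmentation-efficiency jitter, random noise peaks, and Gaussian ppm mass
# error. Ground truth (true fractions, per-scan intensity bookkeeping) is
# returned alongside so recovery can be scored exactly.

# run the body with a private, seeded RNG stream, restoring global state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe the validation conditions: a two-isoform pentamethylated
#' K27-R40 mixture eluting as a single coeluting Gaussian peak at 13.5 min
#' (within the observed 13.3-13.8 min window), one MS1 survey plus three MS2
#' scans per cycle, a 1-4+ charge envelope dominated by 3+ and 4+, y2+
#' fragments roughly tenfold more efficient than y1+/b1+/b2+ (so non-y2+
#' ions are only sporadically detectable), the proline-enhanced y11-13 ions
#' threefold stronger, lognormal per-scan-per-ion fragmentation jitter,
#' uniform-m/z noise peaks with exponential intensities, and 2 ppm Gaussian
#' mass error.
#'
#' @param group An [isobaric_group()] to simulate (default: the
#'   pentamethylated K27-R40 pair, K27me3-K36me2 and K27me2-K36me3).
#' @param fractions Named mixing fractions summing to 1 (names = isoform ids).
#' @param rt_center,rt_sd Gaussian elution center and width, minutes.
#' @param rt_range Simulated acquisition window, minutes.
#' @param ms1_interval MS1 cycle time, minutes.
#' @param ms2_per_cycle MS2 scans triggered after each MS1.
#' @param precursor_charges,envelope_weights Charge states present at MS1 and
#'   their relative weights.
#' @param trigger_charge Charge state isolated for fragmentation.
#' @param base_intensity Apex MS1 intensity scale (arbitrary units).
#' @param frag_efficiency Named per-ion conversion efficiencies for
#'   `y1`, `y2`, `b1`, `b2` (series + charge).
#' @param prominent_y Indices of y ions with enhanced intensity and their
#'   `prominence` multiplier (C-terminal proline effect).
#' @param prominence Multiplier applied to `prominent_y` ions.
#' @param jitter_sigma Lognormal sigma of per-scan-per-ion fragmentation
#'   jitter (0 = perfectly stable fragmentation).
#' @param noise_peaks Mean number of random noise peaks per scan (0 = none).
#' @param noise_mean Mean of the exponential noise-intensity distribution,
#'   as a fraction of `base_intensity`.
#' @param mz_sigma_ppm Gaussian sigma of the m/z error model, ppm.
#' @param mz_range Instrument m/z window for noise peaks.
#' @param seed RNG seed; the same config + seed reproduces the run exactly.
#' @return An object of class `simc_sim_config`.
#' @export
simulation_config <- function(group = h3_k27r40me5_group(),
                              fractions = c(`K27me3-K36me2` = 0.5,
                                            `K27me2-K36me3` = 0.5),
                              rt_center = 13.5, rt_sd = 0.08,
                              rt_range = c(12.8, 14.2),
                              ms1_interval = 0.05, ms2_per_cycle = 3L,
                              precursor_charges = 1:4,
                              envelope_weights = c(0.05, 0.15, 0.50, 0.30),
                              trigger_charge = 3L,
                              base_intensity = 1e6,
                              frag_efficiency = c(y1 = 0.02, y2 = 0.20,
                                                  b1 = 0.02, b2 = 0.02),
                              prominent_y = 11:13, prominence = 3,
                              jitter_sigma = 0.30,
                              noise_peaks = 20, noise_mean = 0.01,
                              mz_sigma_ppm = 2,
                              mz_range = c(200, 1400),
                              seed = 1L) {
  fr <- fractions[names(group$isoforms)]
  if (anyNA(fr)) abort("fractions must be named by the group's isoform ids")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    abort("mixing fractions must be >= 0 and sum to 1")
  }
  stopifnot(length(envelope_weights) == length(precursor_charges),
            jitter_sigma >= 0, mz_sigma_ppm >= 0, noise_peaks >= 0,
            rt_sd > 0)
  structure(
    list(group = group, fractions = fr, rt_center = rt_center, rt_sd = rt_sd,
         rt_range = rt_range, ms1_interval = ms1_interval,
         ms2_per_cycle = as.integer(ms2_per_cycle),
         precursor_charges = precursor_charges,
         envelope_weights = setNames(envelope_weights,
                                     as.character(precursor_charges)),
         trigger_charge = as.integer(trigger_charge),
         base_intensity = base_intensity, frag_efficiency = frag_efficiency,
         prominent_y = prominent_y, prominence = prominence,
         jitter_sigma = jitter_sigma, noise_peaks = noise_peaks,
         noise_mean = noise_mean, mz_sigma_ppm = mz_sigma_ppm,
         mz_range = mz_range, seed = as.integer(seed)),
    class = "simc_sim_config"
  )
}

#' The pentamethylated histone H3 K27-R40 isoform pair
#'
#' Convenience constructor for the canonical isobaric group: the tryptic
#' K27-R40 peptide (KSAPATGGVKKPHR) carrying five methyl groups split over
#' K27 and K36 as trimethyl/dimethyl in either order.
#'
#' @return An [isobaric_group()] with isoforms `K27me3-K36me2` and
#'   `K27me2-K36me3`.
#' @export
h3_k27r40me5_group <- function() {
  isobaric_group(list(
    peptide("KSAPATGGVKKPHR", start = 27,
            mods = c("27:methyl:3", "36:methyl:2"), id = "K27me3-K36me2"),
    peptide("KSAPATGGVKKPHR", start = 27,
            mods = c("27:methyl:2", "36:methyl:3"), id = "K27me2-K36me3")
  ))
}

#' The constitutive H3 D123-R128 normalization peptide
#'
#' DIQLAR, the modification-free tryptic peptide of histone H3 used to
#' normalize isoform abundances across samples (SIC over charges 1-2+).
#'
#' @return A [peptide()].
#' @export
h3_d123r128_peptide <- function() {
  peptide("DIQLAR", start = 123, id = "D123-R128")
}

# Gaussian elution profile normalized to height 1 at the apex
.elution <- function(rt, center, sd) exp(-0.5 * ((rt - center) / sd)^2)

# perturb m/z values with Gaussian ppm error
.jitter_mz <- function(mz, sigma_ppm) {
  if (sigma_ppm <= 0) return(mz)
  mz * (1 + rnorm(length(mz), 0, sigma_ppm) * 1e-6)
}

# noise peaks: uniform m/z, exponential intensity
.noise_peaks <- function(cfg) {
  n <- if (cfg$noise_peaks > 0) stats::rpois(1, cfg$noise_peaks) else 0L
  if (!n) return(tibble(mz = numeric(), intensity = numeric()))
  tibble(mz = runif(n, cfg$mz_range[1], cfg$mz_range[2]),
         intensity = rexp(n, rate = 1 / (cfg$noise_mean * cfg$base_intensity)))
}

#' Simulate a seeded LC-MS/MS run of an isobaric mixture
#'
#' Writes MS1 scans holding the precursor charge envelope with Gaussian
#' elution intensity, and MS2 scans triggered on the configured precursor
#' charge holding both isoforms' full b/y fragment ladders (charges 1-2)
#' scaled by mixing fraction x per-ion efficiency x per-scan lognormal
#' jitter, plus noise peaks; every signal m/z is perturbed by the Gaussian
#' ppm error model. Fragments shared between isoforms (non-specific ions)
#' appear as single peaks with summed intensity. The returned ground truth
#' records, per MS2 scan and isoform, the written (pre-perturbation)
#' specific-y2+ intensity sums, plus per-charge MS1 areas — exact
#' bookkeeping for recovery scoring.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `simc_simulation`: `run` (a [ms_run()]) and
#'   `truth` (list: `fractions`, `per_scan`, `specific_y2_totals`,
#'   `specific_y2_areas`, `expected_percentages`, `ms1_areas`,
#'   `ms1_total_area`).
#' @export
simulate_run <- function(cfg) {
  stopifnot(inherits(cfg, "simc_sim_config"))
  .with_seed(cfg$seed, .simulate_run_impl(cfg))
}

.simulate_run_impl <- function(cfg) {
  group <- cfg$group
  ids <- names(group$isoforms)
  prec_mz <- setNames(map_dbl(cfg$precursor_charges, group_precursor_mz,
                              group = group),
                      as.character(cfg$precursor_charges))
  trigger_mz <- prec_mz[[as.character(cfg$trigger_charge)]]

  # theoretical fragment ladders per isoform, charges 1-2, with per-ion
  # deterministic weights (efficiency x prominence)
  ladders <- map(group$isoforms, function(p) {
    fr <- fragment_ions(p, series = c("b", "y"), max_charge = 2L)
    key <- paste0(fr$series, fr$charge)
    fr$weight <- unname(cfg$frag_efficiency[key]) *
      ifelse(fr$series == "y" & fr$index %in% cfg$prominent_y,
             cfg$prominence, 1)
    fr
  })
  spec <- specific_ions(group, series = "y", charges = 2L)

  ms1_times <- seq(cfg$rt_range[1], cfg$rt_range[2], by = cfg$ms1_interval)
  scans <- list()
  per_scan <- list()
  ms1_book <- list()
  scan_no <- 0L

  for (t0 in ms1_times) {
    el <- .elution(t0, cfg$rt_center, cfg$rt_sd)
    scan_no <- scan_no + 1L
    prec_int <- cfg$base_intensity * el * cfg$envelope_weights
    sig <- tibble(mz = .jitter_mz(unname(prec_mz), cfg$mz_sigma_ppm),
                  intensity = unname(prec_int))
    sig <- sig[sig$intensity > 0, ]
    pk <- bind_rows(sig, .noise_peaks(cfg))
    scans[[scan_no]] <- tibble(
      scan_id = as.character(scan_no), ms_level = 1L, rt = t0,
      precursor_mz = NA_real_, precursor_charge = NA_integer_,
      peaks = list(pk))
    ms1_book[[length(ms1_book) + 1L]] <-
      tibble(rt = t0, charge = cfg$precursor_charges,
             intensity = unname(prec_int))

    for (k in seq_len(cfg$ms2_per_cycle)) {
      tk <- t0 + cfg$ms1_interval * k / (cfg$ms2_per_cycle + 1)
      elk <- .elution(tk, cfg$rt_center, cfg$rt_sd)
      scan_no <- scan_no + 1L
      frag <- imap(ladders, function(lad, id) {
        jit <- if (cfg$jitter_sigma > 0) {
          exp(rnorm(nrow(lad), 0, cfg$jitter_sigma))
        } else 1
        mutate(lad,
               intensity = cfg$base_intensity * elk * cfg$fractions[[id]] *
                 .data$weight * jit)
      }) |> list_rbind()
      # merge ions shared across isoforms (identical theoretical m/z)
      merged <- frag |>
        group_by(.data$mz) |>
        summarise(intensity = sum(.data$intensity), .groups = "drop") |>
        filter(.data$intensity > 0)
      merged$mz <- .jitter_mz(merged$mz, cfg$mz_sigma_ppm)
      pk2 <- bind_rows(merged, .noise_peaks(cfg))
      scans[[scan_no]] <- tibble(
        scan_id = as.character(scan_no), ms_level = 2L, rt = tk,
        precursor_mz = .jitter_mz(trigger_mz, cfg$mz_sigma_ppm),
        precursor_charge = cfg$trigger_charge,
        peaks = list(pk2))
      # bookkeeping: written specific-y2+ intensity per isoform, pre-noise
      sums <- frag |>
        dplyr::semi_join(spec, by = c("isoform_id", "series", "index", "charge")) |>
        group_by(.data$isoform_id) |>
        summarise(intensity = sum(.data$intensity), .groups = "drop")
      per_scan[[length(per_scan) + 1L]] <-
        left_join(tibble(scan_id = as.character(scan_no), rt = tk,
                         isoform_id = ids),
                  sums, by = "isoform_id") |>
        mutate(intensity = ifelse(is.na(.data$intensity), 0, .data$intensity))
    }
  }

  per_scan <- list_rbind(per_scan)
  totals <- per_scan |>
    group_by(.data$isoform_id) |>
    summarise(total = sum(.data$intensity),
              area = .trace_area(.data$rt, .data$intensity), .groups = "drop")
  expected <- if (sum(totals$area) > 0) {
    setNames(totals$area / sum(totals$area) * 100, totals$isoform_id)
  } else {
    setNames(rep(NA_real_, nrow(totals)), totals$isoform_id)
  }
  ms1_book <- list_rbind(ms1_book)
  ms1_areas <- ms1_book |>
    group_by(.data$charge) |>
    summarise(area = .trace_area(.data$rt, .data$intensity), .groups = "drop")

  run <- ms_run(list_rbind(scans),
                metadata = list(source = "simulate_run", seed = cfg$seed))
  structure(
    list(run = run,
         truth = list(
           fractions = cfg$fractions,
           per_scan = per_scan,
           specific_y2_totals = setNames(totals$total, totals$isoform_id),
           specific_y2_areas = setNames(totals$area, totals$isoform_id),
           expected_percentages = expected,
           ms1_areas = ms1_areas,
           ms1_total_area = sum(ms1_areas$area))),
    class = "simc_simulation"
  )
}

#' Simulate tryptic digestion of long isoform precursors, then the run
#'
#' Digests longer peptides (e.g. the L20-R52 pair standing in for intact
#' histone H3) under the methylation-aware [cleavage_rule()], locates the
#' K27-R40-type product of each isoform, optionally skews one isoform's
#' effective yield (emulating small digestion-efficiency preferences), and
#' simulates the run on the products.
#'
#' @param long_isoforms A named list of [peptide()] objects sharing sequence
#'   and start, each carrying one isoform's modifications.
#' @param fractions Named mixing fractions (sum 1) for the long peptides.
#' @param cfg A [simulation_config()]; its `group`/`fractions` are replaced
#'   by the digestion products and skew-adjusted fractions.
#' @param rule A [cleavage_rule()].
#' @param max_missed Missed cleavages allowed in the digest (default 1).
#' @param digestion_skew Named per-isoform relative digestion yield
#'   (default 1 for all); effective fractions are
#'   `fractions * skew / sum(fractions * skew)`.
#' @return As [simulate_run()], plus `products` (the digest tables).
#' @export
simulate_digest_sample <- function(long_isoforms, fractions, cfg,
                                   rule = cleavage_rule(), max_missed = 1L,
                                   digestion_skew = NULL) {
  stopifnot(is.list(long_isoforms))
  ids <- names(long_isoforms)
  fr <- fractions[ids]
  if (anyNA(fr) || abs(sum(fr) - 1) > 1e-9) {
    abort("fractions must be named by isoform and sum to 1")
  }
  skew <- if (is.null(digestion_skew)) setNames(rep(1, length(ids)), ids) else {
    digestion_skew[ids]
  }
  if (anyNA(skew)) abort("digestion_skew must be named by isoform")

  digests <- imap(long_isoforms, function(p, id) {
    p$id <- id
    digest(p, rule = rule, max_missed = max_missed)
  })
  # the quantifiable product: same span across isoforms, carrying both
  # modified sites
  spans <- map(digests, function(d) {
    keep <- map_lgl(d$product, function(q) nrow(q$mods) == nrow(long_isoforms[[1]]$mods))
    d[keep & d$n_missed == min(d$n_missed[keep]), ]
  })
  starts <- map_dbl(spans, function(d) d$start[1])
  ends <- map_dbl(spans, function(d) d$end[1])
  if (length(unique(starts)) != 1 || length(unique(ends)) != 1) {
    abort("digestion products carrying the modifications differ across isoforms")
  }
  products <- map(spans, function(d) d$product[[1]])
  eff <- fr * skew
  eff <- eff / sum(eff)

  cfg$group <- isobaric_group(products)
  cfg$fractions <- eff[names(cfg$group$isoforms)]
  sim <- simulate_run(cfg)
  sim$products <- digests
  sim$truth$input_fractions <- fr
  sim
}
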