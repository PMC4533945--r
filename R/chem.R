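# Monoisotopic mass chemistry: residue masses, modification deltas, peptide
# mass and precursor m/z. All masses in Da, computed at full double precision;
# printed m/z values are conventionally shown to 4 decimals.

# monoisotopic residue (not free amino acid) masses, 6-decimal precision
.aa_mono <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.mass_water  <- 18.010565
.mass_proton <- 1.007276

# per-unit modification mass deltas; multiplicity scales methyl only
.mod_deltas <- c(
  methyl    = 14.015650,
  acetyl    = 42.010565,
  phospho   = 79.966331,
  oxidation = 15.994915
)

# residues each modification kind may sit on
.mod_targets <- list(
  methyl    = c("K", "R"),
  acetyl    = "K",
  phospho   = c("S", "T"),
  oxidation = "M"
)

#' Monoisotopic residue mass table
#'
#' Masses of the 20 standard amino-acid residues (i.e. the free amino acid
#' minus water, as incorporated in a peptide chain), to six decimal places.
#'
#' @return A tibble with columns `residue` (one-letter code) and `mass` (Da).
#' @examples
#' residue_masses()
#' @export
residue_masses <- function() {
  tibble(residue = names(.aa_mono), mass = unname(.aa_mono))
}

#' Mass constants
#'
#' @return Named numeric vector with `water` (18.010565 Da) and `proton`
#'   (1.007276 Da). The proton mass, not the hydrogen atom mass, is used for
#'   charging: `m/z = (M + z * proton) / z`.
#' @export
mass_constants <- function() {
  c(water = .mass_water, proton = .mass_proton)
}

#' Modification mass deltas
#'
#' Per-unit monoisotopic mass shifts of the supported variable modifications.
#' Methylation is the only kind with multiplicity > 1 (mono/di/tri on lysine);
#' the total delta is `multiplicity * unit delta`.
#'
#' @return A tibble with columns `kind` and `delta` (Da per unit).
#' @export
modification_deltas <- function() {
  tibble(kind = names(.mod_deltas), delta = unname(.mod_deltas))
}

# parse "site:kind:multiplicity" strings into a mods tibble
.parse_mod_strings <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  bad <- lengths(parts) < 2L | lengths(parts) > 3L
  if (any(bad)) {
    abort(paste0("malformed modification entry: '", x[bad][1],
                 "' (expected 'site:kind' or 'site:kind:multiplicity')"))
  }
  tibble(
    site = as.integer(map_chr(parts, 1)),
    kind = map_chr(parts, 2),
    multiplicity = map_dbl(parts, function(p) {
      if (length(p) == 3L) as.numeric(p[3]) else 1
    })
  )
}

#' Construct a modified peptide
#'
#' A peptide is a residue string anchored at a protein position (so that
#' modification sites keep their protein numbering, e.g. "K27" of histone H3)
#' together with site-resolved modifications.
#'
#' @param sequence One-letter residue string (standard 20 amino acids).
#' @param start Protein-numbering position of the first residue (default 1).
#' @param mods Site-resolved modifications: either a data frame with columns
#'   `site`, `kind`, `multiplicity`, or a character vector of
#'   `"site:kind:multiplicity"` entries (e.g. `"27:methyl:3"`), or `NULL`.
#' @param id Optional identifier (used as the isoform label in groups).
#'
#' @return An object of class `simc_peptide`.
#' @examples
#' peptide("KSAPATGGVKKPHR", start = 27,
#'         mods = c("27:methyl:3", "36:methyl:2"), id = "K27me3-K36me2")
#' @export
peptide <- function(sequence, start = 1L, mods = NULL, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(.aa_mono))
  if (length(unknown)) {
    abort(paste0("unknown residue code(s): ", paste(unique(unknown), collapse = ", ")))
  }
  start <- as.integer(start)
  end <- start + length(res) - 1L

  if (is.null(mods)) {
    mods <- tibble(site = integer(), kind = character(), multiplicity = numeric())
  } else if (is.character(mods)) {
    mods <- .parse_mod_strings(mods)
  } else {
    mods <- as_tibble(mods)[, c("site", "kind", "multiplicity")]
    mods$site <- as.integer(mods$site)
  }

  if (nrow(mods)) {
    if (any(mods$site < start | mods$site > end)) {
      abort(sprintf("modification site outside peptide range [%d, %d]", start, end))
    }
    if (!all(mods$kind %in% names(.mod_deltas))) {
      abort(paste0("unknown modification kind: ",
                   paste(setdiff(mods$kind, names(.mod_deltas)), collapse = ", ")))
    }
    mods$residue <- res[mods$site - start + 1L]
    ok <- map_lgl(seq_len(nrow(mods)), function(i) {
      mods$residue[i] %in% .mod_targets[[mods$kind[i]]]
    })
    if (!all(ok)) {
      bad <- mods[!ok, ][1, ]
      abort(sprintf("%s not valid on residue %s at site %d",
                    bad$kind, bad$residue, bad$site))
    }
    if (any(mods$kind == "methyl" & mods$residue == "K" &
            !(mods$multiplicity %in% 1:3))) {
      abort("lysine methylation multiplicity must be 1, 2 or 3")
    }
    mods$delta <- .mod_deltas[mods$kind] * mods$multiplicity
    mods <- arrange(mods, .data$site)
  } else {
    mods$residue <- character()
    mods$delta <- numeric()
  }

  structure(
    list(sequence = sequence, residues = res, start = start, end = end,
         mods = mods, id = id),
    class = "simc_peptide"
  )
}

#' @export
print.simc_peptide <- function(x, ...) {
  cat(sprintf("<simc_peptide> %s%d-%s%d%s\n",
              x$residues[1], x$start, x$residues[length(x$residues)], x$end,
              if (!is.null(x$id)) paste0("  [", x$id, "]") else ""))
  cat("  sequence:", x$sequence, "\n")
  if (nrow(x$mods)) {
    cat("  mods:    ",
        paste(sprintf("%s%d:%s x%g", x$mods$residue, x$mods$site,
                      x$mods$kind, x$mods$multiplicity), collapse = ", "), "\n")
  }
  cat(sprintf("  mass:     %.4f Da\n", peptide_mass(x)))
  invisible(x)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water plus all modification deltas.
#'
#' @param p A [peptide()].
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass(peptide("G"))  # 75.032029
#' @export
peptide_mass <- function(p) {
  stopifnot(inherits(p, "simc_peptide"))
  sum(.aa_mono[p$residues]) + .mass_water + sum(p$mods$delta)
}

#' Precursor m/z of a charged peptide
#'
#' @param p A [peptide()].
#' @param z Positive integer charge state.
#' @return `(mass + z * proton) / z`.
#' @examples
#' p <- peptide("KSAPATGGVKKPHR", 27, c("27:methyl:3", "36:methyl:2"))
#' precursor_mz(p, 3)  # 501.9755
#' @export
precursor_mz <- function(p, z) {
  if (any(z < 1)) abort("charge state must be >= 1")
  (peptide_mass(p) + z * .mass_proton) / z
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(667.3890, 667.3886)  # ~ +0.60 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Read a peptide definition from a YAML config
#'
#' The file holds `sequence`, optional `start` (default 1), optional `id`, and
#' optional `mods`, a list of `"site:kind:multiplicity"` strings.
#'
#' @param path Path to a YAML file.
#' @return A [peptide()].
#' @export
read_peptide_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sequence)) abort(paste0("no 'sequence' field in ", path))
  peptide(cfg$sequence,
          start = cfg$start %||% 1L,
          mods = if (length(cfg$mods)) unlist(cfg$mods) else NULL,
          id = cfg$id)
}

#' Read a set of isobaric isoform definitions from a YAML config
#'
#' The file holds `sequence`, optional `start`, and `isoforms`: a named map of
#' isoform id to a list of `"site:kind:multiplicity"` strings.
#'
#' @param path Path to a YAML file.
#' @return An [isobaric_group()].
#' @export
read_isoform_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sequence) || is.null(cfg$isoforms)) {
    abort(paste0("isoform config needs 'sequence' and 'isoforms' fields: ", path))
  }
  isoforms <- imap(cfg$isoforms, function(mods, id) {
    peptide(cfg$sequence, start = cfg$start %||% 1L,
            mods = unlist(mods), id = id)
  })
  isobaric_group(isoforms)
}
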