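# Theoretical b/y fragment ions, isobaric isoform groups and their
# discriminating "specific ions", and in-silico tryptic digestion with
# methylation-dependent cleavage blocking.

#' Theoretical b/y fragment-ion ladder
#'
#' Generates the complete b and/or y ladders of a modified peptide at charges
#' `1..max_charge`. b(i) covers the first `i` residues, y(i) the last `i`;
#' a fragment inherits every modification whose site lies inside its window.
#' Neutral masses: `b(i) = sum(residues) + mods`, `y(i) = sum(residues) +
#' mods + water`; `mz = (neutral + charge * proton) / charge`.
#'
#' @param p A [peptide()].
#' @param series Character subset of `c("b", "y")`.
#' @param max_charge Maximum fragment charge (>= 1).
#' @return A tibble with columns `series`, `index`, `charge`, `neutral`
#'   (neutral fragment mass, Da), `mz`, and `isoform_id` (the peptide's `id`,
#'   `NA` if unset).
#' @examples
#' p <- peptide("KSAPATGGVKKPHR", 27, c("27:methyl:3", "36:methyl:2"))
#' dplyr::filter(fragment_ions(p), series == "y", index == 13, charge == 2)
#' @export
fragment_ions <- function(p, series = c("b", "y"), max_charge = 2L) {
  stopifnot(inherits(p, "simc_peptide"))
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  if (max_charge < 1) abort("max_charge must be >= 1")
  n <- length(p$residues)
  if (n < 2) abort("peptide too short to fragment")

  res_mass <- .aa_mono[p$residues]
  # per-position modification delta (peptide-local index)
  mod_by_pos <- numeric(n)
  if (nrow(p$mods)) {
    mod_by_pos[p$mods$site - p$start + 1L] <- p$mods$delta
  }
  csum <- unname(cumsum(res_mass + mod_by_pos))
  total <- csum[n]

  idx <- seq_len(n - 1L)
  ladders <- list()
  if ("b" %in% series) {
    ladders$b <- tibble(series = "b", index = idx, neutral = csum[idx])
  }
  if ("y" %in% series) {
    ladders$y <- tibble(series = "y", index = idx,
                        neutral = total - csum[n - idx] + .mass_water)
  }
  lad <- bind_rows(ladders)
  out <- tidyr::crossing(lad, charge = seq_len(max_charge))
  out$mz <- (out$neutral + out$charge * .mass_proton) / out$charge
  out$isoform_id <- p$id %||% NA_character_
  arrange(out[, c("series", "index", "charge", "neutral", "mz", "isoform_id")],
          .data$series, .data$index, .data$charge)
}

#' Group isobaric isoforms sharing one precursor
#'
#' Isobaric isoforms have the same sequence, start position and total
#' modification mass but different site placement, so they are
#' indistinguishable at MS1 and co-isolated for fragmentation. The
#' constructor verifies exact mass equality (within `tol`).
#'
#' @param isoforms A list of [peptide()] objects (>= 2 for specific-ion
#'   discovery); each needs a distinct `id` (list names are used as fallback).
#' @param tol Mass-equality tolerance in Da (default 1e-6).
#' @return An object of class `simc_isobaric_group`.
#' @export
isobaric_group <- function(isoforms, tol = 1e-6) {
  stopifnot(is.list(isoforms), length(isoforms) >= 1)
  ids <- imap(isoforms, function(p, nm) {
    p$id %||% (if (is.character(nm) && nzchar(nm)) nm else NULL)
  })
  if (any(map_lgl(ids, is.null))) abort("every isoform needs an id")
  ids <- unlist(ids)
  if (anyDuplicated(ids)) abort("isoform ids must be distinct")
  isoforms <- map2(isoforms, ids, function(p, id) { p$id <- id; p })
  names(isoforms) <- ids

  seqs <- map_chr(isoforms, "sequence")
  starts <- map_dbl(isoforms, "start")
  if (length(unique(seqs)) != 1L || length(unique(starts)) != 1L) {
    abort("isoforms must share sequence and start position")
  }
  masses <- map_dbl(isoforms, peptide_mass)
  if (diff(range(masses)) > tol) {
    abort(sprintf(
      "isoforms are not isobaric: masses span %.6f Da (> %g Da tolerance)",
      diff(range(masses)), tol))
  }
  structure(
    list(isoforms = isoforms, mass = masses[[1]], sequence = seqs[[1]],
         start = starts[[1]]),
    class = "simc_isobaric_group"
  )
}

#' @export
print.simc_isobaric_group <- function(x, ...) {
  cat(sprintf("<simc_isobaric_group> %s (start %d), %d isoforms, mass %.4f Da\n",
              x$sequence, x$start, length(x$isoforms), x$mass))
  for (id in names(x$isoforms)) cat("  -", id, "\n")
  invisible(x)
}

#' Shared precursor m/z of an isobaric group
#'
#' @param group An [isobaric_group()].
#' @param z Charge state.
#' @return m/z of the common precursor.
#' @export
group_precursor_mz <- function(group, z) {
  stopifnot(inherits(group, "simc_isobaric_group"))
  precursor_mz(group$isoforms[[1]], z)
}

#' Discover isoform-specific fragment ions
#'
#' A `(series, index, charge)` slot is *specific* when the theoretical m/z
#' values across the group's isoforms are not all equal (within `tol` Da):
#' its residue window holds an unequal share of the differing modifications.
#' Specific slots discriminate the isoforms in MS/MS spectra even though the
#' precursors are identical. The slot set is symmetric: it is specific for
#' all isoforms or for none.
#'
#' @param group An [isobaric_group()] with >= 2 isoforms.
#' @param series Character subset of `c("b", "y")`.
#' @param charges Integer vector of fragment charges.
#' @param tol m/z equality tolerance in Da (default 1e-6).
#' @return A tibble of specific ions: `isoform_id`, `series`, `index`,
#'   `charge`, `neutral`, `mz`.
#' @examples
#' grp <- isobaric_group(list(
#'   peptide("KSAPATGGVKKPHR", 27, c("27:methyl:3", "36:methyl:2"), "K27me3-K36me2"),
#'   peptide("KSAPATGGVKKPHR", 27, c("27:methyl:2", "36:methyl:3"), "K27me2-K36me3")))
#' unique(specific_ions(grp, series = "y", charges = 2)$index)  # 5..13
#' @export
specific_ions <- function(group, series = c("b", "y"), charges = 1:2,
                          tol = 1e-6) {
  stopifnot(inherits(group, "simc_isobaric_group"))
  if (length(group$isoforms) < 2) abort("need >= 2 isoforms to find specific ions")
  max_z <- max(charges)
  frags <- list_rbind(map(group$isoforms, function(p) {
    filter(fragment_ions(p, series = series, max_charge = max_z),
           .data$charge %in% charges)
  }))
  frags |>
    group_by(.data$series, .data$index, .data$charge) |>
    filter(diff(range(.data$mz)) > tol) |>
    ungroup() |>
    arrange(.data$isoform_id, .data$series, .data$index, .data$charge) |>
    select("isoform_id", "series", "index", "charge", "neutral", "mz")
}

#' Tryptic cleavage rule
#'
#' Trypsin cleaves C-terminal to lysine and arginine, but not when the next
#' residue is proline. Lysine methylation hinders cleavage progressively:
#' monomethyl-lysine is still cut, di- and trimethyl-lysine are not;
#' acetyl-lysine is treated as blocking as well.
#'
#' @param cleave_after Residues cut after (default `c("K", "R")`).
#' @param block_next Residues blocking when immediately C-terminal
#'   (default `"P"`).
#' @param blocking_k_methyl Minimum lysine methyl multiplicity that blocks
#'   cleavage (default 2).
#' @param acetyl_blocks Whether acetyl-lysine blocks cleavage (default TRUE).
#' @return An object of class `simc_cleavage_rule`.
#' @export
cleavage_rule <- function(cleave_after = c("K", "R"), block_next = "P",
                          blocking_k_methyl = 2L, acetyl_blocks = TRUE) {
  structure(
    list(cleave_after = cleave_after, block_next = block_next,
         blocking_k_methyl = blocking_k_methyl, acetyl_blocks = acetyl_blocks),
    class = "simc_cleavage_rule"
  )
}

# protein-numbered positions after which the rule permits cleavage
.cleavage_sites <- function(p, rule) {
  n <- length(p$residues)
  pos <- which(p$residues %in% rule$cleave_after)
  pos <- pos[pos < n]                       # C-terminus is not a site
  pos <- pos[!(p$residues[pos + 1L] %in% rule$block_next)]
  if (length(pos) && nrow(p$mods)) {
    sites <- p$start + pos - 1L
    blocked <- map_lgl(sites, function(s) {
      m <- p$mods[p$mods$site == s, ]
      if (!nrow(m)) return(FALSE)
      any(m$kind == "methyl" & m$multiplicity >= rule$blocking_k_methyl &
            m$residue == "K") ||
        (rule$acetyl_blocks && any(m$kind == "acetyl"))
    })
    pos <- pos[!blocked]
  }
  p$start + pos - 1L
}

#' In-silico digestion with missed cleavages
#'
#' Enumerates every digestion product whose internal (uncut) cleavage sites
#' number at most `max_missed`. Products inherit the parent's modifications
#' and keep protein numbering, so sites like "K27" stay addressable. The
#' fully cleaved set (`max_missed = 0`) is always a subset of the output.
#'
#' @param p A [peptide()] (a whole protein is just a long peptide).
#' @param rule A [cleavage_rule()].
#' @param max_missed Maximum missed cleavages per product (default 0;
#'   the histone workflow uses up to 5).
#' @return A tibble with columns `start`, `end`, `sequence`, `n_missed`,
#'   and `product` (a list-column of [peptide()] objects).
#' @examples
#' long <- peptide("LATKAARKSAPATGGVKKPHRYRPGTVALREIR", 20,
#'                 c("27:methyl:3", "36:methyl:2"))
#' digest(long)$sequence
#' @export
digest <- function(p, rule = cleavage_rule(), max_missed = 0L) {
  stopifnot(inherits(p, "simc_peptide"), inherits(rule, "simc_cleavage_rule"))
  sites <- .cleavage_sites(p, rule)
  bounds <- c(p$start - 1L, sites, p$end)    # cut points flanking products
  nb <- length(bounds)
  prods <- list()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      n_missed <- j - i - 1L
      if (n_missed > max_missed) break
      prods[[length(prods) + 1L]] <-
        c(start = bounds[i] + 1L, end = bounds[j], n_missed = n_missed)
    }
  }
  out <- as_tibble(do.call(rbind, prods))
  out$product <- pmap(out, function(start, end, n_missed) {
    keep <- p$mods[p$mods$site >= start & p$mods$site <= end,
                   c("site", "kind", "multiplicity")]
    sub <- substr(p$sequence, start - p$start + 1L, end - p$start + 1L)
    peptide(sub, start = start, mods = if (nrow(keep)) keep else NULL,
            id = p$id)
  })
  out$sequence <- map_chr(out$product, "sequence")
  arrange(out[, c("start", "end", "sequence", "n_missed", "product")],
          .data$start, .data$end)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble(name = names(aa), sequence = as.character(aa))
}
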