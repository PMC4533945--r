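---
title: "Quantifying isobaric peptide isoforms from specific fragment-ion chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying isobaric peptide isoforms from specific fragment-ion chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simcquant)
```

## The problem

Bottom-up histone proteomics digests H3 into short peptides and quantifies
each modified form at the MS1 level. That works until two modification
*placements* share one peptide: the tryptic K27-R40 peptide
(`KSAPATGGVKKPHR`) carrying five methyl groups can be K27me3-K36me2 or
K27me2-K36me3. Both isoforms have identical elemental composition, identical
precursor m/z at every charge state (3+ at 501.9755), and essentially
identical reversed-phase retention — they coelute as one peak and are
indistinguishable at MS1. Distinguishing transcription-repressive K27
trimethylation from transcription-activating K36 trimethylation in the *same*
H3 tail therefore needs information from fragmentation.

## The method

CID fragmentation of the co-isolated 3+ precursor produces b/y ladders whose
masses depend on *where* the methyls sit. A fragment covering exactly one of
the two differing sites has different mass in the two isoforms — a
**specific ion**. For the pentamethyl pair these are y5–y13 (covering K36
but not K27) and b1–b9 (K27 but not K36); y13 at charge 2 is 667.3886 for
K27me3-K36me2 versus 674.3964 for K27me2-K36me3, a 7.008 Th split
(one methyl, 14.0157 Da, at charge 2).

Single ion pairs in single scans are unreliable quantifiers:
fragmentation efficiency fluctuates scan to scan. The estimator implemented
here therefore:

1. selects every MS/MS scan acquired on the shared precursor
   (`select_ms2()`, isolation window treated as full width, default 2.0 Th);
2. in each scan matches each theoretical specific ion to the peak with the
   smallest absolute mass error inside the tolerance (10 ppm for
   high-resolution spectra, 0.4 Da for ion traps), with **no**
   signal-to-noise gate;
3. sums the matched specific-ion intensities per isoform per scan, giving a
   per-isoform chromatogram across the elution profile (the specific-ion
   chromatogram);
4. integrates each chromatogram over retention time (trapezoid) and reports
   each isoform's share of the summed areas as its constituent percentage.

Pooling many ions over many scans is what makes the estimate stable: ion- and
scan-level efficiency fluctuations average out, while the common elution
profile cancels in the ratio. Quantification defaults to the y²⁺ series at
charge 2 only, because for a 3+ precursor those are by far the most
efficiently produced fragments; b¹⁺/b²⁺/y¹⁺ are available as diagnostics via
the `series`/`fragment_charges` arguments but are sporadically detected and
quantify poorly.

Absolute context comes from MS1: `sic()` integrates the best-matching
precursor peak per MS1 scan per charge state (1–4+ for K27-R40me5) and sums
the per-charge areas. `relative_abundance()` multiplies the target peptide's
total SIC by each isoform's percentage and normalizes to the SIC of the
constitutive, modification-free H3 peptide D123-R128 (`DIQLAR`, charges
1–2+), so isoform levels are comparable across samples.
`replicate_summary()` reports mean and sample SD over replicate runs.

```{r example}
grp <- h3_k27r40me5_group()
sim <- simulate_run(simulation_config(
  fractions = c(`K27me3-K36me2` = 0.75, `K27me2-K36me3` = 0.25), seed = 42))
q <- simc_quantify(sim$run, grp)
tidy(q)
```

## Tryptic digestion with methylation blocking

Producing K27-R40 in the first place relies on methylation-dependent trypsin
behaviour: trypsin cleaves after K/R except before proline, cuts
monomethyl-lysine, but not di-/trimethyl-lysine (acetyl-lysine is treated as
blocking too — a standard assumption; only the methyl states are documented
behaviourally). `digest()` implements these rules with protein numbering
preserved and missed-cleavage products enumerated explicitly (`max_missed`,
up to 5 in the histone workflow). Consequences the tests verify: the
pentamethylated K27-R40 product appears already in the fully cleaved set
(K27 and K36 blocked, K37 proline-blocked), whereas hypomethylated material
is cut into S28-R40 / K27-K36-type pieces — which is exactly why trypsin
*enriches* highly methylated K27-R40 before quantification. Whether a
"fully digested" expectation should include single-missed-cleavage products
like K27-K36 is left to the caller: `digest()` reports `n_missed` per
product rather than deciding.

## What the simulator emulates — and what it does not

`simulate_run()` exists so that every stage is testable against known truth
without instrument files. Its defaults are fixed descriptions of the
measurement situation, chosen once:

| parameter | default | rationale |
|---|---|---|
| elution | Gaussian, center 13.5 min, sd 0.08 min | single coeluting peak in the observed 13.3–13.8 min window |
| duty cycle | 1 MS1 + 3 MS2 per 0.05 min | data-dependent "top-3" acquisition |
| charge envelope | 1–4+ at 0.05/0.15/0.50/0.30 | 3+/4+ predominant; 3+ is the fragmentation target |
| fragment efficiency | y²⁺ 0.20, y¹⁺/b¹⁺/b²⁺ 0.02 | y²⁺ dominance (~10×); others sporadic |
| y11–13 prominence | ×3 | enhanced cleavage N-terminal of proline |
| per-scan-per-ion jitter | lognormal, σ = 0.30 | per-scan ratio instability; magnitude is qualitative, documented as a free parameter |
| noise | Poisson(20) peaks/scan, uniform m/z 200–1400, exponential intensities at 1% of base | simplest model that exercises smallest-error peak selection |
| m/z error | Gaussian, σ = 2 ppm | well inside the 10 ppm matching window |

The generator records exact bookkeeping (per-scan written specific-ion sums,
per-charge MS1 areas) so recovery is scored against ground truth, not
against itself. `simulate_digest_sample()` prepends in-silico digestion of
longer precursors (the L20-R52 pair standing in for intact H3) and supports
a per-isoform digestion-efficiency skew; a relative yield $s$ applied to one
isoform of a 1:1 mixture moves its expected share to $s/(1+s)$.

Deliberately *not* modelled: isotope envelopes, chimeric co-isolation,
dynamic exclusion, retention-time drift between runs, detector saturation,
and real chromatographic tailing. Passing recovery tests on this generator
therefore demonstrates correctness of the estimator under its stated
assumptions — not instrument-grade performance on biological extracts,
where interference ions within the matching window are the dominant error
source (they bias pure samples below 100%).

## Numerical and design choices

- **Mass scale.** Monoisotopic residue masses at six decimals; water
  18.010565 Da; charging uses the *proton* mass 1.007276 Da — the printed
  3+ value 501.9755 reproduces only with proton charging (hydrogen-atom
  charging would give 501.9771). Methyl 14.015650, acetyl 42.010565,
  phospho 79.966331, oxidation 15.994915 Da per unit.
- **Specificity tolerance.** Two theoretical slot masses are "different" when
  they differ by more than 1e-6 Da — float-safe strict inequality; real
  placement differences are ≥ one methyl per charge.
- **Integration.** Trapezoid over RT in minutes (robust to uneven scan
  spacing); scans with no matched intensity contribute zero-height points. A
  per-scan sum is available (`integration = "sum"`). A single-point trace
  has zero trapezoid area; when signal was observed but total area is zero
  the tally is used instead, with a warning, so observed signal never
  reports as "undefined".
- **Ties.** Equal |mass error| resolves to the higher-intensity peak —
  deterministic and signal-favouring.
- **SIC peak choice.** Best (smallest-error) peak per MS1 scan; summing all
  in-window peaks is available (`mode = "sum"`). The whole run is
  integrated — no RT gating anywhere, matching the whole-elution-profile
  design of the MS2 estimator.
- **Unknown precursor charge.** MS2 scans without a recorded charge are
  excluded by default (the method targets one charge state); a flag includes
  them.
- **Degenerate inputs.** Zero total specific-ion intensity yields `NA`
  percentages and an explicit `undefined` flag, never 0/0; fewer than 6
  contributing MS2 scans or fewer than 22 MS1 trace points trigger stability
  warnings (the scan counts below which chromatogram outlines become
  unreliable).
- **Determinism.** The simulator consumes a private seeded RNG stream and
  restores the caller's; identical config + seed reproduces a run
  byte-for-byte, and the pipeline's JSON report contains no timestamps.

## Problem sizes used in validation

The shipped test suite validates mixture recovery on simulated runs of
~29 MS1 + ~87 MS2 scans over a 1.4 min window, across the mixing series
1:0, 6:1, 3:1, 1:1, 1:3, 0:1 (three seeds each under default noise, plus
noiseless runs, recovered within 3 and 0.1 percentage points respectively);
digestion against an exhaustive cleavage-bitmask oracle on peptides up to
40 residues; and property suites (percentage normalization, label symmetry,
intensity-scale invariance, b/y complementarity, isobaric mass invariance,
specificity-window equivalence) over several hundred randomized cases with
fixed seeds. These sizes give stable statistics at interactive runtimes
while exercising every code path end to end.

## Limitations

- Identification is assumed: candidate isoforms are declared up front; there
  is no database search, localization scoring, or FDR control here.
- Adjacent differing sites leave few specific ions (e.g. hypothetical
  K36/K37 variants retain only y4 and b10), so precision degrades with site
  proximity — the specific-ion count is reported so users can judge.
- MS1 SIC uses single best peaks, not isotope-envelope deconvolution;
  heavily overlapping envelopes would need upstream deconvolution.
- The matching window admits interference ions in complex backgrounds; with
  no signal-to-noise threshold (by design), pure samples report slightly
  below 100%.
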