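---
title: "Methods: T-RFLP fingerprinting and bioenergetics of iron-reducing enrichments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-RFLP fingerprinting and bioenergetics of iron-reducing enrichments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetrflp)
```

## The problem this package addresses

Dissimilatory iron-reducing microorganisms couple the oxidation of simple
carbon substrates to the reduction of Fe(III) (hydr)oxide minerals. Which
organisms come to dominate an enrichment culture depends jointly on the
carbon source offered, on the crystallinity (hence bioavailability) of the
Fe(III) phase — ferrihydrite is readily reduced, goethite less so, hematite
barely — and on how far the inoculating sediment was diluted. A classic,
inexpensive way to fingerprint dozens of such enrichment communities is
terminal restriction fragment length polymorphism (T-RFLP): the 16S rRNA
gene is amplified with fluorescently labelled primers at both ends, digested
with restriction enzymes, and the lengths of the labelled terminal
fragments (T-RFs) are read on a capillary sequencer. Each phylotype leaves a
characteristic set of fragment lengths; peak areas proxy relative
abundance.

`fetrflp` implements the full analysis chain for such an experiment:

1. **In silico digestion** (`locate_amplicon()`, `terminal_fragment()`,
   `trf_signature()`, `digest_phylotypes()`) predicts, for a clone
   sequence, the six T-RF lengths produced by three enzymes (MspI `C^CGG`,
   HhaI `GCG^C`, HaeIII `GG^CC`) at the two labelled ends.
2. **Peak processing** (`export_window()`, `denoise_peaks()`,
   `consensus_duplicates()`, `bin_peaks()`) turns raw electropherogram peak
   tables into a relativized samples-by-bins matrix.
3. **Taxon assignment** (`match_signature()`, `assign_bins()`,
   `collapse_groups()`, `build_community_matrix()`) assigns bins to
   phylotypes only when all six slots of the in silico signature are
   corroborated ("six of six"), collapses phylotypes into taxon-group bins
   and tracks the unassigned area as an explicit unknown fraction.
4. **Community statistics** (`bray_curtis()`, `upgma()`,
   `cophenetic_correlation()`, `cut_dendrogram()`, `kruskal_wallis()`)
   quantify between-enrichment dissimilarity and its structure.
5. **Geochemistry and bioenergetics** (`percent_reduced()`,
   `select_reduced()`, `delta_g_prime()`) select actively iron-reducing
   enrichments and rank candidate electron-accepting pathways
   thermodynamically.
6. A **synthetic-data generator** (`plant_signature()`,
   `generate_community()`, `synthesize_profiles()`, `generate_fe_grid()`,
   `simulate_study()`) produces sequences, electropherograms and Fe
   chemistry grids with known ground truth, under full seed control.

Everything is tibble-in/tibble-out and pipeable; `run_trflp_pipeline()`
orchestrates an end-to-end run with per-stage files and a manifest.

## Coordinate and measurement conventions

Sequence coordinates are 0-based and half-open; fragment lengths are
integer base pairs and *include* the labelled primer (the label sits on the
primer's 5' end, so capillary sizing reports primer-inclusive lengths — the
magnitudes in published clone tables are only consistent with this
convention). For the forward label the fragment is the 0-based start of the
first recognition-site occurrence plus the enzyme's cut offset; for the
reverse label the same computation runs on the reverse complement. A
missing recognition site yields the no-cut sentinel (`NA`). Because all
three recognition sequences are palindromic, a cut site always produces a
fragment at *both* labelled ends — a fact with consequences for signature
planting (below).

The default primers are the near-full-length pair 8F
(`AGAGTTTGATCCTGGCTCAG`) and 1492R (`GGTTACCTTGTTACGACTT`); both are
matched IUPAC-aware with a configurable mismatch allowance (default 0,
appropriate for synthetic sequences). The 1492R literal is the common
published sequence for that primer name; nothing in the package depends on
the exact literal, and fixtures are built through the same primer object
they are digested with.

## Peak processing choices

* **Export window** 50-550 bp, bounds inclusive: outside the size-standard
  range fragment sizing is unreliable. Library slots printed as `<50`
  (below window), as `NC` (no cut), or as numeric values outside the
  window are all treated as *categorically unobservable* during matching —
  the instrument cannot distinguish them.
* **Signal/noise discrimination** follows the iterative zero-mean
  threshold family of procedures: relativize areas, compute the standard
  deviation of areas about zero over peaks not yet flagged as signal, flag
  peaks above `k` sigma (default `k = 3`), and repeat on the shrinking
  noise pool until nothing new is flagged. The published descriptions of
  this family leave the variant ambiguous (areas vs heights, deviation
  about zero vs about the mean); we fix areas and deviation about zero,
  with `k` configurable. Two guards: profiles with fewer than three peaks
  pass through unchanged, and when the first pass flags nothing the whole
  profile is retained rather than discarded — otherwise a low-diversity
  profile of a few near-equal true peaks (where the dominant peak can
  never exceed `3*sqrt(mean(a^2))` for small n) would be annihilated. A
  consequence worth knowing: with fewer than about ten peaks the first
  pass cannot flag anything, so tiny profiles are effectively passed
  through whole and later cleaned by the duplicate-consensus step.
* **Duplicate consensus**: each replicate digest is relativized first
  (correcting for injected-DNA differences), peaks are matched greedily
  nearest-first within 0.5 bp, matched peaks keep mean size and mean
  relative area, unmatched peaks are discarded, and the consensus is
  re-relativized. The order relativize -> average -> re-relativize is one
  consistent reading of "discard and average"; averaging raw areas first
  would let the better-injected replicate dominate.
* **Binning** pools consensus peak sizes over samples within each digest
  and chains them by single linkage with a 1.0 bp gap; ties are processed
  in ascending size order. Single-linkage chains can grow wider than the
  gap (documented behaviour, tested explicitly). For that reason the bin
  table carries both the global bin centre and each sample's own mean
  member size, and signature matching uses the latter.

## Six-of-six assignment

Published practice assigned T-RFs to phylotypes manually when six of six
peaks matched the in silico digestion. The codified rule: a library entry
matches an observed signature only if every slot agrees — numeric in-window
slots within `tol` (default 1.0 bp, the capillary sizing error scale),
unobservable slots categorically. How the six electropherograms of one
sample were paired into a single observed signature is not part of the
published record; our reconstruction is presence-based: an entry can
explain a fingerprint bin only if each of its other five in-window slots
has a peak within `tol` in the sample's corresponding consensus profile.
This is conservative — one missing companion peak vetoes the assignment —
and it cannot distinguish co-occurring taxa that share a slot value, which
is precisely why the fingerprint digest's bin, not the companions, carries
the abundance.

Ambiguity handling: among several matching entries the nearest by summed
absolute slot deviation wins; an exact tie across different group labels is
left unassigned with a warning. An exact tie *within* one group resolves to
that group, because real clone tables contain phylotypes with identical
six-slot signatures in the same genus-level bin (several *Aeromonas*
clones, two *Serratia*/*Klebsiella* rows) and a strict tie-to-unknown rule
would make such libraries unusable.

## Community statistics

Bray-Curtis dissimilarity (`sum|x_i - y_i| / sum(x_i + y_i)`, computed via
`vegan::vegdist`; a pair of all-zero profiles is defined as 0),
average-linkage (UPGMA) clustering via `stats::hclust`, cophenetic
correlation as the Pearson correlation between input and cophenetic
dissimilarities, and dendrogram cutting at a chosen dissimilarity (0.7 is
the conventional community-delimiting height here). The test suite checks
UPGMA and its cophenetic matrix against an independent brute-force
implementation that recomputes cluster means by explicit member
enumeration. When two merge candidates tie exactly, `hclust`'s tie order
decides the tree *shape*; heights — and thus everything this package reads
off the tree — are tie-invariant. The Kruskal-Wallis test is applied per
taxon group: relative abundances grouped by an experimental factor (carbon
source, mineral). The published analysis does not state the exact response
variable passed to its rank test, so both per-group abundances and cluster
memberships can be used; the pipeline reports the former.

## Thermodynamic calculations

For a balanced reaction the activity-corrected energy yield is

```
yield = -(dG0 + RT ln Q) / n_basis     [kJ per mol electron donor]
```

with `dG0` from standard Gibbs formation energies (25 C), `Q` the reaction
quotient with molar concentrations as activities (no ionic-strength
correction — the bracketed millimolar concentrations typical of enrichment
media make activity coefficients a second-order concern), `10^-pH` for the
proton, and unit activity for solids and water. Favorable reactions are
reported as positive yields, the sign convention of the enrichment
literature this package accompanies. Reactions are validated for element
and charge balance against a built-in composition table before evaluation.

The shipped compilation (`thermo_table()`, editable YAML) uses the
Thauer/Stumm-Morgan lineage of constants: goethite -488.6, Fe2+ -78.9,
acetate -369.4, lactate -517.8, bicarbonate -586.9, water -237.2, sulfate
-744.6, HS- +12.1 kJ/mol. At the enrichment conditions (pH 7.3, acetate
10 mM, Fe2+ 5 uM, bicarbonate 10 mM for the acetate couple; lactate 10 mM,
acetate 1 uM, sulfate 200 uM, HS- 1 uM in addition for the lactate
couples) these give approximately +1.7 kJ/mol acetate for acetate/goethite
— thermoneutral, explaining why acetate supports no reduction of
crystalline oxides — and +86.5 kJ/mol lactate for lactate/goethite.

For lactate/sulfate the same table and conditions give +121.8 kJ/mol
lactate. This value is sensitive to the treatment of the half mole of
protons the reaction produces: assigning that proton its ambient activity
(`10^-7.3`), as thermodynamic consistency requires and as this package
does, contributes about -21 kJ relative to leaving it at unit activity.
Reported literature values near +101 kJ/mol for this couple under these
conditions are reproducible only under the unit-activity reading (or a
different constant set); we keep the consistent treatment and document the
~20 kJ spread. Either way the qualitative ranking that matters — sulfate
reduction outcompetes goethite reduction for lactate even at 200 uM
sulfate — is robust. An internal consistency check verifies that the
lactate/goethite energy equals lactate/sulfate plus half the
sulfide-reoxidation-by-goethite energy within one table, so the ranking
does not depend on how the reactions are decomposed.

## The synthetic-data generator

The generator defines the study conditions the package is validated under.

* **Signature planting** (`plant_signature()`) inverts digestion: given a
  six-slot target it writes the primers, places each enzyme's first and
  last recognition sites at the positions the target dictates, fills the
  background uniformly over A/C/G/T while scrubbing accidental recognition
  sites (occurrences between an enzyme's first and last planted sites are
  harmless and left alone), and verifies by re-digesting. Infeasible
  targets fail constructively: one numeric and one no-cut slot for the
  same palindromic enzyme, sites colliding with primers, or overlapping
  sites demanding contradictory bases (the printed 210/210 MspI+HaeIII
  forward pair of one Spirochaetes clone is a real example). Background
  composition is uniform by design — the guarantee is signature
  correctness, not biological realism.
* **Communities** are symmetric Dirichlet draws (`concentration = 1`,
  uniform on the simplex) over per-carbon taxon pools; noise parameters
  default to 30 spurious peaks per profile with exponential areas of mean
  0.5% of the signal (the zero-mean sigma statistic needs a realistic
  noise floor to behave as it does on real traces; the 30-600 bp noise
  range deliberately overhangs the export window on both flanks), 0.1 bp
  replicate size jitter (capillary sizing precision), and a 0.001 per-peak
  per-replicate dropout probability — detectable peaks essentially always
  reproduce in duplicate digests of the same amplification; the dropout
  knob exists to let users stress the consensus rule, and it is the
  mechanism behind the few-percent recovery losses the end-to-end tests
  tolerate.
* **The structured study** (`simulate_study()`) emulates a 3 carbons x 3
  minerals x 5 dilutions selection experiment: 45 samples, each carbon
  source enriching its own three-group pool, duplicate digests for all
  six enzyme/label combinations. Pool members were chosen so their
  fingerprint fragments do not share single-linkage bins across pools;
  with a shared bin (e.g. two clones at 492 and 493 bp MspI) enrichments
  on different carbon sources can legitimately merge below the 0.7 cut —
  worth remembering when interpreting real data, where such collisions are
  exactly what the six-of-six rule guards against.
* **The Fe grid** (`generate_fe_grid()`) draws, per mineral x carbon
  combination, an amplitude from its documented range and shapes it over
  dilutions 10^-1..10^-5: `decreasing` for ferrihydrite (acetate amplitude
  84-88%), `unimodal_at_third` for crystalline oxides with fermentable
  substrates (56-67% on goethite; the first two glucose dilutions sit at
  ~30% of amplitude, emulating the moderate 18-21% shoulder), `flat_low`
  (<= 6%) for acetate on goethite/hematite. Duplicate measurements get
  additive Gaussian noise (sd 2 percentage points, truncated to [0, 100]);
  `flat_low` series are additionally capped at their amplitude ceiling,
  which that tag defines as an upper bound on observable reduction.
  Inter-dilution steps exceed 15 percentage points, so the 2-point noise
  cannot invert the shapes. Total Fe is fixed at 25 mM.

**What passing tests do and do not show.** The generator plants exact
signatures into compositionally unstructured sequences, uses flat dropout
and Gaussian jitter, and keeps carbon pools disjoint. Passing the
end-to-end tests therefore demonstrates that the pipeline's logic is
correct and its thresholds mutually consistent — not that real sediment
communities will be recovered at these rates. Real data add pseudo-T-RFs,
partial digestion, size-calling bias against long fragments, phylogenetic
correlation between signatures and overlapping taxon pools, none of which
are modelled; size-standard fitting is upstream of this package entirely.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; identical seeds give
bit-identical outputs throughout, and the pipeline manifest echoes the seed
and every parameter. The test suite exercises the round-trip property on
500 random feasible targets, digestion against a brute-force scan oracle on
sequences up to 2 kb, clustering against a brute-force UPGMA oracle on 100
random matrices (n <= 8), and two full 45-sample studies; it completes in a
few minutes on one CPU. These sizes were chosen to keep property tests
routine to run while matching the scale of the emulated experiment (45
fingerprinted enrichments, 120-enrichment chemistry grid).

## Known limitations

* Assignment confidence is binary (six-of-six or unknown); no
  probabilistic fragment-size model.
* The empirical-signature pairing across digests is a reconstruction of
  undocumented manual practice (conservative by design).
* Thermodynamics uses concentrations as activities and a fixed 25 C; no
  ionic-strength or temperature corrections, no mineral surface-energy
  terms (bulk goethite free energy only).
* The generator does not model inter-replicate dilution offsets between
  duplicate enrichments, nor fluorescence physics of detection.
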