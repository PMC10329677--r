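---
title: "Identifying intact glycopeptides: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying intact glycopeptides: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscout)
```

# The problem

An intact glycopeptide couples two unknowns in one tandem mass spectrum: a
peptide backbone (fragmenting into b/y or c/z ions) and a glycan tree
attached at a glycosylation site (fragmenting at glycosidic bonds into B
ions — oxonium ions of the detached subtree — and Y ions — the peptide
retaining a root-containing subtree). Either ion series can be weak, so
glycoscout searches in two complementary directions and controls error at
both the peptide and the glycan level.

All masses are monoisotopic and derived from atomic masses; the five
monosaccharide classes are Hex, HexNAc, Fuc, NeuAc and NeuGc, with residue
masses `r paste(sprintf("%s %.3f", MONO_CODES, MONO_MASS), collapse = ", ")`
Da.

# Spectrum triage

A spectrum is treated as a glycopeptide spectrum when it shows glycan
signature ions — the nine oxonium masses of `signature_ions()` — or a
Y-ion ladder (three or more peaks spaced by HexNAc/Hex/Fuc residue
masses):

* one signature ion with relative intensity at least 5% of the base peak, or
* at least two signature ions at any intensity, or
* at least one ladder run.

Everything else is searched as a plain peptide spectrum. Two details are
under-determined by the rule as usually stated and are fixed here as
documented choices: *relative intensity* is measured against the base
peak (not the total ion current), and *continuous* ladder peaks means
consecutive within the matched run — unrelated peaks may lie in between.
Both triage tolerances default to 0.02 Da.

# The staged search

1. **Peptide-based search.** Putative glycan peaks (signature ions,
   ladder runs) are removed, and candidate peptides are scored on
   backbone ions at the lower end of the spectrum — below the peptide
   mass plus two HexNAc — including b/y + HexNAc stubs, ammonia/water
   losses and doubly charged states. For each peptide passing the score
   floor, the glycan mass is the neutral precursor minus the peptide
   mass, and glycans are fetched from the database within the precursor
   tolerance (10 ppm default).
2. **Glycan-based search.** If stage 1 identifies nothing, the
   direction is reversed: for each database glycan the peptide mass is
   inferred from the precursor, peptides are fetched by mass, and the
   glycopeptide Y-ion series (charges 1–2, 20 ppm) is matched.
3. **De novo sequencing** (N mode): when the peptide is confident but no
   database glycan fits the mass, the glycan is reconstructed from the
   spectrum (below).

Candidates from both stages are pooled, deduplicated and rescored with
the comprehensive ion set (second-round scoring); the stage fall-through
criterion — "cannot be identified" — is an empty list of candidates with
a peptide score above `min_peptide_score` (default 1.0).

## Surrogate scores

The trained scorers used by the commercial engines this design follows
(a linear discriminant for peptides, a boosted-tree regressor for
glycans) have unpublished coefficients. glycoscout ships documented
fixed-form surrogates with the same qualitative contract:

* **Peptide score** — `sum(log2(1 + relative intensity))` over matched
  theoretical ions plus `0.5 ×` the matched fraction of the primary
  series. Deterministic, non-negative, strictly increasing in matched
  evidence, invariant to global intensity scaling.
* **Glycan score** — a fixed-weight combination of five features of the
  Y/B evidence: 0.4 × fraction of theoretical Y ions observed, 0.2 ×
  min-max-normalised log10 summed matched-Y intensity, 0.2 × an
  indicator that the five N-core Y ions are all observed, 0.1 × fraction
  of B ions observed, 0.1 × matched-Y count capped at ten. The weights
  are defaults, not claims; a trained regressor with the same signature
  can replace them.

Candidates are ranked by `peptide_score + glycan_weight × glycan_score`
(default weight 10, so a fully supported glycan outweighs a handful of
backbone ions).

# Two-level FDR

Peptide-level error uses classical target–decoy competition: one decoy
per target protein, shuffled within enzymatic segments with the cleavage
residue kept in place so decoy peptides stay tryptic and iso-distributed
in mass. Glycan-level error cannot use shuffled glycans (trees do not
shuffle the way strings do), so each glyco-triaged spectrum is paired
with a **decoy spectrum** in which every fragment peak is shifted by an
independent uniform draw of 3–30 m/z (random sign, per peak — per-peak
shifting destroys ladder structure more thoroughly than a single global
shift). Decoy spectra take the *identical* search path as targets; they
are routed directly into the glyco branch because that is where their
paired targets were triaged.

FDR at a threshold is the decoy/target count ratio, converted to a
monotone q-value; at equal scores decoys sort first (conservative). A
glycoPSM passes the joint filter only if both its peptide q-value and
its glycan q-value are at or below the configured level (1% default).
Known limitation, inherited from the decoy-spectrum approach: false
matches to glycans sharing many fragment ions can be underestimated.

# Site and structure confidence

* **A-score**: when a peptide admits several sites, each site is scored
  by its site-determining internal ions — backbone ions carrying either
  the glycan root residue or the intact glycan (series per fragmentation
  scheme). The A-score is `-10·log10(P)` with `P` a binomial tail: `n`
  determining ions unique to the best site vs the runner-up, `k` of them
  matched, and a chance-match probability per ion taken from the local
  peak density (peaks within ±100 m/z × twice the tolerance / 200,
  capped into `[1e-4, 0.5]`). A single-site peptide is a forced
  assignment and scores exactly 1000. An A-score of 42.89 corresponds to
  a chance probability below 1 in 15,000.
* **S-score**: among same-composition candidate structures,
  `(top − second) / top` of the glycan scores; defined as 1 when only
  one candidate exists (documented convention; undefined, reported
  missing, when the top score is not positive).

# De novo glycan reconstruction

## Composition by dynamic programming

The glycan-mass interval `[0, precursor − peptide]` is discretised into
bins of width 0.01 Da. Peaks above the peptide mass (potential Y ions,
singly charged interpretation) deposit their intensity into bins; a
table `T` starts at 0 in bin 0 and `-Inf` elsewhere, and each bin takes
its intensity plus the best reachable predecessor one residue mass away
(±1 bin, which absorbs the rounding drift of long residue chains — up to
~0.3 bins per Hex). Empty bins stay traversable at zero reward, so a
composition can bridge Y-ion gaps; the documented consequence is that a
composition can be completed across missing ions without support. The
maximum-intensity path from the final bin (the exact bin or its lower
neighbour, whichever is reachable and better) is traced back and its
residues are the composition. The table fill is implemented in C++; a
brute-force oracle over all residue orderings on the same lattice checks
it exactly in the tests.

## Tree construction by beam search

The tree grows from the peptide attachment point. The extension
vocabulary has exactly 21 candidates: the 20 non-empty multisets of at
most two residues over the five classes, plus a termination token that
closes the current node (attaching two residues at once creates a
branch). The frontier advances in breadth-first order; out-degree is
capped at 4 (beyond biological branching in curated N-glycan
databases). Each partial tree is scored by fragment evidence — the
exponential activation `exp(-|Δm/z|·c)` with `c = 100` per Da — and the
top `beam_width = 5` *distinct partial trees* survive each iteration.
Only complete trees using exactly the DP composition are emitted.

Three engineering choices in the default scorer deserve an explanation,
because each one was forced by an identifiable failure mode of the naive
"sum of matched-intensity activations":

* **Single-residue and signature-mass B ions are excluded.** Oxonium
  ions at single-residue masses (and at the ubiquitous Hex+HexNAc 366
  signature) are present in essentially every glycopeptide spectrum and
  carry no topology information; scoring them systematically rewards
  topologies with matching terminal residues.
* **Intensity enters with weight `(1 + relative intensity)/2`** rather
  than the raw relative intensity, so an observed low-intensity fragment
  always adds evidence; a raw weight makes the scorer prefer rivals that
  simply avoid predicting genuinely present but weak fragments.
* **A miss penalty of 0.1 per unsupported theoretical ion** breaks the
  structural tie between the true topology and any rival predicting a
  superset of its observed fragment masses (a pure sum never penalises
  over-prediction).

Each beam iteration attaches exactly one residue group, with
terminations replayed implicitly (a group may attach at any open node
reachable by closing the nodes before it in breadth-first order). This
keeps serial construction paths and branching paths synchronized: an
earlier design in which termination consumed an iteration starved
deep-chain topologies out of the beam.

The scorer is pluggable (`beam_search(scorer = ...)`): a trained
structure-aware model — the role the original design gives to a graph
transformer plus a point-cloud fragment network — can replace the
fragment-evidence default without touching the search. Training pairs
for such a model are generated by `training_pairs()`, the deterministic
reverse-construction trace (children sorted canonically, chunked in
groups of two, each node closed by a termination token) whose forward
replay through `extend()` rebuilds the tree exactly.

De novo is restricted to N-linked spectra; O-linked de novo remains out
of scope. Compositions beyond 16 residues are not attempted (runtime
guard). De novo trees identified on *target* spectra at the FDR filter
can be appended to the glycan database for a second-round search
(`second_round_rescue()`); decoy-spectrum de novo products are a
by-product of the symmetric decoy path and are never promoted.

# O-linked peptides

O mode uses the S/T sequon, allows at most two glycans per peptide, and
enumerates candidate glycan *pairs* whose summed mass fits the
precursor. A pair is scored by cleaving one glycan while the other stays
intact on the peptide (the average of the two single-glycan scores at
shifted anchor masses); site localization uses the first glycan's tree.
This is a deliberately minimal treatment — the combinatorics of
simultaneous fragmentation of two glycans are not modelled.

# Quantification

A glycopeptide's abundance is the sum of its MS1 precursor feature areas
across charge states, read from a feature TSV (feature detection itself
is upstream engine territory and out of scope) or, as a fallback,
integrated trapezoidally from an MS1 trace (`xic_area()`). Per
glycosylation site, areas pool over all carrier glycopeptides (e.g.
missed-cleavage variants) and normalise to fractions that sum to one.
Normalisation is per site and per run; cross-replicate normalisation is
deliberately not defined here.

# The synthetic world

`simulate_dataset()` generates proteins, glycan databases and spectra
with known ground truth so that every stage is testable offline. The
defaults state one fixed world, chosen once:

* tryptic-like proteins (cleavage residue every 6–14 positions, an
  N-sequon in ~60% of segments) so glyco-candidates exist at any scale;
* glycans grown on the HexNAc2Hex3 core with class weights 0.45 Hex /
  0.30 HexNAc / 0.10 Fuc / 0.10 NeuAc / 0.05 NeuGc, 5–9 residues;
* per-ion emission probabilities 0.9 (backbone and Y), 0.7 (B), 1.0
  (oxonium signature); log-normal intensities with boosted oxonium ions;
  30 uniform noise peaks; 5 ppm Gaussian mass error; precursor charges
  2–4. These describe a clean, well-fragmented Orbitrap-like HCD run.
* `noise_free_spec()` sets coverage 1 / noise 0 / error 0 / constant
  intensity, making the spectrum equal its theoretical peak set — the
  oracle regime for search and de novo tests.

The generator emulates fragment-ion structure only: no chromatography,
co-isolation, isotope envelopes or profile peaks. A green test on this
world establishes algorithmic correctness, not instrument-level
performance. The entrapment design mirrors the classic audit: spectra
come only from species-A proteins and Fuc/NeuAc/NeuGc-free
(high-mannose-like) glycans, while the searched databases also contain
an equal species-B proteome and sialylated/fucosylated glycans; any
accepted hit in the entrapment sets is a known false positive, so the
realized error rate can be compared with the reported FDR.

Withholding glycans for de novo/rescue tests is composition-level: a
same-composition structure left in the database would absorb the
withheld spectra by mass alone.

# Numerical conventions and degenerate inputs

* Tolerances: 10 ppm precursor, 0.05 Da backbone fragments, 20 ppm
  glycan fragments, 0.02 Da triage, 0.01 Da DP bin width — all
  configurable in `search_config()`.
* Ties: decoys sort above targets at equal score (conservative FDR);
  beam states and candidate tables break ties by canonical key (radix
  order), making every ranking deterministic.
* Spectra with no peaks, empty digests, compositions of mass zero and
  single-candidate S-scores all have defined, tested behaviour rather
  than errors.
* All randomness (decoy generation, simulation) is seed-derived;
  `search_dataset()` is byte-identical across runs with the same seed.

# A worked example

```{r example, eval = FALSE}
sp  <- noise_free_spec(seed = 3, n_proteins = 6, n_glycans = 8)
ds  <- simulate_dataset(sp, n_spectra = 20)
cfg <- search_config(mods = mod_spec(variable = NULL))
res <- search_dataset(ds$spectra, ds$proteins, ds$glycan_records, cfg,
                      seed = 3)
res
merge(res$psms[res$psms$passes_fdr, ], ds$truth, by = "spectrum_id")
```

# Known limitations

* The surrogate scores are stand-ins: absolute score values are not
  comparable to any trained engine, only their orderings are meaningful.
* Internal (doubly cleaved) glycan fragments and cross-ring fragments
  are not modelled; linkage and anomeric configuration are ignored
  (including in the GlycoCT reader).
* Quantification consumes precomputed feature areas; there is no LC
  feature detection, match-between-runs or isotope deconvolution.
* Decoy-spectrum FDR can underestimate false matches among glycans with
  heavily shared fragment ions.
* O-linked pair handling is mass-driven and approximate, as described
  above.
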