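# glycoscout

Identification, de novo sequencing and site-specific quantification of
intact glycopeptides from centroided MS/MS spectra, in R.

Glycosylation attaches branched carbohydrate trees (glycans) to specific
protein sites; an intact glycopeptide spectrum therefore mixes two
fragment languages — peptide backbone b/y (or c/z) ions and glycan B/Y
ions from glycosidic cleavage. glycoscout is for computational
proteomics researchers who need a transparent, fully scriptable engine
for this problem: it triages glycopeptide spectra by oxonium signature
ions and Y-ion ladders, identifies them with complementary
peptide-based and glycan-based database searches, controls error
separately at the peptide level (shuffled-protein decoys, Eq. below)
and the glycan level (mass-shifted decoy spectra), scores site
assignments (A-score) and structure assignments (S-score), reconstructs
glycans absent from the database by dynamic programming plus beam
search, and turns MS1 feature areas into per-site glycan profiles.

The core quantities:

- peptide FDR = #(glycoPSMs with decoy peptides) / #(glycoPSMs with
  target peptides); glycan FDR = #(glycoPSMs with decoy spectra) /
  #(glycoPSMs with target spectra). A glycoPSM passes the 1% filter
  only if **both** are ≤ 1%.
- S-score = (top − second) / top over same-composition glycan scores.
- A-score = −10·log₁₀ P, with P a binomial tail over site-determining
  internal fragment ions; a peptide with a single candidate site scores
  1000 by convention.
- De novo composition: a table over the glycan-mass interval (bin width
  = 0.01 Da tolerance), `T[m] = Intensity[m] + max T[m − m_mono]` over
  the five monosaccharide residue masses, traced back from the
  precursor−peptide mass; tree reconstruction then applies 21 extension
  candidates (20 multisets of ≤2 residues + a termination token) under
  a width-5 beam scored by the fragment activation `exp(−|Δm/z|·c)`.

A synthetic-data module generates proteins, glycan databases and
spectra with known ground truth (including two-species / impossible-
monosaccharide entrapment designs for FDR audits), so the whole engine
is testable offline.

## Worked example

```r
library(glycoscout)

sp  <- noise_free_spec(seed = 3, n_proteins = 6, n_glycans = 8)
ds  <- simulate_dataset(sp, n_spectra = 20)
cfg <- search_config(mods = mod_spec(variable = NULL))
res <- search_dataset(ds$spectra, ds$proteins, ds$glycan_records, cfg,
                      seed = 3)
res
#> <glyco_search_result>
#>   glyco spectra: 40 (peptide-based 22, glycan-based 0, de novo 4, unidentified 14)
#>   native spectra: 0
#>   glycoPSMs passing 1% joint FDR: 20
```

All 20 target spectra are identified through the peptide-based stage
and pass the joint 1% FDR filter. The other 20 "glyco spectra" are the
paired decoy spectra, searched through the identical code path: most
stay unidentified or produce low-scoring de novo attempts, and none
pass the filter — that is what a calibrated decoy looks like. Comparing
with the generating truth:

```r
m <- merge(res$psms[res$psms$passes_fdr, ], ds$truth, by = "spectrum_id")
sum(m$sequence.x == m$sequence.y & m$glycan_key == m$key)
#> [1] 20
```

Every PSM row carries the peptide and glycan scores, both q-values, the
localized site with its A-score (1000 for single-sequon peptides), and
the S-score against same-composition alternatives.

A thin command-line wrapper is available at `exec/glycoscout`
(`simulate`, `search` and `denovo` subcommands over MGF/mzML, FASTA and
the glycan tree dialect / GlycoCT subset).

## Acceptance script

`scripts/acceptance.R` rebuilds the desk-scale acceptance quantity from
scratch against the installed package — it simulates a glycopeptide
whose peptide contains exactly one N-sequon, runs the full search, and
reports the site-localization score of the resulting glycoPSM:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette
(`vignettes/glycopeptide-identification.Rmd`) describes the models, the
surrogate scoring functions and their rationale, the synthetic world and
its limits, and the numerical conventions.
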