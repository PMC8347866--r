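---
title: "Profiling beta-casein phosphorylation and O-glycosylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling beta-casein phosphorylation and O-glycosylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casoform)
```

## The problem

Human milk beta-casein is heavily post-translationally modified: an
N-terminal Ser/Thr cluster carries zero to five phosphate groups, and the
C-terminal region — which also spawns the endogenous "ladder" peptides of
the milk peptidome — carries mucin-type core 1 O-glycans. Quantifying how
site occupancy of these modifications changes over lactation requires
stitching together three levels of mass-spectrometric evidence:

1. **Intact level** — deconvoluted neutral masses of the whole protein,
   annotated as proteoforms (which combination of modifications a mass
   corresponds to);
2. **Bottom-up level** — peptide-spectrum matches (PSMs) from proteome
   (tryptic) and peptidome (endogenous) runs, curated and counted per
   modification site;
3. **MS1 level** — integrated precursor areas of peptidoforms, used to
   cross-validate the PSM counting.

`casoform` implements this protein-specific pipeline for beta-casein, plus
a seeded simulator that generates each input with known ground truth so
every stage can be validated end to end without raw data.

## Mass model

Masses are computed incrementally from frozen residue tables: the neutral
peptide mass is the sum of residue masses plus one water, plus modification
deltas — phosphorylation (+79.966331 Da mono), methionine oxidation
(+15.994915 Da, bookkeeping only) and compositional glycans. Glycans are
multisets over four monosaccharide classes, written in the field's
letter-count notation (`N` = HexNAc +203.079373, `H` = hexose +162.052824,
`F` = deoxyhexose +146.057909, `S` = NeuAc +291.095417; e.g. `"N1H1"` for
the core 1 disaccharide). Two deliberate simplifications:

* **Compositional, not structural, glycans.** Isomeric monosaccharides
  (GalNAc vs GlcNAc) and linkage are indistinguishable by the mass-based
  evidence this pipeline consumes, so compositions are the unit of
  identity.
* **Two mass scales.** Monoisotopic masses serve isotopically resolved
  (high-resolution) data, average masses unresolved (low-resolution) data.
  Both tables are elemental sums frozen to six decimals; the test suite
  re-derives them independently from atomic masses and requires agreement
  to 1e-4 Da (mono) / 1e-2 Da (avg) on random modified peptides.

All coordinates are 1-based precursor numbering (signal peptide = 1-15,
mature chain = 16-226), because the literature's site labels (Thr18 ...
Ser225) include the signal peptide. Site positions are configuration, not
constants: the C-terminal glycosite is labelled Thr207 here, and position
208 is His in the printed C-terminal sequence, but the site vector is a
plain named-integer argument everywhere.

## Proteoform library

`enumerate_proteoforms()` crosses phosphorylation counts 0-5 with
order-insensitive multisets of 0-2 O-glycans drawn with repetition from a
nine-composition core 1 catalog, giving 6 x 55 = 330 proteoforms. Choices:

* **Count, not sites, at the intact level.** A deconvoluted mass cannot
  localize a phosphate, so library entries encode `nP` only.
* **Repetition allowed.** Two sites can carry the same glycan species, so
  glycan multisets are combinations *with* repetition.
* **The catalog is a default, not a truth.** Only the catalog's *size*
  (nine core 1 compositions) is well determined; the default set
  {N1, N1H1, N1F1, N1H1F1, N1H1S1, N1H1S2, N1H1F1S1, N1S1, N2H2} is the
  package's documented choice and should be confirmed or overridden per
  study.

## Intact annotation

Deconvoluted features (mass, retention time, intensity) are annotated in
two passes with the windows `mass_tol` = ±1 Da and `rt_tol` = ±1 min:

1. **Database pass** (`match_to_prsm`): a feature within both windows of a
   proteoform-spectrum-match record takes that identification
   (`method = "database"`); the nearest mass wins and the in-window
   candidate count is kept as `ambiguity`.
2. **Theoretical pass** (`match_to_library`): remaining features matching
   a library mass are accepted only if they elute within ±1 min of at
   least one database-annotated feature in the same run — the RT gate that
   keeps stray masses from being named. Database annotation always
   pre-empts theoretical annotation.

Numerical choices: ties on |mass error| prefer fewer total modifications,
then the lexicographically smaller label (parsimony); window boundaries
are inclusive; high-resolution features match monoisotopic library masses
and low-resolution features average masses; the RT gate anchors on *any*
identified feature by default (`rt_gate = "any"`), with a stricter
`"same_backbone"` mode restricting anchors to the same phospho count.
Annotated intensities are normalized to the per-run total of annotated
features so proteoform profiles sum to one; an all-zero intensity vector
is rejected as degenerate rather than silently propagating NaN. This is a
single-protein pipeline by design — protein assignment of a feature is not
a problem it attempts to solve.

## PSM curation and plausibility flags

`curate_psms()` applies the removal rules in a fixed order — signal
peptide (`start < 16`), decoy, `|log Prob| < 1.5`, `score < 150`,
`delta_mod <= 5` — and attributes each removed row to the *first* failing
rule, so rejection logs are reproducible and kept + rejected = input
always. The score thresholds are inclusive; the Delta Mod gate is strict
(`> 5`), and doubles as the localization gate: only PSMs passing it count
toward site-localized totals.

Manual spectral inspection cannot be automated faithfully, so it is
approximated by two *advisory* flags (`flag_implausible_glyco()`): more
glycans per PSM than `max_glycans_per_psm` (default 2), and glycan
localizations inside the excluded N-terminal region (default positions
16-100 — the region boundary is a documented, user-confirmable default;
downstream counting excludes flagged glycan localizations but the rows
themselves are never removed, and the exclusion is switchable).

## Site occupancy

Occupancy is PSM counting: per (site, donor, week, dataset),
`occupancy = n_modified / n_covering`, where the denominator is the
number of curated PSMs whose peptide span contains the residue — span
coverage, not protein-wide totals, so sites in poorly covered regions are
not diluted by unrelated peptides. Cells with zero coverage emit no
record rather than a 0/0. A residue carries at most one modification per
PSM (phospho and glycan are exclusive at a site). Reporting conventions:
mean per-week PSM counts divide the lactation-wide total by the number of
sampling weeks (nine by default) with half-up rounding; site rankings
break ties by ascending position; longitudinal trends are the sign of the
least-squares slope of occupancy against week *index* (1..9), not
calendar week, since sampling is unevenly spaced.

PSM counts are a semi-quantitative proxy: within one dataset, relative
occupancies and trends are meaningful; absolute counts are not comparable
between proteome and peptidome. `glyco_fraction()` provides the
orthogonal MS1-area estimate (glycoform area / total area per span and
week, scale-invariant), and `build_ladder()` organizes the C-terminal
peptide families that share an end position.

## The simulator: what it does and does not emulate

`simulation_truth()` fixes the study shape — 2 donors x 9 sampling weeks
(1, 2, 3, 4, 6, 8, 10, 12, 16) x proteome/peptidome — and carries every
generator parameter alongside the truth it encodes. Defaults are
plausible values mirroring the qualitative pattern reported for
beta-casein, and are explicitly non-normative: Ser24/Ser25 phosphorylation
declining 0.90 to 0.65 over lactation with S24 ≥ S25 > S23 > S21 > T18;
glycosylation at Thr207 (0.12) and Thr214 (0.17) with species weights
N1H1 0.6 > N1 0.3 > N1F1 0.1; per-week covering PSM counts of 750
(proteome) and 575 (peptidome), chosen so that the default glyco
occupancies yield per-week modified-PSM counts of the magnitude seen in
practice (~90 and ~69 at 12% occupancy).

PSMs are drawn per peptide *region* (the N-terminal cluster 16-30 and the
C-terminal ladder region 190-226 with jittered start positions), and each
PSM carries each covered site modified by an independent Bernoulli draw of
that site's truth — so every site's estimator remains exactly
Binomial(n_covering, p) and recovery tests are unbiased. Target and decoy
scores come from truncated-normal families with overlap, so threshold
filters visibly act; decoys and deliberately implausible glyco rows
(triply glycosylated, N-terminal glycosites) are appended at configurable
rates. Intact features get Gaussian mass error and backbone-clustered
retention times; only the phospho backbones are emitted as PrSM records by
default, leaving glycoproteoforms to the theoretical pass — the same
division of labour the annotation stage expects in practice. MS1 areas
are multiplicative log-normal around a per-week glyco-fraction truth.

What the simulator does **not** emulate: chromatographic peak shape,
charge states, spectral interference, search-engine score-to-error
calibration, isotope-pattern deconvolution errors (harmonics, off-by-one
isotope), shared peptides from other proteins, and missingness structure
across weeks. Passing recovery tests therefore demonstrates that the
*computations* are correct and statistically calibrated under clean
generative assumptions — not that real-data occupancy estimates carry the
same accuracy.

Determinism: each generator reseeds from `truth$seed` (the intact and MS1
generators at fixed small offsets), so equal seeds give identical tables.

## Validation design and problem sizes

The test suite checks, among others: mass agreement with an independent
elemental-composition oracle (100 random peptides, 0-3 modifications);
library cardinality against a brute-force multiset enumerator across
configurations; a noiseless intact round-trip (100% label recovery, exact
abundances) and a noisy one (0.3 Da mass error, 20% noise features, ≥95%
true-label recovery pooled over 50 seeds); binomial occupancy recovery at
truths {0.05, 0.17, 0.70, 0.85} with 500 covering PSMs — coverage of the
±1.96·√(p(1−p)/500) band is computed over 200 replicates *pooled across
the sites sharing a truth*, because the band's exact per-site coverage
(~0.94-0.95 at these n, p) makes a per-site ≥93% check at 200 replicates
unstable by construction; and declining-trend recovery (0.90 → 0.65,
200 PSMs/week, negative slope in ≥95% of 100 replicates). These sizes
keep the whole suite under a minute while leaving the statistical checks
well-powered.

The packaged reference FASTA is a clearly labelled **synthetic stand-in**:
its residues 16-30 and 190-226 are the documented beta-casein fragments
and it reproduces the precursor's headline values (226 aa, average mass
rounding to 25 kDa), but positions 31-189 and the signal peptide are
filler (deliberately Ser/Thr-free so no spurious sites exist). Analyses
of real data should load the canonical UniProtKB P05814 FASTA with
`read_protein_fasta()`.

## Known limitations

* Donor-specific occupancy values from real milk are not reproducible
  from synthetic data and are out of scope; defaults mirror the pattern
  only.
* FDR estimation, spectral searching, deconvolution and XIC integration
  are upstream tools' territory; their outputs are consumed as schemas.
* The glycan catalog and the excluded N-terminal region are documented
  defaults that a user must confirm against their own search setup.
* Occupancy's covering-PSM denominator treats every covering PSM as an
  independent detection; shared precursors sampled repeatedly violate
  this mildly in real data.

## A worked example

```{r example, eval = FALSE}
library(casoform)

# enumerate the proteoform space of the mature chain
lib <- enumerate_proteoforms(beta_casein_reference(mature = TRUE))
nrow(lib)                      # 330

# simulate one study, run the bottom-up tier
truth <- simulation_truth(seed = 1)
psms <- simulate_psm_table(truth)$psms
cur <- curate_psms(psms)
occ <- occupancy_table(flag_implausible_glyco(cur$kept))
longitudinal_summary(occ)$trend

# per-week mean glyco PSMs at Thr214, donor 1, proteome
mean_site_psms(occ, "T214", 1, "proteome")
```
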