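---
title: "Methods: tandem-repeat detection, GCPSR delimitation and spore morphometrics"
author: "boletax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem-repeat detection, GCPSR delimitation and spore morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boletax)
```

`boletax` implements the three bespoke computational procedures used in
multi-locus re-assessments of bolete (Boletaceae) species: detection and
characterisation of tandem-repeat insertions within the nuclear ribosomal ITS
region, rule-based Genealogical Concordance Phylogenetic Species Recognition
(GCPSR) over support-annotated single-locus genealogies, and the spore and
pileipellis morphometric conventions used in species descriptions.  This
vignette explains the models and conventions, the tunable parameters and their
defaults, the design choices that were genuinely open, and what the synthetic
data generators do and do not emulate.

## 1. Tandem-repeat detection in ITS

### Scoring model

A tandem array is scored by aligning the sequence region against its
cyclically tiled consensus pattern:

\[
\mathrm{score} \;=\; m \cdot \#\mathrm{matches} \;-\;
x \cdot \#\mathrm{mismatches} \;-\; g \cdot \#\mathrm{indels},
\]

so a perfect array of total length $L$ scores $mL$ regardless of its period.
The two weight settings of interest are **2-7-7** ($m{=}2, x{=}7, g{=}7$, the
TRF default used for the primary full-sequence scan) and the more permissive
**2-3-5** used for a second, more sensitive pass over the ITS2 insertion
region.  Only arrays reaching `min_score = 50` are reported.  Under 2-7-7
this reproduces the observed detection floor for pure AC dinucleotide runs:
a 24-bp run scores $2 \times 24 = 48 < 50$ and is silent, a 26-bp run scores
52 and is reported — the smallest detectable AC microsatellite is 26 bp.

Candidate periods are seeded by exact k-mer recurrence: for periods up to
10 bp, substrings with an exact tandem repetition (or, in `exhaustive` mode,
every distinct substring); for longer periods, pairs of identical 5-mers at a
distance $d \in (10, \texttt{max\_period}]$ propose a candidate of period
$d$.  Candidates are deduplicated up to rotation, and patterns that are exact
powers of a shorter unit are dropped (their tiling — hence every alignment
against them — is identical to the unit's).  Each candidate is aligned by a
wraparound local dynamic programme (the pattern index is read modulo the
period, so arrays may begin and end at any phase and carry fractional
copies), then refined by iterated column-majority consensus updates
(ties broken alphabetically A<C<G<T) until a fixpoint, keeping the
best-scoring round.

Reported hits additionally require the array span to reach **1.8 periods**.
Without this floor, any 25-bp-or-longer substring would qualify by matching a
single copy of itself at score ≥ 50; requiring close to two copies matches
how TRF behaves in practice, and the smallest copy number printed in the
study's insertion table is 1.9.  Overlapping hits are resolved by score,
then smaller period, then leftmost start — so a perfect AC run is reported
with period 2, not 4 or 6.  `copy_number` is the array span divided by the
period (one decimal); `percent_matches` and `percent_indels` use the total
number of aligned columns as their denominator, rounded half-up (the source
material never defines this denominator; this is a package convention).
`N` and IUPAC ambiguity codes score as mismatches against every base, and
records with more than 5% non-ACGT bases in the scanned region are refused
unless explicitly overridden, mirroring the upstream sequence-quality screen.

Coordinates are 0-based half-open internally; rendered reports print 1-based
inclusive positions.

### Two-pass ITS2 protocol

`two_pass_its_scan()` runs the 2-7-7 scan over the full sequence and the
2-3-5 scan over the ITS2 window only, lifting second-pass coordinates back to
full-sequence space.  The original protocol defined the window in alignment
columns (position 770 to the ITS end at 1169); since alignment columns are
meaningless for a single sequence, the package takes a per-sequence ITS2
interval from the annotation instead, with the alignment-column route
available through `infer_insertion_boundaries()` (the insertion is the
maximal contiguous block that is gap in every insertion-free reference and
non-gap in the target; with several disjoint blocks the longest is returned
and the others flagged).

### Motif comparison

Consensus motifs are compared by exact global alignment under unit costs
(match +1, mismatch −1, gap −1), reporting matched columns over alignment
length, optionally maximised over rotations (`cyclic = TRUE`) since a
tandem consensus is defined only up to rotation.  This replaces the original
BLASTn comparison with a deterministic, dependency-free computation — a
deliberate design substitution, not an emulation of BLAST statistics.

### Verification strategy

The wraparound detector is checked against an independent brute-force oracle
(`oracle_best_score()`): plain Smith–Waterman of the sequence against
explicitly tiled copies of every distinct substring pattern.  The test suite
proves score equality over **every** `{A,C}` sequence of length ≤ 20 at
periods ≤ 10 under 2-7-7 weights (canonical representatives under
base-complement and reversal, both score-invariant; the invariance itself is
re-verified on a sampled subset).  Under 2-7-7 the substring-pattern
maximisation is the true maximum on such short sequences: a majority
consensus can only beat every substring pattern when each copy carries an
error *and* $2p(k-1) > 9k$, which forces $kp > 20$.  Under softer weights
(e.g. 2-3-5) consensus refinement can exceed any substring pattern even
below 20 bp, which is precisely why the production detector refines; the
equivalence check is therefore run at the 2-7-7 study setting.

## 2. GCPSR species delimitation

Single-locus genealogies arrive as Newick trees whose internal labels carry
maximum-likelihood bootstrap (BS) and/or Bayesian posterior probability (PP)
in `"BS/PP"`, bare-BS or bare-PP dialects.  Support bands: **strong** at
BS ≥ 90 and PP ≥ 0.99, **medium** at BS 70–89 and PP 0.95–0.98, **weak** at
BS 50–69 and PP 0.80–0.94; strong or medium is **well supported**
(equivalently BS ≥ 70 and PP ≥ 0.95).  Where the two metrics fall in
different bands the weaker is binding, because the bands are conjunctions.
Where only one metric is present the class comes from it alone and the
result is flagged `single_metric`: trees are routinely drawn with supports
below the reporting floor (BS ≤ 50, PP ≤ 0.8) collapsed, so absence is
treated as unknown, not as conflict.

A candidate lineage is any well-supported clade of any single-locus
genealogy (outgroup excluded, at least two taxa, and not the entire ingroup
taxon set — the whole genus is not a species hypothesis).  A candidate is
**accepted** when no other genealogy contradicts it, where contradiction
requires a *well-supported* clade overlapping the candidate's restriction
without nesting; unsupported conflicting topology is merely `compatible`
(otherwise any poorly resolved tree would contradict everything).  A
genealogy sharing fewer than two of the candidate's taxa, or all of its
taxa with nothing outside, is `uninformative`.

Lineages are reported at the **maximal** accepted clade; nested accepted
clades are recorded as substructure rather than separate species.  Mutually
incompatible accepted clades (possible with heavy taxon masking) are
resolved deterministically: more independently inherited supporting linkage
groups, then stronger minimum support class, then the smaller clade, then
lexicographic order.  A lineage whose support all comes from one linkage
group — a single locus, or loci inherited together such as ITS and LSU — is
a **putative** phylogenetic species; support from two or more independent
groups makes it a phylogenetic species.  Taxa in no accepted lineage are
listed as unassigned.  A concatenated multilocus tree, when supplied, only
*flags* lineages it contradicts; it never removes them.  Merging putative
lineages observed at non-overlapping locus sets (conspecificity judgments)
is left to the analyst: the report surfaces them for manual review.

`count_parsimony_informative()` implements the usual site statistic: a
column is informative when at least two unambiguous nucleotide states each
occur in at least two sequences; gaps and ambiguity codes are missing data.

## 3. Morphometrics

Measurements are grouped collection → basidiome → structure, with the
`[n/m/p]` bookkeeping (n structures from m basidiomes of p collections).
For each collection the mean length, width, length/width quotient Q and
rotation-ellipsoid volume $V_m = \pi L W^2 / 6$ are computed **per structure
and then averaged**; across collections the summary follows the
(minimum of the averages) average ± standard deviation of the averages
(maximum of the averages) convention, with an $n{-}1$ standard deviation
across collection means.  Averaging volumes per spore rather than plugging
grand means into the formula matters: by positive association of length and
width, $\mathbb{E}[LW^2] \ge \mathbb{E}[L]\,\mathbb{E}[W]^2$, so a printed
$V_m$ legitimately exceeds $\pi \bar L \bar W^2/6$ (e.g. 151.8 from the
means 11.6 × 5.0 µm versus a printed 155); the test suite asserts this
inequality.  Display rounding follows the descriptions: dimensions to
0.1 µm, Q to two decimals, $V_m$ to integers.  With a single collection the
sd is reported as 0 and flagged.

The isoprobability (confidence) ellipse of a bivariate Gaussian at level
$\alpha$ is the equal-density contour enclosing probability $\alpha$:
squared Mahalanobis radius $k^2 = \chi^2_2(\alpha) = -2\log(1-\alpha)$
(at the 68% level used for spore and pileipellis size distributions,
$k \approx 1.5096$), axes along the covariance eigenvectors with semi-axes
$\sqrt{\lambda_i}\,k$.  The centre — the mean length and width — is the most
probable value of the pair.  Boundary points count as inside.  Ellipses can
be fitted to raw structures or to per-collection mean points; the latter is
the mode used when comparing species-level spore-size distributions across
collections.  Sample covariance uses $n-1$.

## 4. Synthetic data: what it emulates, and what it does not

The generators provide the statistical structure each pipeline stage
assumes, so everything is testable offline.

* `simulate_genealogy_set()` emulates the study design of several
  independently inherited loci (default ITS, LSU, tef1, rpb2, with ITS and
  LSU sharing the `ITS-LSU` linkage group) over a known species partition.
  Topologies are random coalescent-style joins: each species drawn
  concordant (probability `concordance_prob`, default 1) contributes a
  random subtree whose root takes supports from the "true" ranges (defaults
  BS 95–100, PP 0.99–1.00, i.e. strongly supported); discordant species
  scatter their members as independent tips.  All other internal nodes draw
  from the "other" ranges (defaults BS 20–69, PP 0.30–0.94, below the
  well-supported threshold, as deep inter-species nodes in the real trees
  are rarely decisive).  A species that becomes monophyletic *by chance*
  after scattering keeps ordinary node supports — deliberate: a fabricated
  high support on an accidental clade would not resemble data, and the
  chance-monophyly rate itself is pinned against an exact enumeration
  oracle in the tests.  No substitution models or branch lengths are
  simulated; the trees are fixtures for the delimitation rules, not an
  inference target.
* `simulate_marker_sequences()` plants an exact AC microsatellite in ITS1
  (default 26 bp) and a minisatellite in ITS2 built as
  $\lfloor\kappa\rfloor$ full copies plus a prefix of length
  $\lfloor(\kappa - \lfloor\kappa\rfloor)\,p\rfloor$ (defaults: the 82-bp
  insertion consensus at $\kappa = 2.8$), then mutates the planted array at
  the stated substitution and indel rates (defaults 2% and 0.5%,
  within-species variation being small).  One backbone per call stands for
  the species; truth records carry exact planted coordinates and the
  pre-mutation string.  Flanking backbone is i.i.d. uniform DNA — more
  repetitive than real ITS in expectation of short motifs, less so for long
  ones; passing tests demonstrate detector behaviour under the planted
  model, not performance on real ITS composition.
* `simulate_spore_measurements()` draws (length, width) pairs from a
  bivariate Gaussian per collection, the collection means jittered around
  the global mean.  Defaults: mean 11.6 × 5.0 µm, within-collection sds
  0.9/0.3 µm, between-collection sds 0.6/0.2 µm (the magnitude of the
  printed sd-of-averages), 31 spores × 1 basidiome × 19 collections.
  Non-positive draws are rejected and redrawn, preserving the Gaussian bulk
  rather than clipping.

Every generator reseeds from its parameter object, so outputs are
byte-identical under a fixed seed.

## 5. Numerical choices and degenerate inputs

* Wraparound DP rows are swept twice so deletion chains may cross the
  pattern boundary; a full-cycle deletion (zero net phase shift) is never
  optimal, so two sweeps reach the fixpoint.
* Consensus-refinement iterations are capped at 6 with cycle detection;
  the best-scoring round is kept, so the cap can only lose improvements,
  never correctness of reported scores.
* Empty sequences yield empty hit tables; an all-gap reference block absent
  from an alignment yields the empty interval ("no insertion"); a singular
  covariance is rejected when building an ellipse; a single-collection
  summary reports sd 0 with a flag rather than NA.
* Problem sizes in the test suite: the detector–oracle equivalence
  enumerates all ≈ 2.1 M `{A,C}` sequences up to 20 bp (≈ 526 k canonical
  representatives); GCPSR recovery runs 50 seeded replicates at 2–6 species
  × 3–8 specimens; ellipse calibration uses 10⁵ draws; the
  consensus-recovery Monte Carlo uses 100 seeded replicates at 5%
  substitution.  These sizes make the full suite run in a few minutes while
  keeping Monte-Carlo standard errors well inside the asserted tolerances.

## 6. Known limitations

* The detector reproduces the scoring conventions of the original tandem
  repeat finder but not its Bernoulli-model significance filter, entropy
  column, or genome-scale performance engineering; on megabase inputs it
  would be slow.
* Table-style "insertion size" is reported as the detected array span; the
  alignment-derived insertion block is available separately and the two can
  differ at fuzzy boundaries.
* GCPSR here is the rule-based criterion only — no Bayesian species
  delimitation, no tree inference, no alignment.
* The putative-vs-phylogenetic distinction depends on declared linkage
  groups; misdeclared linkage silently changes lineage status.

## 7. Worked example

```{r example}
motif <- read.delim(system.file("extdata", "table1_motifs.tsv",
                                package = "boletax"))$consensus[1]
detect_tandem_repeats(strrep(motif, 2))

part <- setNames(rep(c("sp1", "sp2", "sp3"), each = 4),
                 paste0(rep(c("a", "b", "c"), each = 4), 1:4))
sim <- simulate_genealogy_set(genealogy_sim_params(part, seed = 7))
delimit_species(sim$genealogies)

ms <- simulate_spore_measurements(spore_sim_params(seed = 3))
summarize_structure(ms)
fit_isoprobability_ellipse(ms, level = 0.68, use_collection_means = TRUE)
```
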