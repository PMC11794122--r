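---
title: "Modelling antibody-DNA conjugate qPCR assays on extracellular vesicles"
author: "evImmunoPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antibody-DNA conjugate qPCR assays on extracellular vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evImmunoPCR)
```

## The assay, in brief

Tumor-associated extracellular vesicles (EVs) carry surface antigens — here
the epithelial cell adhesion molecule, EpCAM — that distinguish them from
the vastly more abundant normal vesicles in a biofluid. The assay this
package models converts that protein signal into an amplifiable DNA signal:
a biotinylated monoclonal antibody and biotinylated reporter
oligonucleotides are joined on a streptavidin tetramer, so that each
antibody that finds its antigen parks a fixed number of qPCR-amplifiable
DNA strands on the vesicle surface. After bead capture, washing and
elution, qPCR of the reporter strands quantifies the antibody — and hence
the antigen — bound to the vesicles. A dual-conjugate variant adds a
proximity ligation step: two conjugate types carrying different strands
(C1, C2) must sit on the *same* vesicle for a bridging connector and ligase
to seal them into the single amplifiable template C1C2, trading raw signal
for specificity.

The package implements this as a forward generative model (conjugate
assembly statistics, EV populations, labeling, capture, ligation, Ct
generation) and the matching inverse pipeline (standard-curve fitting and
inversion, the DNA-to-antibody-to-mass conversion chain, digital Poisson
particle counting), so that every quantification step can be exercised
against simulated ground truth.

## Conjugate assembly statistics

Streptavidin binds four biotins with effectively irreversible affinity.
When biotinylated antibodies and DNAs compete randomly for those sites, the
number of antibodies per streptavidin is governed by the loading ratio
$\lambda$ (antibody moles : streptavidin moles). In the Poisson description

$$P(N = n \mid \lambda) = \frac{\lambda^n e^{-\lambda}}{n!},
\qquad
P(N > 1 \mid \lambda) = 1 - e^{-\lambda} - \lambda e^{-\lambda},$$

so at $\lambda = 1/80$ the chance of a multivalent (two-or-more-antibody)
conjugate is

```{r}
signif(probMultivalentAntibody(1 / 80), 2)
```

which is why the assembly can be treated as "one antibody, three DNAs, per
occupied tetramer". The package also implements the exact finite-valence
model: `enumerateSiteOccupancy(p_ab, p_dna)` enumerates all $3^4$
assignments of the four sites to {antibody, DNA, free}, assuming sites fill
independently with no ligand depletion and equal biotin affinity for all
species. That independence assumption is the minimal model consistent with
the Poisson limit; the antibody-count marginal is exactly
$\mathrm{Binomial}(4, p_{ab})$, and the test suite checks that the Poisson
form is its small-$\lambda$ limit. `meanDnaPerConjugate()` gives
$E[n_{dna} \mid n_{ab} = 1]$, which approaches 3 when antibody is rare and
DNA saturating — the nominal conjugate design. Biocytin blocking is
modelled as sites that are simply unavailable (inert).

A note on the loading ratio: the mix this assay family actually describes
(0.06 µM antibody × 10 µL against 1.6 µM streptavidin × 3 µL) works out to
$\lambda = 0.125$, i.e. 1:8, while the ratio quoted alongside it is 1:80.
`lambdaFromMix()` reports the arithmetic value; the analytic multivalency
reproduction uses 1:80 as quoted; `validateFixtures()` surfaces the
discrepancy as a warning. At 1:8 the multivalent probability is still below
1%, so the one-antibody picture survives either reading.

## The oligo design table

The packaged FASTA (`assayOligos()`) carries the thirteen oligos of the
assay design: the biotinylated 69-mer reference amplicon with its primer
pair and ROX-labelled probe, the proximity strands C1 and C2 (plain and
biotinylated), the bridging connector, the proximity primer pair, a TaqMan
probe, and the synthetic full-length ligation product C1C2. Terminal
modifications (biotin, 5′-phosphate, fluorophores, MGB) are metadata tags,
never sequence characters. Sequence-level checks are exact-match only —
there is no thermodynamic or mismatch-tolerant model, because the design
justifies none — with 0-based, half-open coordinates throughout, and
amplicon lengths include both primer footprints.

Two printed-sequence quirks are handled deliberately:

* the reverse complement of the EXO reverse primer does not exactly match
  the 3′ end of the printed 69-mer (`GTATCCGAGCC...` vs `GTATCCGATAG...`),
  almost certainly a design-table typo. `findAmplicon()` reports "no
  amplicon" rather than guessing the intended sequence, and
  `validateFixtures()` lists the mismatch as a documented warning;
* the connector's complementarity to the C1-3′/C2-5′ junction is only
  partial as printed, so its bridging geometry is carried as metadata of
  the ligation event and not sequence-verified. `ligateOligos()` enforces
  only the chemically necessary condition, a 5′-phosphate on the downstream
  strand.

## The synthetic-data generator

`simulatePopulation()` draws a vesicle population in which each EV is
tumor-derived with probability `tumor_fraction`; tumor vesicles carry
negative-binomially distributed antigen copy numbers
(`antigen_mean`, `antigen_dispersion`), normal vesicles none. The negative
binomial was chosen because surface-marker copy numbers on vesicles are
over-dispersed as a rule; nothing in the assay description pins down a
distribution, and the dispersion parameter lets a user interpolate toward
Poisson (`size` large) or heavier tails (`size` small). Defaults — 80%
tumor vesicles with a mean of 50 antigen copies at dispersion 5, and a
nonspecific rate of 0.05 conjugates per EV — describe a cultured-cell EV
preparation from an EpCAM-positive line rather than plasma, where the tumor
fraction would be far smaller.

`labelPopulation()` is binomial thinning: each antigen copy independently
recruits a conjugate with probability `p_bind`; dual labeling splits
conjugates evenly and independently between the two types; nonspecific
binding is an EV-level Poisson count (kept at the vesicle level, rather
than as bulk background, so the proximity-ligation background mechanism
stays expressible). Each conjugate contributes `dna_per_conjugate` reporter
strands — default 3, the nominal valence; the occupancy model's
`meanDnaPerConjugate()` can be plugged in instead when the stochastic
valence matters. `captureWashElute()` thins vesicles independently with
probability `capture_eff × wash_retention` and converts the surviving
strand count to a concentration via the Avogadro constant
(6.02214076e23) and the eluate volume; with lossless settings this ground
truth is exact to floating precision, which the tests assert.

All randomness flows through per-call seeds; `spawnSeeds()` expands one
master seed into per-stage seeds so that pipeline stages can be rerun in
isolation and whole runs are byte-reproducible.

What the generator does **not** emulate: vesicle size distributions,
plasma matrix effects, antibody cross-reactivity, diffusion or steric
limits on binding, and the mapping from particle counts to total exosomal
protein mass (real preparations are usually characterized in µg/mL of
protein; that mapping is left as a user-set scale factor). Passing tests
therefore demonstrate the internal consistency of the quantification
chain, not field performance on clinical material.

## The qPCR model

Ct values follow the log-linear standard curve
$\mathrm{Ct} = a X + b$ with $X = -\log_{10}(\text{dilution})$, so larger
$X$ is more dilute and the slope is positive. The packaged reference curve
is $a = 4.059$, $b = 8.144$, the curve fitted for the full-length C1C2
template; its implied amplification efficiency,
$10^{1/|a|} - 1 \approx 0.76$, is noted as sub-ideal (perfect doubling
corresponds to $|a| = \log_2 10 \approx 3.32$). Because the curve is
stated on a dilution scale, absolute quantification needs an anchor:
`conc_at_x0`, the concentration at $X = 0$, supplied by the user (default
10 nM in the packaged scenarios).

Replicate noise is Gaussian with a default SD of 0.2 cycles — typical
replicate scatter for this kind of assay; nothing in the source material
states a value. Wells whose Ct would exceed `max_cycles` (default 40) are
censored to "undetermined" and are excluded (and counted), never imputed.
Fitting is ordinary least squares on the determined wells; inversion is
the exact algebraic inverse, with extrapolation beyond the fitted range
flagged. The limit of detection is the most dilute level at which *all*
replicates are determined — the rule an instrument operator applies when
reading a dilution series — rather than a 95% probit fit, which would
demand replication the modelled experiments do not have.

One subtlety the tests document: expected LOD degrades monotonically with
added noise only for dilution grids whose detectable levels sit clear of
the censoring boundary. A level lying just *past* the max-cycle floor can
be "rescued" by a lucky late amplification under noise — real qPCR
behavior — so the monotonicity test uses an interior grid.

## Proximity ligation

Proximity is binary colocalization: a vesicle carrying `bound_1` type-1 and
`bound_2` type-2 conjugates yields `min(bound_1, bound_2)` ligatable pairs
(each conjugate used at most once — the simplest conservative pairing rule;
no geometry is modelled), each sealing with probability `p_ligate`.
Background is a reaction-level Poisson count representing free-conjugate
collision ligation. Its default is zero: the assay's non-biotinylated
controls produced no Ct at all, which cannot distinguish "no background"
from "background below detection", so zero is the neutral default and any
positive rate is an explicit user choice. The closed form
`detectionProbability()` gives the per-vesicle detection probability under
Poisson labeling and is the analytic companion the simulator is tested
against. Conservation (`templates = from_ev + from_background`) holds by
construction and is asserted across seeds.

`plaVsDirectGain()` compares the two readout arms on one simulated
scenario. Both arms share the same curve and censoring, so their
concentration floors coincide; the comparison reports each arm's LOD in
absolute concentration and their ratio. In this model the PLA arm can only
lose material relative to direct readout (ligation is sub-unit, pairing
takes the minimum), so its gain is specificity — zero templates without
dual labeling — rather than raw sensitivity; the scenario in which a
ligation-based readout detects ten-fold more dilute input than direct qPCR
reflects assay-level differences (different amplicons and primer systems)
that sit outside this model and are therefore documented, not asserted.

## The inverse quantification chain

The chain is linear and exact:

$$c_{ab} = \frac{c_{dna}}{r}, \qquad
m = c_{ab} \times MW, \qquad
\sigma_{out} = \sigma_{in} \times \prod_i |f_i|$$

with $r$ the strands-per-antibody ratio (default 3) and the dimensional
identity 1 nM × 1 kDa = 1 ng/mL doing the mass conversion. The default
molecular weight is 29.1 kDa — the value the assay's own conversion uses
for EpCAM; the ~40 kDa figure quoted elsewhere for the glycosylated
protein is a documented inconsistency, and `mw` is always user-overridable.
All arithmetic is kept at full precision; the reporting convention
(concentrations to 2 decimals in nM, masses to 3 significant figures in
ng/mL) is applied only in `show()`. Worked through the packaged example —
2.41 ± 0.48 nM reporter DNA — the chain gives 0.80 ± 0.16 nM antibody and
23.4 ± 4.66 ng/mL antigen mass; note 0.16 × 29.1 = 4.656, so the package
reports 4.66 at 3 s.f. (a truncated 4.6 is sometimes seen for this
example).

```{r}
quantifyConcentration(2.41, 0.48)
```

Digital particle counting uses the standard single-molecule partition
correction $\lambda = -\ln(1 - n_{pos}/n_{total})$, concentration
$\lambda$ per partition volume. The source material invokes "standard
curve plus Poisson" for particle concentrations without specifying a
procedure (and prints per-mL figures that are dimensionally puzzling —
sub-unity counts per mL — which no operation here reproduces); the
implemented estimator is this package's interpretation, clearly labelled
as such, and it refuses the all-positive plate, where the estimate is
infinite, with advice to dilute.

## Problem sizes and numerical choices

The statistical test suite runs at sizes chosen to give comfortable Monte
Carlo margins while staying quick on one core: law-of-large-numbers and
thinning checks at $10^4$–$10^5$ vesicles; OLS bias and LOD-monotonicity
studies over 200 seeds; PLA monotonicity at $2\times10^4$ vesicles per arm
with paired seeds over 20–30 seeds; end-to-end parameter recovery over 200
seeds of a 2,000-vesicle scenario whose expected eluate concentration is
2.41 nM (antigen mass ≈ 23.4 ng/mL), asking for a median absolute relative
error on the recovered mass under 10% with 3 qPCR replicates at 0.2-cycle
noise; the digital-Poisson bias check averages 100 simulated $10^4$-well
plates per occupancy (a single plate at $\lambda = 0.1$ carries ~3%
sampling noise, so a one-plate check would test the draw, not the
estimator). Probability tables must sum to 1 within $10^{-12}$; exact
identities (ligation concatenation, noiseless round trips) are asserted at
$10^{-9}$ or tighter.

## Known limitations

* No kinetics: binding, washing and ligation are single-probability
  events, not rate processes; incubation times and temperatures have no
  representation.
* No antibody bivalence, steric hindrance, or ligand depletion in the
  occupancy model.
* The qPCR model is the fitted line plus Gaussian noise; raw amplification
  curves, probe chemistries and multiplex compensation are out of scope.
* The mapping from simulated particle counts to total-protein mass
  (µg/mL), and therefore to the protein-based detection limits reported
  for instrument experiments, is a user-supplied scale factor; those
  instrument-measured values are treated as data, not reproduction
  targets.
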