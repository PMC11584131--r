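---
title: "Modelling self-excising homing gene drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-excising homing gene drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remede)
```

## The question the model answers

A homing gene drive converts heterozygotes to homozygotes in the germline
and therefore invades from arbitrarily low release frequencies. That power
is also the problem: no widely accepted mechanism exists to take a drive
*out* of a population once released. A self-excising architecture embeds
the drive between engineered direct repeats together with a second
endonuclease site; single-strand annealing (SSA) between the repeats
deletes the element and reconstitutes a functional wild-type allele,
marked with a silent PAM mutation (TcG) that the drive can no longer cut.
The package asks, quantitatively: for which excision rates does the drive
first spread and then replace itself with resistant wild-type alleles?

## Germline repair-outcome model

One germline passage treats every allele independently ("single pass"):

* a susceptible wild-type allele `w`, in the presence of any nuclease
  source (`g` or `s`), is cut with probability $q$; a cut converts to `g`
  by HR with probability $p$, else NHEJ yields in-frame `u` with
  probability $\delta$ or out-of-frame `r`;
* a drive allele `g` is excised by SSA with probability $\alpha$
  (sex-specific), yielding marked `v` with probability $\varepsilon$ or
  reverted plain `w`; or suffers second-site NHEJ with probability
  $\gamma$, becoming the SSA-immune drive `s`;
* `u`, `r`, `v` transmit unchanged; `s` transmits unchanged but remains a
  full nuclease source for cutting `w`.

Two orderings were genuinely open. First, whether SSA resolution of `g`
precedes or follows homing of `w` within one passage: we treat them as
simultaneous independent draws, matching the flat outcome tree, and a `w`
produced by excision-with-reversion is **not** re-exposed to cutting in
the same passage — any other choice introduces an order dependence the
biology does not pin down. Second, what an HR event copies when the
nuclease source is `s`: we copy `g` (the conversion probability tree is
defined per target, not per template). This matters only at order
$\gamma$ and is invisible at $\gamma \le 10^{-3}$.

Males are hemizygous at the X: no homing target exists, so male germlines
cut nothing, but the male drive allele still undergoes SSA at
`alpha_male`.

### Zygotic channels

Maternally deposited nuclease cuts the *paternally inherited* `w` with
probability `z_maternal` when the mother carried a drive; a paternally
inherited drive's zygotic expression cuts the maternal `w` with
probability `z_paternal`. Both resolve by NHEJ only (no template is
reliably available in the zygote). Sons inherit no paternal X and are
untouched by either channel. Population simulations default both to zero:
the empirical contrast between drive architectures (heavy deposition for
the plain drive, little for the insulated self-excising construct) is
exposed through presets for cross generation, not baked into the
population model.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| $q$ | 0.95 | per-allele cut probability | with $p$, calibrated so heterozygous females transmit the drive at ~87%, the empirically observed super-Mendelian rate; $q,p$ are not separately printed anywhere |
| $p$ | 0.78 | HR fraction of cuts | see $q$ |
| $\delta$ | 0.4 | in-frame fraction of NHEJ | empirical resistant-allele split |
| $\alpha_f$, $\alpha_m$ | 0.1, 0.01 | per-passage SSA probability | female rate from the observed excision frequency; male rate an order of magnitude lower (X transgene silencing in the male germline) |
| $\gamma$ | 0 | second-site NHEJ | the second-nuclease site was stable for ~2 years; sensitivity runs use $10^{-3}$ |
| $\varepsilon$ | 1 | marker retention of SSA | presets explore 0.25 (mismatch repair can revert the marker) |
| costs | 0.97 / 0.31 | yellow male / female mating-weight reduction | competitive assay (1 win in 30) and courtship observations |

The "no resistant alleles" presets (`fig6c/d/e`) deserve a note. Setting
$p = 1$ while keeping $q = 0.95$ would raise heterozygous transmission
from ~87% to ~97.5% — a different drive, not the same drive minus
resistance. We instead preserve the calibrated conversion product,
$q \leftarrow qp = 0.741,\ p \leftarrow 1$: a cut either converts or the
allele is left intact. This reproduces the published peak frequencies
(~60% at 10% SSA, ~90% at 5% SSA); the alternative reading overshoots
(~71% at 10% SSA).

## Population engines

Generations are discrete with a constant census $N$ (default 1000,
unstated in the source material and exposed in the config). For each of
the $N$ offspring slots, conceptually: draw a mother and a father
proportionally to mating weight, draw one gamete from each parental
germline law, apply zygotic effects, assign sex fairly. Because parents
are drawn independently per offspring, this collapses to a single exact
multinomial draw over the 27 sex-by-genotype categories, which is what
`simulate_drive()` performs — there is no per-individual loop, and 100
replicates of 60 generations run in seconds. Mating costs act on mating
weight for **both** sexes (yellow females weight $1-0.31$); with costs
off, mothers are sampled uniformly. Costs-as-mating-weight (rather than
fecundity) matches how the costs were measured: copulation failure in
competitive assays.

`expected_trajectory()` iterates the same law without sampling, as an
infinite-population oracle. One numerical point: the recursion is
bilinear in the maternal and paternal laws, so the tiny float drift in
the frequency sums compounds *multiplicatively* (log-error grows like a
Fibonacci sequence) and visibly explodes near generation 80 if left
alone; both engines therefore renormalize each generation.

Zero males or zero females is recorded as extinction and the trajectory
carries its last composition forward; it is not resampled.

Replicate seeding: one master seed deterministically spawns per-replicate
child seeds (`sample.int` under the master seed), so any replicate is
reproducible in isolation.

## Cage-trial protocol

`run_cage_trial()` emulates the discrete bottle protocol: a founding pool
(default 200 flies, 75% drive homozygotes), a brood of 600 offspring per
generation (the protocol does not state brood size; it only must exceed
the 300 flies removed — exposed in the config), from which two *disjoint*
uniform pools of 150 are drawn: one scored, one seeding the next
generation. Elimination is declared on the scored pools — what an
experimenter can observe — as the first generation at which the class
count is zero and stays zero. With the default parameters the drive
phenotype is eliminated at median generation ~13, with most replicates in
the 10–14 window.

## Calibration

`cross_loglikelihood()` scores sequenced allele-class counts, split by
parental origin, against the exact class law of a single-pair cross:
maternal-origin alleles follow the maternal gamete law; paternal-origin
alleles (females only) follow the paternal law after zygotic deposition.
The multinomial coefficient is dropped (parameter-free). Identifiability
drives the interface: from one cross design, $q$ and $p$ enter the law
only through $qp$ and the uncut fraction $1-q$, so the free parameter is
the aggregate `qp` (with `q` fixed, pinned by the TGG class when
sequencing data are present); freeing `q` and `qp` jointly, or `p`, is
refused with a diagnostic. Origin-unassigned counts are likewise refused:
the likelihood is defined for origin-resolved tables (the generator's
`full_genotyping` mode, mirroring a two-primer genotyping strategy that
resolves zygosity in females). Optimization is bounded L-BFGS-B with 10
random restarts (single golden-section search in one dimension), tie
broken toward the lexicographically smallest parameter vector; confidence
intervals are percentile parametric-bootstrap (default 200 resamples).

## Synthetic data

`generate_cross_dataset()` draws broods (Poisson mean 50 by default —
single-pair fly crosses of this size are routine; fixed sizes available
for exact tests) from *the same analytic law the likelihood uses*, so
calibration on generated data is a true round trip: recovery of
$\alpha_f = 0.1$ to ±0.02 and $\delta = 0.4$ to ±0.05 from $10^4$ gametes
is part of the acceptance suite. The generator emulates genotype-driven
class counts and parental origin; it does **not** emulate sequencing
error, chromatogram ambiguity, somatic mosaicism, or the rare `gGG` class
of indeterminate biogenesis (the schema and tabulation accept `gGG`, the
generator never emits it, the dynamics ignore it). A green round-trip
test therefore establishes internal consistency of generator, likelihood
and optimizer — not correctness of the biological tree itself, which only
real crosses can test.

`generate_courtship_assays()` emits per-pairing courtship indices (Beta
law matched to a stated mean/sd, degenerate when sd = 0) and Bernoulli
copulation outcomes, enough to exercise `courtship_index()` and
`estimate_mating_cost()` at their empirical operating point (1 success in
30 trials → cost 0.97).

## Numerical and interface choices

* Allele distributions are validated to sum to 1 within $10^{-12}$.
* Release counts round half-up with the census total preserved.
* Config files are flat `key: value` YAML-subset or JSON; nested YAML and
  TOML are deliberately unsupported (no parser in the dependency budget;
  the flat key set covers every documented field). Unknown keys are
  rejected; out-of-range probabilities name the offending key.
* Every CLI run writes a JSON manifest (config, child seeds, package
  version) sufficient to reproduce outputs bit for bit.

## Known limitations

* Non-overlapping generations, no age or spatial structure, no
  density-dependent fecundity; census size is fixed by fiat.
* Fitness costs enter only through mating weight; viability or fecundity
  costs of the drive or of yellow body colour are not modelled.
* The excision probabilities $\alpha$ are per-germline-passage constants;
  dependence on direct-repeat length is represented only by choosing a
  different $\alpha$.
* Marker reversion is phenomenological ($\varepsilon$); the underlying
  mismatch-repair mechanism is out of scope.
* Mosaic phenotypes are not a scored state; flies are scored by genotype.
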