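---
title: "Detecting sex-biased admixture with autosome-X f-statistic contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-biased admixture with autosome-X f-statistic contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swampx)
library(dplyr)
```

## The problem

When two diverged populations hybridize, the sexes rarely contribute
equally. In taxa with female philopatry and male dispersal — macaques are
the canonical example — gene flow is carried predominantly by males. The
chromosome classes then record the process at different rates: an autosome
receives migrant alleles in proportion to the average of the male and
female migration rates, the X chromosome (two copies in females, one in
males) receives them at a reduced rate, and the mitochondrial genome only
through females. Under sustained, strongly male-biased introgression a
recipient population's autosomes can be almost completely replaced by donor
ancestry while its mitochondrial lineage remains untouched and its X
retains an intermediate share of the original ancestry. This is the
*nuclear swamping* scenario, and it produces a testable signature:
admixture statistics should look stronger on autosomes than on the X for
the replaced fraction, or equivalently, the f4 statistic that measures
residual affinity to the original sister lineage becomes **more negative on
the X than on the autosomes**.

`swampx` implements the full inference chain for this test:

1. genotype handling with correct ploidy semantics (hemizygous male X,
   haploid mitochondria),
2. f2 / outgroup-f3 / f4 statistics with weighted block-jackknife errors,
3. the autosome-versus-X Welch contrast on per-block f4 values,
4. admixture-graph fitting with an X-specific refit of mixing proportions,
5. identity-by-state distances and neighbor-joining trees, and
6. a sex-structured Wright-Fisher simulator that generates the swamping
   scenario so every stage can be validated end to end.

## Models and estimators

### f-statistics

For populations with derived-allele frequency estimates $\hat p$ computed
from allele counts (ploidy-aware: a male contributes one X copy), the
per-site estimators are

* $f_2(A,B) = (\hat p_A - \hat p_B)^2 - \hat h_A/n_A - \hat h_B/n_B$,
* $f_3(A,B;C) = (\hat p_C - \hat p_A)(\hat p_C - \hat p_B) - \hat h_C/n_C$
  (outgroup form, $C$ the outgroup),
* $f_4(A,B;C,D) = (\hat p_A - \hat p_B)(\hat p_C - \hat p_D)$,

where $\hat h = \hat p(1-\hat p)\,n/(n-1)$ is the unbiased within-population
heterozygosity and $n$ the number of called copies. The h-terms remove the
finite-sample bias of the squared terms; $f_4$ is already unbiased. Sites
where a requested correction is undefined ($n < 2$) are skipped and
counted, never silently imputed. A population represented by a single
diploid individual is legal throughout: its genotype is an unbiased
(if noisy) estimate of the population frequency.

Under a tree relating the four populations with $\{A,B\}$ separated from
$\{C,D\}$, $E[f_4] = 0$. With the outgroup fixed in the $A$ slot, gene flow
between $B$ and $C$ drives $f_4$ negative, between $B$ and $D$ positive —
these sign rules are verified against the simulator in the test suite.

### Block jackknife

Estimates are pooled as the global mean of per-site values; the standard
error comes from the weighted delete-one-block jackknife with block weights
equal to site counts (Busing-type weighting), over non-overlapping 5-Mb
windows keyed by `floor((pos - 1)/B)` per chromosome. With equal block
sizes the formula reduces exactly to the textbook unweighted delete-one
jackknife, and the implementation is tested against an explicit
leave-one-block-out recomputation at $10^{-12}$ tolerance. The 5-Mb default
follows standard practice for whole-genome f-statistics; any width can be
passed.

### The autosome-X contrast

`contrast_autosome_x()` computes the same f4 configuration on autosomal and
(masked) X blocks and compares the two sets of **raw within-block means**
with Welch's unequal-variance t-test. Raw block means rather than jackknife
pseudovalues are used deliberately: pseudovalues are a linearization device
for the pooled SE, while raw means keep the two samples' variances honest
and independent of the pooling step; at realistic block counts the two
choices give very similar p-values, but they are not identical, so the
choice is documented here. The direction label (`x_more_negative` /
`x_less_negative` / `none`) follows the sign of the difference in block
means; `none` is reported only for an exactly zero difference.

X statistics should always be computed after masking the pseudoautosomal
regions and the 10-Mb window proximal to the PAR1 boundary, which shows
anomalous differentiation in empirical baboon-aligned data. These
assembly-specific intervals ship as the named preset `preset_mask("x_default")`
(data, not code), and the pipeline applies them by default.

### Admixture graphs

An admixture graph is a rooted DAG with drift lengths (f2 units) on tree
edges and a mixing proportion $\alpha$ at each two-parent node. Allele-
frequency covariance propagates from the root: a tree child adds its edge
length to its variance; an admixture child mixes its parents' rows
bilinearly with weights $(\alpha, 1-\alpha)$. Writing $a_e(\ell)$ for the
total mixture weight of the paths from leaf $\ell$ through edge $e$, the
leaf covariance is $V = \sum_e \mathrm{len}_e\, a_e a_e^{\top}$ — linear in
the drift lengths for fixed $\alpha$s. The fitter exploits this: the inner
problem (drift lengths, nonnegative) is solved exactly by nonnegative least
squares and only the $\alpha$s are searched with seeded multi-start
bounded optimisation, weighting each observed statistic by $1/\mathrm{SE}^2$.
The observed basis is all pairwise f2 plus all outgroup-f3 statistics —
the qpGraph-class information content with diagonal weighting, which stays
stable at small block counts where a full jackknife covariance inverse
would not.

Three structural non-identifiabilities are handled explicitly rather than
hidden:

* only the *sum* of the two root-child edge lengths is observable; the
  first is pinned at 0 during fitting (root placement is a convention);
* pre- versus post-admixture drift on the recipient lineage trades off as
  $(1-\alpha)^2\,\mathrm{len}_{pre} + \mathrm{len}_{post}$; fitted edge
  vectors are therefore compared through predictions, not raw values;
* **an admixture proportion is not identifiable from f-statistics when the
  donor lineage is an unsampled dead end in a 4-leaf graph** (6 observable
  f2 degrees of freedom against more free parameters: the optimizer finds a
  zero-score ridge with arbitrary $\alpha$). The minimal identifiable
  configuration samples the donor-side split on both sides — outgroup plus
  four populations. All graph analyses and recovery claims in this package
  use that configuration, and `nuclear_swamping_scenario(sample_donor_sister
  = TRUE)` provides it.

Greedy search (`greedy_edge_addition()`) inserts candidate admixture events
between midpoints of every acyclic ordered pair of drift edges, refits each
candidate (warm-started from the incumbent, so the score never increases),
and keeps the one that most reduces the worst standardized f4 residual,
stopping at `z_stop` (default 3, i.e. deviations within ~3 SE of treeness
are accepted as fit).

`refit_admixture_on_x()` freezes the autosomally inferred graph —
topology *and* drift lengths — and re-estimates only the admixture
proportions on the X basis. That is the fixed-graph comparison implied by
an admixture graph annotated with a single (autosomal) drift scale and
per-class admixed fractions, and it is the statistically cleaner contrast:
every autosome-X difference is attributed to the mixing proportions rather
than being partly absorbed by refitted drift. An `alpha_and_drift`
sensitivity mode also refits drift (X drift genuinely differs — X effective
size is about 3/4 of the autosomal one) but is noisier on X-sized panels,
because the freed drift parameters trade off against the proportions.

### Distances and trees

`ibs_distance()` is the 1-IBS metric (mean shared-allele proportion
subtracted from 1) over co-called diploid autosomal sites; X sites are
excluded by default because mixed ploidy puts per-site sharing on an
inhomogeneous scale. Neighbor joining and outgroup rooting are delegated to
\pkg{ape} (negative branch lengths clamped to zero with a warning); on
additive matrices NJ provably recovers the generating tree exactly, which
the tests assert on a fixture set of 4- and 5-taxon trees.

## The simulator and what it emulates

`simulate_genotypes()` is a frequency-level forward Wright-Fisher engine: a
demographic model is a timeline of splits, sex-specific pulses, and
continuous sex-specific migration over populations of diploid size $N$
(1:1 sex ratio). Each generation, migration updates recipient frequencies
deterministically, $p \leftarrow (1-w)p + w\,p_{donor}$, with class-specific
weights from copy counting:

$$ w_A = \tfrac{m_f + m_m}{2}, \qquad w_X = \tfrac{2m_f + m_m}{3}, \qquad
   w_{mito} = m_f, $$

and drift resamples each class binomially with copy numbers $2N$ (autosome),
$\lfloor 3N/2 \rfloor$ (X), $\lfloor N/2 \rfloor$ (mitochondria); $N = \infty$
freezes a population (the zero-drift limit). Purely male-mediated flow
($m_f = 0$) therefore hits the X at exactly 2/3 the autosomal rate — the
mechanical core of the nuclear-swamping signature. Terminal sampling draws
genotypes binomially at the final frequencies with per-sample ploidy
(hemizygous male X). A truth record tracks the realized ancestry
decomposition per population and class; because migration acts
deterministically on frequencies, cumulative donor ancestry equals
$1-(1-w)^t$ exactly.

Design choices, made once as the package's study conditions:

* **Frequency-level, no linkage.** f-statistics depend only on population
  allele frequencies, so individual genealogies are unnecessary at this
  scale. Loci are independent, which means jackknife blocks are independent
  by construction and block-jackknife SEs are exact-to-conservative here;
  on real genomes linkage makes the blocks the *reason* for the jackknife.
  Passing tests therefore validate the estimators and the inference logic,
  not LD robustness.
* **Panel layout.** 10,000 autosomal loci on 20 chromosomes and 4,000 X
  loci at 25-kb spacing, giving 60 autosomal and 20 X jackknife blocks of
  5 Mb. The spacing was chosen so the 5-Mb partition yields a healthy block
  count (>= 50 autosomal blocks); the X panel is sized so the X block count
  supports a block-level Welch test (empirical X SNV panels are vastly
  larger, so this under- rather than over-states real X information).
* **Ancestral frequencies** from Beta(0.8, 0.8) truncated to [0.05, 0.95]:
  a polymorphism-rich spectrum resembling a complete-case SNV panel
  (complete-case calling across many samples strongly depletes rare
  alleles); a uniform option exists.
* **Scenario presets.** $N = 500$, split depths up to ~160 generations,
  swamping migration $m_m = 0.05$ per generation for 30 generations
  (cumulative autosomal donor ancestry $\approx 0.53$, X $\approx 0.40$),
  5 female + 5 male samples per population. The sources that motivate the
  swamping scenario never quantify its strength or duration, so these are
  calibration choices — exposed as arguments, documented here, and not
  claims about any real species' history. They were fixed a priori by a
  power calculation (block counts and drift depths chosen so the contrast
  test has ~90% power at the preset effect size), not tuned against test
  outcomes.
* **No mutation, selection, recombination, or Y chromosome**; standing
  variation only. Mitochondria are a token single-locus class used to
  verify the "recipient keeps its original maternal lineage" property.

## Numerical conventions and degenerate inputs

* VCF positions are 1-based; masks are BED-style 0-based half-open;
  conversion happens exactly once, at read time.
* Heterozygous male X calls default to missing-with-warning (upstream
  callers emit them); a strict mode errors instead.
* Mitochondrial sites are carried through the data model but refused by
  f-statistics (mito history is a tree/haplotype question, not a
  frequency-moment one).
* Complete-case filtering is the default missing-data policy (matching
  joint-called, all-samples-genotyped panels); skipping it gives per-site
  pairwise-complete counting, since allele counts are accumulated over
  called samples per site.
* A zero jackknife SE yields a flagged sentinel (`zero_se`), never a
  numeric Z used downstream; fewer than 2 blocks is an error.
* Welch's test on two zero-variance samples reports the degenerate flag
  with p = 1 (equal means) rather than erroring mid-pipeline.
* In `enumerate_f4()` each unordered triple is reported in its
  best-fitting orientation (smallest |Z| of the three topologies, ties
  broken lexicographically) and Bonferroni correction is applied across
  the enumeration — the only multiple-testing scheme offered, matching
  standard practice for this family of screens.
* Non-finite per-site statistic values abort with a site-identified error.

## What the acceptance checks compute

`scripts/acceptance.R` regenerates every headline quantity from scratch
with the installed package: the 220-configuration enumeration and
7 within-population pairs on the 17-sample panel, the jackknife-oracle
discrepancy, treeness-null calibration, gene-flow sign rules, the exact
2/3 X/autosome pressure ratio and the ancestry ordering, swamping-contrast
power, admixture-proportion recovery and its X deficit, NJ recovery on
additive fixtures, and the Wright-Fisher closed-form drift check. Replicate
counts are scaled to desk hardware (30-100 replicates per property, stated
per entry in the JSON); the test suite runs the same properties at the
scales given in `tests/testthat/test-acceptance.R`.

## Known limitations

* No linkage disequilibrium anywhere in the simulator; LD-aware block
  sizing cannot be studied with it.
* The graph fitter uses diagonal (per-statistic) jackknife weights, not the
  full covariance; scores are comparable between nested models but are not
  calibrated chi-squared deviances.
* Per-parameter flatness flags catch isolated unconstrained parameters but
  not multi-parameter ridges (the two structural ridges above are handled
  by convention instead).
* Greedy edge addition explores single insertions ordered by worst-residual
  reduction; like all greedy graph searches it can settle on a
  historically wrong but statistically adequate placement when several
  placements fit equally well.
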