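---
title: "Detecting selection through locus-specific demographic parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection through locus-specific demographic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lsdscan)
```

## The idea

Genome scans usually hunt for loci whose summary statistics (F~ST~,
Tajima's D, ...) are outliers against the genome-wide distribution.
`lsdscan` takes the complementary route: it fits an explicit demographic
model and asks, locus by locus, whether the *demographic parameters* a
locus implies are compatible with the neutral, genome-wide estimate.
Divergent selection between two populations connected by gene flow purges
immigrant alleles at the selected site, which depresses the *effective*
migration rate at that locus relative to the neutral rates. Deviations of
the locus-specific reciprocal migration rates (M~12~, M~21~) from their
neutral point estimate are therefore the detection signal, and because
migration is directional, the *asymmetry* of the deviation carries
information about where selection acts — separating symmetric antagonistic
pleiotropy from conditional neutrality or asymmetric trade-offs.

The scan proceeds in two steps:

1. Per-locus posteriors $\pi_l(\theta)$ of $\theta = (\log_{10} M_{12},
   \log_{10} M_{21})$ are obtained by approximate Bayesian computation for
   every locus, from a single shared reference table of neutral
   coalescent simulations. The neutral point estimate is
   $\hat\theta = \arg\max_\theta \sum_l \log \pi_l(\theta)$ over the loci
   designated as putatively neutral (the product-of-densities rule, which
   is robust to a moderately contaminated neutral set because density
   multiplication follows majority rule).
2. Every locus is scored by $p_l = 1 - h_l$, where $h_l$ is the mass of
   the smallest highest-posterior-density region of $\pi_l$ containing
   $\hat\theta$. Under the null — a locus that truly evolved at
   $\hat\theta$ — $p_l$ is (conservatively) uniform, so it is used as a
   p-value. The asymmetry mass $\sigma_l = P[\log_{10}M_{21} -
   \log_{10}M_{12} < \log_{10}\hat M_{21} - \log_{10}\hat M_{12}]$ and its
   log-odds $a_l = \ln(\sigma_l / (1-\sigma_l))$ quantify directionality;
   $a = 0$ is perfect symmetry.

## Demographic models and conventions

Models are lists of demes (diploid sizes, exponential growth rates),
a migration matrix, and timed events (size/growth/migration changes and
backward joins), so island, isolation-with-migration, bottleneck-growth
and hierarchical divergence histories are all expressible. Conventions
that matter:

* **Migration is backward and scaled as `M = N m`**: `M[i, j]` is the
  expected number of lineages in deme *i* per generation whose parent is
  in deme *j*, so each backward lineage migrates at rate `m_ij = M_ij /
  N_i`. The forward simulator uses the matching gamete-pool fractions
  `M_ij / N_i`; the two conventions coincide to first order for
  conservative migration.
* **Events are half-open backward**: an event at time *t* applies to all
  times `>= t`.
* **Time is in generations before present; sizes are diploid** (haploid
  sample counts are twice the sampled individuals).

The genealogy simulator is a continuous-time exponential race (Hudson
algorithm); under exponential growth the total rate is a sum of
exponentials in *t* and event times are drawn exactly by thinning on
bounded windows. Infinite-sites mutations are Poisson on total branch
length with uniform positions in `[0, 1)`.

## The ABC machinery

**Statistics.** Per population: segregating sites *S*, private *S*,
nucleotide diversity π, Watterson's θ~W~, Tajima's D, and a 4-bin unfolded
site-frequency spectrum; per pair: Hudson's F~ST~ (`1 - mean(pi_A, pi_B) /
pi_between`, clamped to `[-1, 1]`) and per-site D~XY~; plus total *S* and
π. π, θ~W~ and *S* are per-locus window statistics; D~XY~ is per site.
Undefined values (Tajima's D at `S = 0`, F~ST~ at zero between-population
diversity) stay `NA` and propagate — they are never silently zeroed. The
exact SFS encoding used as an ABC statistic is this package's documented
choice (binned, unfolded, 4 equal bins), as is Hudson's F~ST~ estimator;
both are configurable.

**PLS reduction.** Statistics are standardized and rotated by a partial
least squares regression of the focal parameters on the statistics
(`mixOmics::pls` behind `fit_transform()`); retention distances are
Euclidean in component space, which makes them invariant to affine
rescaling of any raw statistic. The default component count is `4 x
#focal = 8`, not the smaller `2 x #focal`: with two reciprocal migration
rates the first few components capture the *magnitude* of gene flow
(which dominates covariance), and resolving its *direction* — needed for
an accurate neutral-estimate ratio and hence for asymmetry inference —
requires the weaker components loading on between-population contrasts of
private S, the SFS bins and Tajima's D. With four components the
recovered neutral ratio wobbles by a couple of grid cells on symmetric
truths; with eight it is stable.

**ABC-GLM posterior.** For each locus the `n_ret` closest simulations
(default 1% of the table with a floor of 1000) are retained and an
ordinary-least-squares linear-Gaussian model `s = c0 + B theta + eps`
with ridge-regularized residual covariance is fitted. The posterior on a
33 x 33 grid of cell centers over the prior box is

$$\pi_l(\theta) \propto N(s_{obs};\, c_0 + B\theta,\, \Sigma)\;
  \left[(1-\varepsilon)\, N(\theta;\, m_t, S_t) + \varepsilon\,
  \mathrm{Unif}(\mathrm{box})\right],$$

where `(m_t, S_t)` are the moments of the retained parameter values —
the Gaussian approximation of the retention-truncated prior that the
ABC-GLM algorithm prescribes — and the defensive uniform floor
(`eps = 0.25`) keeps tail coverage honest in directions the statistics
barely identify. The truncated-prior factor matters: the likelihood
surface of reciprocal migration rates has a curved ridge (statistics
respond mostly to the larger of the two rates), which a linear-Gaussian
likelihood alone cannot bend around; the retained-set Gaussian carries
that geometry. Without it the product-of-densities estimate drifts to a
corner of the prior box; with a pure Gaussian (no uniform floor) the
posterior under-covers weakly identified tails and fails
simulation-based calibration. All density arithmetic is in log space
with a `1e-300` floor, so heavy underflow can never produce an all-zero
grid. The conjugate-normal oracle in the test suite uses the
`prior = "uniform"` mode, where the grid posterior must match the closed
form to total variation < 0.01.

**Numerical tie rules.** `h_l` sums cells *strictly* denser than the
cell of $\hat\theta$, so a perfectly flat posterior gives the
conservative `p = 1`. Asymmetry boundary cells (exactly on the neutral
ratio line) contribute half their mass — the continuum integral puts
zero measure there, and the half-mass rule makes an exactly symmetric
posterior give exactly $\sigma = 0.5$. $\sigma$ is clamped to
`[1e-6, 1 - 1e-6]` before the (natural-log) logit. Ties in
`estimate_neutral()` break toward the smallest column-major cell index;
ties at the retention cutoff break by row index.

## The validation simulator

Pseudogenomes emulate the validation design: `n_n = 1000` neutral + `n_s
= 50` selected loci of 5 kb (5.25 Mb total) by default, desk-scale runs
use 200 + 50. Neutral loci come from the coalescent engine; selected
loci from an individual-based forward Wright-Fisher simulation of all
`2N_i` haplotypes with infinite-sites mutation, whole-haplotype
migration, and selection through a biallelic site fully linked to the
locus. The genotype fitnesses default to `(1 + s1, 1, 1)` in environment
1 and `(1, 1, 1 + s2)` in environment 2 for `(AA, Aa, aa)` — the
homozygote-advantage table; a `dominance` switch makes the favoured
allele dominant instead. The package exposes both because the two
parameterizations circulate in the local-adaptation literature and they
differ at low allele frequency.

Implementation points worth knowing:

* **Rescaling.** Forward simulation at `N = 10,000` is wasteful; desk
  runs rescale by the smallest integer λ with `N/λ <= 1000` (λ = 10 for
  the default model): `N -> N/λ`, `t -> t/λ`, `s -> sλ`, `mu -> muλ`,
  with `4Nmu`, `Ns`, `Nm` (= M) and `t/N` invariant. Rescaling is
  refused when it leaves the diffusion regime (`sλ > 1` or forward
  migration fractions above 1).
* **Burn-in** runs `20 x N/λ` neutral generations from a monomorphic
  founder population before the selected variant is introduced —
  several times the expected total tree depth of the two-deme systems
  used here, and verified against the coalescent by distributional
  (Kolmogorov-Smirnov) tests on per-locus statistics.
* **Survival conditioning.** The derived allele must not be lost
  system-wide at sampling ("not lost": segregating or fixed somewhere;
  a strict "segregating" rule is available). Each forward generation
  factorizes into a binomial draw of the deme's derived-allele count
  followed by a class-level multinomial conditioned on it, so the
  derived-allele path is an autonomous Markov chain that can be
  pre-simulated and rejection-resampled in microseconds; the haplotype
  process is then simulated conditional on the accepted path. This
  reproduces the conditioned-simulation semantics at a cost that allows
  a resample cap of 10^4; the power-evaluation grid uses a cap of 2000,
  i.e. regimes with conditional survival probability below ~1/2000 are
  reported as loss regimes ("derived allele is always lost"), never
  silently skipped.
* **Standing variation** initializes the derived allele at frequency
  `f` on haplotypes drawn at random after burn-in; the allele's age
  before the onset of selection is *not* modelled. **De novo**
  variants start as a single copy in deme 1. Conditioning restarts
  replay from the post-burn-in state rather than re-running burn-in.
* The forward haplotype simulator requires constant demography (the
  trajectory simulator handles the general time-resolved model); all
  validation regimes in this package use the constant two-deme model.

What the generator does *not* emulate: within-locus recombination (loci
are single genealogies by construction), linked selection across loci,
soft sweeps with recurrent mutation, sequencing error in the haplotype
path, and any uncertainty in the assumed demographic model itself.
Passing power checks on these pseudogenomes therefore demonstrates the
statistical machinery under a correctly specified model at desk scale,
not performance on real short-read data.

## Choices made at open points

* True parameter values of the validation models beyond the two-deme
  case are not pinned down here; fixtures use `N1 = N2 = 10,000`
  diploids — a package choice, not an external given.
* Sample configuration defaults to 20 diploid individuals (40
  haplotypes) per deme, a typical population-genomic sampling depth.
* Pool-seq emulation draws per-site depths from a negative binomial
  (mean 30, dispersion 5 by default), derived reads binomially, pools
  `2 x` individuals haplotypes, and applies a 2-read minimum count per
  allele before a site counts as polymorphic (anti-singleton-noise);
  zero-depth sites are missing and excluded.
* The HPD region is computed on the joint 2-D grid (matching the
  2-D highest-density-region credible contours used for reporting),
  not on marginals.
* Problem sizes for routine runs: 50,000 reference simulations,
  1000-row retention, 33 x 33 grid, 200 + 50-locus pseudogenomes,
  rescaling to `N' = 1000`. All are configuration, not constants.

## Known limitations

* Detection is specified through migration-rate deviations only;
  deviations in effective size (sweeps within a single population) are
  expressible in the model but not wired into the scan score.
* The desk-scale loss-regime threshold (survival < ~1/2000 under
  conditioning) is coarser than a conditioned simulator that samples
  arbitrarily rare surviving trajectories; truly marginal regimes near
  the threshold may flip between "loss" and "evaluated" across seeds.
* The linear-Gaussian likelihood with a truncated-prior factor is an
  approximation; per-locus posteriors are calibrated in rank
  (simulation-based calibration at α = 0.001) but individual posterior
  shapes inherit the smoothing of the GLM.
* Genotype-likelihood (low-coverage) data paths and LD-based statistics
  are out of scope.
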