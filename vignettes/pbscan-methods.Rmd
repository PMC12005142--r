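---
title: "Methods: genotype-likelihood population genetics and the PBS scan"
author: "pbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood population genetics and the PBS scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbscan)
```

# Why genotype likelihoods

At ~2x sequencing coverage, per-individual genotype calls are unreliable:
most sites see zero, one or two reads per individual, and a single read
cannot distinguish a heterozygote from a homozygote. pbscan therefore never
hard-calls genotypes on the analysis path. Every stage — allele frequency
estimation, the site frequency spectrum, FST, the selection scan, admixture
and PCA — consumes per-genotype likelihoods and integrates over genotype
uncertainty. The package targets the common three-population design: a
focal population scanned for selection against two related reference
populations.

# The likelihood model

For a biallelic site with declared major and minor alleles, the likelihood
that an individual carries $g \in \{0,1,2\}$ copies of the minor allele is
the independent-error allele-sampling product over its reads,

$$L(g) = \prod_r \left[(1 - g/2)\, e(b_r \mid \text{major}) +
 (g/2)\, e(b_r \mid \text{minor})\right],
 \qquad e(b \mid a) = \begin{cases}1-\epsilon_r & b = a\\
 \epsilon_r/3 & b \neq a,\end{cases}$$

with $\epsilon_r = 10^{-q_r/10}$ from the read's Phred quality. Reads below
the base-quality minimum (default 20) or carrying a third allele are
discarded first; a mapping-quality minimum (default 30) applies when the
pileup carries that column. Triples are stored max-rescaled (Beagle
convention), and an individual with no surviving reads is the uninformative
triple $(1,1,1)$. This is the standard model behind the "GATK" genotype
likelihood as implemented by ANGSD's `-GL 2`.

Minor-allele frequencies come from a per-site EM under Hardy-Weinberg
proportions ($f_0 = 0.1$, tolerance $10^{-6}$ on $f$, at most 100
iterations). Downstream structure analyses use sites with MAF strictly
greater than 0.05, mirroring common practice; the comparison is strict, so
a site at exactly the threshold is removed.

# Site filters

Three snpCleaner-style predicates run before analysis, as independent
per-site filters:

* **coverage**: at least $k = 10$ individuals with at least $u = 1$ read;
* **heterozygote excess**: one-sided exact Hardy-Weinberg test using the
  Levene-Haldane distribution of the heterozygote count conditional on the
  minor-allele count; fail below $10^{-6}$. The one-sided direction (excess
  only) targets collapsed paralogs, which inflate heterozygosity; a deficit
  is left alone. Genotype counts come from hard calls at posterior
  $\ge 0.95$ under the site's MAF-HWE prior, with uncalled individuals
  excluded — a self-contained rule at low coverage where an external caller
  is unavailable.
* **strand bias**: two-sided Fisher exact test (minimum-likelihood rule, as
  in base R's `fisher.test`) on the major/minor x forward/reverse table;
  fail below $10^{-4}$.

Read-level bias tests that need alignment metadata (base-quality bias,
mapping-quality bias, end-distance bias) and accessibility/mappability
masks are outside the package's data model and are not implemented.

# SAF, SFS, and FST

Per population, the sample allele frequency (SAF) likelihood
$L(j)$ of $j$ minor alleles among $2N$ chromosomes is computed by the
dynamic program
$q_i(j) = \sum_g q_{i-1}(j-g)\,GL_i(g)\binom{2}{g}$, finishing with
$L(j) = q_N(j)/\binom{2N}{j}$. Rows are renormalized after each individual
so only relative likelihoods (which are what every downstream expectation
uses) are retained; this avoids underflow at large $N$ without log-space
bookkeeping.

The joint 2D spectrum $\eta(j,k)$ of two populations is estimated by EM
from a uniform start: the per-site posterior is
$P_s(j,k) \propto \eta(j,k) L_{1s}(j) L_{2s}(k)$ and the update is the
mean posterior across sites. Iteration stops at
$\max|\Delta\eta| < 10^{-8}$ or 500 iterations; the log-likelihood is
monotone and is checked in the tests at every iteration. Sites are treated
as independent (linkage is ignored, as in the genome-wide SNP setting the
method comes from).

Per-site FST components are posterior expectations of the Hudson/Bhatia
moment estimator with sample-size correction,

$$N(j,k) = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{2n_1-1} -
 \frac{p_2(1-p_2)}{2n_2-1}, \qquad
 D(j,k) = p_1(1-p_2) + p_2(1-p_1),$$

taken under $P(j,k)$ with the estimated spectrum as prior. Window and
genome-wide FST are the **ratio of sums** $\sum a / \sum d$, never the mean
of per-site ratios. The estimator family is a deliberate choice: the
upstream tooling this emulates cites Reynolds' moment estimator, which is
also a ratio-of-sums estimator of the same estimand; the Hudson/Bhatia
components have the cleaner closed-form relation to the simulator's drift
coefficients ((c_1+c_2)/2 for a pair), which the recovery tests exploit. A
Reynolds-mode could sit behind the same interface; no equivalence claim is
made.

# PBS and the peak-calling rule

With $T = -\log(1 - F_{ST})$, the population branch statistic for focal
population $i$ is $PBS_i = (T_{ij} + T_{ik} - T_{jk})/2$. Negative window
FST is clamped to zero before the transform (keeping $T$ real; the
unclamped FST stays in the window table for audit), and $F_{ST} = 1$ maps
to an infinite, flagged branch length.

The scan uses half-open windows $[\text{start}, \text{start}+W)$, 1-based,
starting at $1, 1+\text{step}, \dots$ per chromosome (defaults
$W = 50$ kb, step $= 10$ kb; a 1 kb / 500 bp zoom is the conventional
follow-up in candidate regions). Windows with fewer than `minSites`
(default 10; the source analyses state none, so this is the package's own
guard against ratio noise) are excluded from percentile ranking. Peaks are
outliers, not test statistics: windows with PBS strictly above the
empirical $1 - f$ order-statistic quantile (default $f = 0.001$) form the
top set; the highest top window seeds a peak and absorbs top windows
within 1 Mb (center-to-center) on its chromosome; clusters with at least 6
top windows are reported. "At least 6" resolves an internal ambiguity in
the source material in favor of the tabulated peaks (one of which has
exactly 6 windows). The reported position is the best window's start;
whether the upstream analyses report start or midpoint is not stated, so
this choice is documented rather than asserted.

# Admixture and PCA

The admixture model binds per-individual proportions $Q$ ($N \times K$,
rows on the simplex) and component frequencies $F$ through individual
allele frequencies $h = QF$ and the likelihood
$\prod_{i,s} \sum_g GL_{isg} \mathrm{Binom}(g; 2, h_{is})$. Optimization is
the standard multiplicative EM on expected allele-copy assignments
(NGSadmix-style) rather than a Newton-type optimizer: the contract carried
over from the emulated protocol is the likelihood model plus the
3-restart / 1000-iteration / best-likelihood selection, all preserved as
defaults. Frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ to avoid
absorbing states; the clamp is far outside the data-supported range for
MAF-filtered sites. Components are identifiable only up to permutation, so
reported tables pass through `alignLabels()`, which exhaustively maximizes
$\sum Q[, \pi] \cdot Q_\text{ref}$ over the $K!$ permutations.

PCA follows the iterated individual-allele-frequency scheme: expected
dosages under a HWE prior at the current $h$, standardization by the
global MAF, covariance $C = XX^\top/S$, then refreshed $h$ from the
projection onto the top $K-1$ eigenvectors (default $K = 3$, matching the
three-ancestry framing; 2 refinement cycles). With certain genotypes and
zero refinement cycles this reduces exactly to the classical standardized
dosage covariance, which is the complete-data oracle the tests use.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: a focal
population of 33 diploids at mean depth 2 (the emulated study reports
~1.95x) plus two reference populations (defaults 15 each), biallelic SNPs
with uniform ancestral frequencies on $[0.05, 0.95]$, Balding-Nichols
drift $p_i \sim \mathrm{Beta}(p(1-c_i)/c_i,\,(1-p)(1-c_i)/c_i)$, Poisson
read depth, uniform sequencing errors at $\epsilon = 0.01$ (all reads carry
Phred $-10\log_{10}\epsilon$, so the GL model's error rate matches the
generator exactly and oracles stay closed-form), Bernoulli(1/2) strands,
optional admixture via a true $Q$ matrix, and an optional sweep that
displaces the focal population's frequency by $p' = p + \delta(1-p)$
inside an interval. Positions are drawn uniformly without replacement and
sorted; coordinates are 1-based throughout; the major allele is the
ancestral-majority allele with ties broken toward the lexicographically
smaller base.

The default drift vector $(0.068, 0.020, 0.012)$ was fixed once so that
the expected pairwise FST $(c_i + c_j)/2$ reproduces the genome-wide trio
scale (0.044 / 0.040 / 0.016) typical of closely related South American
populations; no demographic parameters are available to emulate more
directly.

Balding-Nichols with independent sites was chosen over coalescent
simulation deliberately: the closed-form drift-FST relation gives analytic
acceptance checks, and independence matches the assumptions of the SFS
machinery. The cost is realism: the generator has **no linkage
disequilibrium or haplotype structure, no recombination map, no indels, no
real quality-score profiles, and no mapping artifacts**. Passing recovery
tests therefore demonstrate correctness of the estimators under their own
assumptions, not robustness to LD, batch effects or reference bias in real
data. The sweep model displaces frequencies site-by-site — a mean-shift
caricature of a sweep, sufficient for localization power tests but without
hitchhiking structure.

# Reproducibility and problem sizes

Every stochastic function takes a seed; `runPipeline()` fans a master seed
out to per-stage child seeds through a fixed affine map (`childSeed()`),
so stages are independently reproducible and reruns are byte-identical.

The validation suite runs at desk scale, chosen as the smallest sizes at
which the checked quantities are statistically decidable: FST recovery
uses 50,000 sites and 15+15 individuals over five seeds (band
[0.035, 0.065] around the estimand 0.05); the scan calibration uses a
10 Mb genome with 15,000 SNPs (1.5 SNPs/kb) and 15+15+15 individuals, 20
sweep and 20 null replicates, with the spectrum EM capped at 100-200
iterations (FST ratios stabilize long before the spectrum's tail bins do).
At 10 Mb the canonical top-0.1% rule cannot call any peak — 0.1% of ~996
windows is a single window, below the 6-window minimum — so the scan test
uses the smallest tail compatible with the rule, $f = 0.007$, keeping
every other element (window geometry, ≥6 windows, 1 Mb merge) unchanged.
At genome scale the 0.1% default stands.

# Degenerate inputs and numerical conventions

* Uninformative sites (all triples $(1,1,1)$) get `NA` MAF and are removed
  by `filterMaf()` whatever the threshold.
* All-zero SAF rows (possible only through external input) are excluded
  from the spectrum EM with a warning.
* $\sum d = 0$ windows and windows under `minSites` report `NA` and never
  enter the percentile pool.
* The peak threshold is the type-1 (order statistic) quantile; comparison
  is strict, so threshold ties fall out of the top set together.
* Beagle alleles are coded A,C,G,T = 0,1,2,3; marker ids are
  `chrom_pos`, split on the last underscore so chromosome labels may
  contain underscores. VCF output is v4.2 with a log10-scaled `GL` FORMAT
  field; multiallelic or non-SNP records are rejected on read.

# Known limitations

Major/minor alleles are taken as declared inputs, never inferred from the
data; there is no SNP discovery. The SAF convention (binomial
within-individual weights, hypergeometric normalization) is validated
against its own enumeration oracle — published variants differ and no
equivalence to any specific external implementation is claimed. The
spectrum EM is plain (unaccelerated) EM; very large $N$ would warrant an
accelerated variant. PBS significance is by outlier ranking only; no
p-values are attached, and haplotype-based statistics are out of scope.
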