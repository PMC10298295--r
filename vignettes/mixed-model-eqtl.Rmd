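---
title: "Mixed-model eQTL scanning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model eQTL scanning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlmeqtl)
```

# The model

`mlmeqtl` tests the association between a single genetic variant and one
gene's (already normalized, standardized) expression under a mixed linear
model with a polygenic random effect:

$$ y = x\beta + g + \epsilon, \qquad
   g \sim N(0,\, G\sigma_g^2), \qquad \epsilon \sim N(0,\, I\sigma_e^2), $$

where $y$ is the $n$-vector of expression values, $x$ the minor-allele
dosage (0/1/2) of the candidate variant, $\beta$ its fixed effect, and $G$
the $n \times n$ genomic similarity matrix

$$ g_{jk} = \frac{1}{n_v} \sum_{i=1}^{n_v}
   \frac{(\tau_{ij} - 2f_i)(\tau_{ik} - 2f_i)}{2 f_i (1 - f_i)}. $$

The polygenic term absorbs expression covariance due to genome-wide
relatedness, which otherwise inflates single-variant test statistics and
produces spurious eGenes. Two modeling choices matter here:

* **Leave-one-chromosome-out (LOCO).** For each candidate variant, $G$ is
  rebuilt excluding every variant on the candidate's chromosome. Variants in
  LD with the candidate would otherwise let the random effect absorb part of
  $\beta$ and deflate the test. A scan builds each LOCO matrix (and its
  eigendecomposition) once per chromosome and reuses it across pairs.
* **An intercept is always included** even though the model above has none:
  expression is consumed standardized, so the intercept is $\approx 0$, but
  keeping it protects against inputs that are shifted rather than strictly
  standardized. It changes nothing when $y$ is truly centered.

Allele-frequency conventions: dosages always count the *cohort minor*
allele ($f \le 0.5$), re-orienting on input; $f_i$ in the similarity matrix
is taken from the analysis sample itself (no external reference panel), and
missing dosages are mean-imputed to $2f_i$, which contributes zero after
centering. A consequence worth knowing: with sample frequencies the rows of
$G$ sum to zero exactly, so $G$ is always singular — the Henderson solver
detects this and switches to the equivalent GLS form.

# Estimation and testing

**Variance components** are estimated per (variant, gene) pair by restricted
maximum likelihood using the average-information (AI) algorithm. The model
is rotated by the eigenvectors of $G$ so the covariance is diagonal and each
iteration costs $O(np^2)$; the optimum is identical to dense evaluation of
the restricted likelihood (a test asserts this agreement, keeping the fast
path honest against the textbook formula). Numerical policy:

* start values $\sigma_g^2 = \sigma_e^2 = \mathrm{Var}(y)/2$;
* components floored at $10^{-6}\,\mathrm{Var}(y)$ ("bending");
* each iteration proposes the AI step, step-halved AI steps, and an EM
  fallback, and accepts the best; when a proposal touches the floor, the
  exact constrained optimum along that boundary (a 1-D profile of the free
  component) is offered as well, because plain AI/EM iterations crawl near
  boundaries and can exhaust the iteration budget without converging;
* convergence when both the likelihood change and the parameter change fall
  below $10^{-8}$, with a cap of 100 iterations; accepted iterations never
  decrease the likelihood, and the convergence flag is truthful.

**Fixed effects** solve Henderson's mixed model equations at the REML
optimum, or the equivalent GLS closed form when $G$ is singular (always, for
sample-frequency GRMs; the two routes agree to machine precision whenever
both are defined, and a property test checks this on random instances).
At $\sigma_g^2$ on the floor the fit degenerates to ordinary least squares.

**The test** is a 1-df Wald chi-square $(\hat\beta/\mathrm{SE})^2$ with the
standard error from the $(X^\top V^{-1} X)^{-1}$ diagonal; a positive
$\hat\beta$ means the minor allele increases expression. P-values are kept
in $\log_{10}$ space as well, so magnitudes like $10^{-38}$ remain exact
rather than underflowing. The scan threshold defaults to $4 \times 10^{-5}$;
it is a configuration constant, not derived from a Bonferroni count, because
the number of effective tests it corresponds to is not recoverable from the
published description. The threshold is strict: a pair is retained iff
$p < \alpha$.

A likelihood-ratio alternative to the Wald test was considered and not
implemented; the Wald form is the convention of mixed-model association
tools and its calibration is verified by simulation (type-I error at
$\alpha = 0.05$ within binomial bounds over 1,000 null replicates with
polygenic background $h^2 = 0.4$, $n = 400$).

# Genotype QC and the signal funnel

Variants are filtered on two per-variant statistics:

* **Minor allele frequency** $(n_{Aa} + 2n_{aa})/2n$, folded to
  $\min(f, 1-f)$; variants with $f < 0.05$ are excluded.
* **Hardy–Weinberg equilibrium**, tested with the exact conditional test:
  given the allele counts, the p-value sums the probabilities of all
  heterozygote counts no more likely than the observed one. Probabilities
  are accumulated by recurrence outward from the conditional mode, which is
  numerically stable at any $n$ (a naive recurrence from the extreme
  overflows). Variants with $p < 10^{-6}$ are excluded. The exact test was
  chosen over the 1-df chi-square because it is well defined at the small
  counts the test suite exercises exhaustively ($n \le 20$ against full
  enumeration). A monomorphic table returns $p = 1$ by convention.

Exclusion is strict on both filters (the boundary value is kept), one fixed
convention for what the source describes both ways.

GWAS signals pass through a funnel: deduplication per (rsid, trait group);
panel filtering (absent / MAF / HWE, each drop logged with its reason);
exclusion of signals shared between the target trait and the contrast
group; and greedy $r^2$ pruning (drop a signal whose squared genotype
correlation with an already-kept same-chromosome signal exceeds 0.8,
iterating in input order). The independence criterion and its 0.8 default
are our operationalization — the source states that independent signals
were used without defining independence — so the threshold is exposed as a
parameter and the kept/dropped sets are reported. Every stage returns a
subset of its input and the counts compose exactly (40 target − 16 shared =
24 target-specific is an acceptance check).

# LD blocks

Haplotype frequencies for a variant pair are estimated from unphased
genotypes by EM over the double-heterozygote phase ambiguity (tolerance
$10^{-10}$, cap 1,000 iterations; with no double heterozygotes the estimate
is direct counting in one step). From the frequencies: $D' = |D|/D_{max}$
and $r^2$. The 90% confidence interval for $D'$ profiles the multinomial
log-likelihood on a fixed 101-point grid of $D' \in [0,1]$ (marginals held
at their EM estimates, sign of $D$ fixed at the point estimate), normalizes
the curve, and takes the cells where the cumulative crosses the 5th and
95th percentiles; both bounds include their crossing cell. The construction
is fully deterministic.

Blocks follow the Gabriel confidence-interval rule with the Haploview
default thresholds: a pair is *strong LD* if CI low $\ge 0.70$ and CI high
$\ge 0.98$, *strong recombination* if CI high $< 0.90$, otherwise
uninformative; a candidate span of $\ge 2$ consecutive markers (markers with
MAF $< 0.05$ skipped) is accepted when it has at least one informative pair
and $\ge 95\%$ of its informative pairs are strong LD. Overlapping
candidates are resolved deterministically: most markers first, ties by
leftmost start. Significant variants sharing a block collapse to one
independent eQTL signal indexed by the most significant member, and the
collapse is applied after thresholding.

# The synthetic cohort generator

The generator exists so every stage is testable without the original data.
It emulates exactly the structure the model assumes:

* biallelic genotypes in Hardy–Weinberg equilibrium (two independent
  haplotypes per individual) with population frequencies drawn uniformly
  from a configurable MAF range;
* block-wise LD by **ancestral copying**: each haplotype carries one latent
  ancestral allele per block, and every variant in the block copies it with
  probability $\sqrt{\rho}$, so any two variants in a block share the
  ancestral state with probability $\rho$. This makes within-block LD
  equicorrelated — the defining feature of a haplotype block, where $D'$ is
  uniformly high across all pairs. A first-order chain (each variant copying
  its predecessor) was tried first and rejected: its $D'$ decays as
  $\rho^k$ with marker lag, so the far pairs of a $\rho = 0.95$ block are
  classified as strong recombination and block recovery becomes a coin
  flip, which mis-states what the block finder does on block-structured
  data. $\rho = 0$ gives linkage equilibrium; $\rho = 1$ copies perfectly
  ($r^2 = 1$);
* expression from the generative model itself: $y = x\beta + g + \epsilon$
  with $g$ drawn from the *realized* LOCO similarity matrix of the
  simulated panel (eigenvalues floored at zero before factorization, since
  sample GRMs can be indefinite at small variant counts) — matching the
  model actually fitted rather than an idealized kinship;
* signal catalogs with configurable target/contrast sizes and overlap.

One seed determines every output byte-for-byte. The expression generator
reseeds at `seed + 1` so it is reproducible standalone. `sigma_e2 = 0` is
accepted as the noise-free limit used by degenerate-case tests.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: recombination-map LD decay, population
structure and admixture (individuals are exchangeable), genotyping error
and missingness mechanisms, the empirical distribution of RNA-seq residuals
after normalization (residuals here are exactly Gaussian), multi-variant
and multi-gene regulatory architecture, and trans-acting effect-size
distributions. Results on real cohorts additionally depend on normalization
upstream of this package (expression is consumed already normalized; the
residual-factor normalization used in the original study is out of scope).

# Problem sizes used by the tests

Simulation-based checks run at sizes chosen to estimate the relevant
quantity with useful precision while keeping the suite quick: parameter
recovery at $n = 500$ with a 2,000-variant GRM over 200 replicates
(interior-truth bias bound 0.05); null calibration at $n = 400$ over 1,000
replicates (binomial 95% band around 0.05); power at $\beta = 0.5$,
$f = 0.3$, $h^2 = 0.4$, $n = 400$; REML-vs-grid agreement on 50 instances
with $n \le 12$ (where the dense grid oracle is exact and cheap); HWE
against full enumeration for all tables with $n \le 20$. The
zero-heritability recovery cell is judged by its boundary pile (the
constrained estimator cannot center on zero), not by a mean-vs-truth
comparison.

# Known limitations

* Per-pair REML refits make a full transcriptome scan $O(\text{pairs})$
  REML problems; the chromosome-level eigendecomposition cache removes the
  $O(n^3)$ term per pair but large cohorts would still want the
  reuse-components approximation, which is not enabled by default.
* cis/trans is same-chromosome vs different-chromosome, with no distance
  window; a windowed definition would reclassify some far same-chromosome
  pairs.
* The Wald test at the REML optimum ignores variance-component estimation
  uncertainty, as is conventional; at small $n$ this is mildly liberal or
  conservative depending on the spectrum of $G$.
* No covariates are included by default (none appear in the model); the
  fitting interface accepts them.
* Sex chromosomes, multi-allelic sites, imputation dosages and phased
  shortcuts beyond the unambiguous-phase fast path are out of scope.
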