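---
title: "Windowed population-genomic scans on small resequencing panels"
author: "popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed population-genomic scans on small resequencing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

## The setting

`popgenscan` implements the population-genomic half of a typical crop
resequencing study: a few dozen diploid accessions of a highly selfing
species, mapped to a reference and called into a joint VCF, from which
one wants (i) a QC-filtered SNP set, (ii) genome-wide diversity
summaries (windowed π, per-individual inbreeding F), (iii) a windowed
Weir–Cockerham F~ST~ outlier scan contrasting phenotype-defined groups
(here: light vs dark seed coats), cross-checked between two independent
contrasts and intersected with gene annotation, (iv) a neighbour-joining
phylogeny with SNP-column bootstrap, and (v) a microsatellite census of
the reference for marker development.

The motivating system is Kersting's groundnut (*Macrotyloma
geocarpum*), a West African legume with exceptionally low genomic
diversity (roughly one SNP per 650 bp, against one per ~34 bp in
lablab and one per ~77 bp in cowpea), strong geographic clustering, and
inbreeding coefficients above 0.5 — but every statistic here is
generic and works on any multi-sample diploid VCF.

Because real resequencing data are far too large for unit tests, the
package carries a first-class simulator with known truth
(`sim_config()`, `simulate_genotypes()`, `generate_dataset()`); every
estimator is validated by parameter recovery against that truth and by
independent brute-force oracles.

## The generative model

The simulator uses the Balding–Nichols model: each site has an
ancestral allele frequency $p$ drawn uniform on
$[\mathrm{maf\_floor}, 1-\mathrm{maf\_floor}]$ (default floor 0.05, so
the MAF filter removes a predictable fraction), and each cluster $k$
draws its own frequency

$$p_k \sim \mathrm{Beta}\!\left(\frac{p(1-F_k)}{F_k},
\frac{(1-p)(1-F_k)}{F_k}\right),$$

which has mean $p$ and variance $F_k\,p(1-p)$. The expected pairwise
Weir–Cockerham F~ST~ between clusters $k$ and $l$ is close to
$(F_k+F_l)/2$. Genotypes within a cluster are drawn with an
identity-by-descent indicator per individual, giving
$P(\text{het}) = 2 p_k q_k (1-f)$ with inbreeding coefficient $f$.

Defaults mirror the study conditions the package is validated against:
three clusters of 8/8/10 samples, per-cluster $F = 0.1$ (pairwise
divergence in the 0.07–0.13 band), $f = 0.55$ (the 0.52–0.58 band),
13% of variants emitted as 1–5 bp indels, 2% missing calls, Poisson
read depths with mean 25, site qualities uniform on 15–500 (so a small
fraction fails Q > 20), and roughly one variant per 600 bp. The
simulator is deterministic given its seed, down to byte-identical VCF
output.

Divergent windows are *planted* by displacing cluster frequencies
inside an interval: contrast-A clusters move to $p + \delta(1-p)$,
contrast-B clusters to $p(1-\delta)$. $\delta = 1$ fixes opposite
alleles (window F~ST~ = 1); $\delta = 0$ is the identity. Planting at
$\delta = 0.8$ on an $F = 0.1$ background lifts a window far above the
genome-wide top-1% threshold.

What the simulator does **not** emulate: linkage/recombination
structure (sites are exchangeable draws), realistic indel length
spectra, allele-frequency ascertainment from real site-frequency
spectra, and sequencing error. Passing recovery tests therefore shows
the estimators are correct under the stated model, not that real-data
idiosyncrasies are handled.

## Filtering

`filter_sites()` applies, in a fixed order with first-trigger
attribution: site quality (Q > 20 retained), per-call depth (DP ≤ 10
set missing, so low-depth calls count toward missingness), indel
removal, biallelic-only, missingness (more than 3 samples missing →
removed; exactly 3 retained), and MAF (< 0.05 removed; exactly 0.05
retained — the inequalities are strict on both rules). MAF is computed
over non-missing alleles after depth masking. The operation is
idempotent, and removal counts always partition input − output.

`ld_prune()` mirrors PLINK's `--indep-pairwise 50 5 0.5`: sliding
windows of 50 SNPs advanced by 5, and within each window every pair
with dosage $r^2 > 0.5$ marks its *later* (higher-index) SNP for
removal. Marks accumulate across windows, so the result is independent
of traversal order and the retained set provably contains no
within-window pair above the threshold. Which SNP of a pair is dropped
is not specified by the upstream tools' documentation; the
higher-index rule was chosen for determinism (a MAF-based heuristic
would tie itself to filtering order). Zero-variance or
too-few-shared-sample pairs have undefined $r^2$ and are treated as
not in LD.

## Diversity statistics

Per-site diversity uses the unbiased pairwise form
$\pi = 2c(n-c)/(n(n-1))$ over $n$ called alleles with $c$ alternate
copies; `windowed_pi()` sums site values over 100 kb windows in 50 kb
steps and divides by the *window length in bp* (invariant positions
included), matching the 10^-3^-scale per-bp values reported by
vcftools' `--window-pi`. Dividing by variant count instead is not the
default. Trailing windows are emitted truncated to the chromosome end,
flagged, and included in means.

Per-individual inbreeding F uses observed vs expected homozygosity,
$F = (O - E)/(L - E)$, with the expected value per site taken as
$1 - 2c(n-c)/(n(n-1))$ — the same unbiased form, which is what
vcftools' `--het` uses. At $n = 60$ alleles the estimator carries a
small $O(f/n)$ downward bias (about 0.005 at $f = 0.55$), well inside
the ±0.03 recovery tolerance the tests assert.

`variant_spacing()` rounds half-up (469,291 SNPs over 306.4 Mb →
653 bp); `species_density()`/`diversity_ratio()` combine SNP and indel
densities so that cross-species comparisons can be reproduced directly
from printed spacings.

## The Weir–Cockerham scan

`wc_fst_site()` implements the 1984 variance-component estimator for
two groups of diploids ($a$ among groups, $b$ between individuals
within groups, $c$ within individuals), with the per-site estimate
$\theta = a/(a+b+c)$. Because the $h̄$ (observed heterozygote) terms
enter $b$ and $c$, the estimator remains centred on the among-cluster
$F$ under strong inbreeding — the recovery test runs at $f = 0.55$ and
still lands on $F = 0.13 \pm 0.02$. Negative per-site components are
retained, preserving the estimator's expectation; the windowed default
is the weighted ratio of sums $\sum a / \sum(a+b+c)$ (the standard
headline output of vcftools' windowed F~ST~), with mean-of-sites
available as an alternative. A weighted window value can slightly
exceed 1 when $b$ sums negative; values are deliberately not clipped.

Thresholding: the top-q set is the $\lceil (1-q)N \rceil$ largest
defined windows (ties included), and the reported threshold is the
largest value *not* in the set, so membership is exactly
"F~ST~ > threshold" — the convention that matches statements like
"the top 1% of windows had F~ST~ > 0.7790". Each top-1% window seeds a
region extended through contiguous top-5% neighbours (unbounded
extension; overlapping regions merge). Two contrasts are cross-checked
by ≥ 1 bp region overlap; the merged candidate is tier 1 when the
overlap contains a top-1% window of both contrasts, tier 2 for top-1%
of one and top-5% of the other, tier 3 for top-5% of both, and
untier-ed otherwise. Any top-5% window in the overlap counts (it need
not be a flank of that contrast's own seed region). Gene intersection
and locus checks use 1-based inclusive coordinates with ≥ 1 bp
overlap.

A deliberate pipeline choice: windowed π/F~ST~ and the scan run on the
full QC-passed SNP set, while the LD-pruned subset feeds only the
phylogeny. Pruning exists to de-correlate sites for tree and
clustering inference; a genuinely divergent window is internally in
strong LD, so pruning first would thin precisely the windows the scan
is built to find (in simulation, tier-1 recovery of planted windows
drops from 100% to roughly 90% when the scan is run on the pruned
set).

## Phylogeny

`p_distance()` computes pairwise genotype distances by allele-multiset
matching (for biallelic dosages, $|g_i-g_j|/2$ averaged over
jointly-called sites); identical heterozygotes are distance 0. The
convention of the upstream distance tool is not printed anywhere
authoritative, so the choice is documented and oracle-tested rather
than assumed. Triangle-inequality violations are possible and allowed.

`neighbor_joining()` is the Saitou–Nei algorithm with the
Studier–Keppler Q-criterion. Ties are broken toward the pair with the
lowest sorted subtree leaf labels, which makes the topology invariant
to input row order — necessary for the bootstrap-support
permutation-invariance property. Negative branch lengths are clamped
to zero with the deficit moved to the sibling edge (path lengths
preserved); raw lengths are available via `clamp_negative = FALSE`.
On additive matrices the generating topology and branch lengths are
recovered exactly (tested to 10^-9^ on random 5–12 taxon trees, and
cross-checked topologically against an independent NJ implementation).

`bootstrap_support()` resamples SNP columns with replacement, rebuilds
the distance matrix and tree per replicate, and scores each internal
edge of the full-data tree by the percentage of replicates containing
the same leaf bipartition. A replicate that leaves some pair with no
jointly-called site is redrawn (capped at 100 retries). Rooting places
the root at the midpoint of the outgroup edge and re-maps supports by
bipartition, which rooting does not change.

## SSR mining

`find_ssrs()` reports maximal perfect tandem repeats of primitive
1–6 bp motifs with MISA-style minimum unit counts 10/8/6/4/4/4. A run
is reported once, at its primitive period (an `A`-run is mono, never
`AA`; `ATATAT` is di, never mono), which the Fine–Wilf periodicity
argument makes unambiguous at these run lengths. `N` never
participates; soft-masked lowercase is eligible. Partial trailing
units are trimmed (floor of run length over period). Compound and
interrupted repeats are out of scope. Motif classes are canonicalised
as the lexicographic minimum over cyclic rotations of the motif and of
its reverse complement.

## Numerical and degenerate-input choices

* Quantile set sizes use `ceiling((1-q)N - 1e-9)`: the epsilon guards
  against floating-point excess in `(1-q)*N` (0.01 × 100 is slightly
  above 1 in double precision, which would otherwise double the
  top-1% set).
* Sites where any group has no called genotype, or where `a+b+c = 0`
  (monomorphic across groups), return zero components and an undefined
  θ; windows with no usable site are excluded from quantiles.
* All-missing genotype columns give `NA` MAF/π and are removed by the
  missingness rule before any division can occur.
* Undefined $r^2$ (zero variance, < 2 shared calls) is "not in LD".
* `individual_f()` returns `NA` when $L - E = 0$.
* All internal coordinates are 1-based inclusive; only BED output is
  0-based half-open.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations so
each statistic is measured where its sampling error is well inside the
asserted tolerance: F~ST~ recovery at 50+50 samples × 5×10^4^ sites;
F recovery at 30 samples × 10^4^ sites; planted-window recovery over
100 seeded replicates (50 in the acceptance script) of a 5.1 Mb,
4×10^3^-site, 27-sample panel (~100 windows, so the top-1% set holds
exactly the two planted windows per contrast); bootstrap support at
16 samples × 800 sites × 200 replicates; oracle comparisons at
100–1000 random cases per operation.

## Known limitations

* The simulator draws sites independently; LD beyond the planted
  windows is absent, so LD-pruning behaviour on realistic haplotype
  structure is exercised only through duplicated-column fixtures.
* Plain NJ is implemented; tools that refine NJ topologies under
  balanced minimum evolution can differ on strongly non-additive
  matrices. Agreement is expected, not guaranteed, and is not assumed
  anywhere.
* Windowed statistics assign sites to windows by position only; a
  window containing a single usable SNP still yields an estimate, and
  downstream interpretation should weight by `n_snps`.
* Cluster π summaries default to sites polymorphic within the cluster
  (`within_only = TRUE`); the all-sites alternative is exposed because
  the upstream convention is ambiguous.
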