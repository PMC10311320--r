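---
title: "Mining significant genetic meta-markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining significant genetic meta-markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaminer)
```

## The problem

Complex binary phenotypes are rarely explained by a single variant. Under
*genetic heterogeneity*, mutations at different loci produce the same
phenotypic effect, so each individual marker carries a weak signal while
their aggregate carries a strong one. `metaminer` searches for such
aggregates — **meta-markers** — while keeping the family-wise error rate
(FWER) of the search under a user-chosen level $\alpha$.

A dataset holds $n$ samples with binary labels $y_i$, an optional categorical
covariate $c_i \in \{0, \dots, C-1\}$, and $L$ ordered genetic markers. In
*additive* coding a SNP counts minor alleles, $\phi(t) \in \{0, 1, 2\}$; in
*binary* coding $\phi(t) \in \{0, 1\}$. A marker can be binarized two ways:

* **dominant**: carrier iff $\phi(t) \ge 1$;
* **recessive**: carrier iff $\phi(t) = 2$.

A **pattern** spans one genomic interval per gene of a *gene interaction*
(a set of genes supplied as prior knowledge), with one encoding per gene;
all markers inside one interval share that gene's encoding, which keeps the
pattern class at $2^k$ encoding assignments per $k$-gene interaction rather
than $2^{\#markers}$. The pattern's value for sample $i$ is the OR over its
member markers' binarized values, and the samples where it is 1 form its
*support*.

### A note on the recessive encoding

Conventions for "recessive" binarization differ between sources; we fix it
as *carrier iff homozygous minor* ($\phi = 2$), the standard genetics usage.
This choice also makes every recessive support a subset of the same marker's
dominant support, which is what gives the encoding dimension of the pattern
class its partial order (flipping any gene's indicator from recessive to
dominant can only grow the support). A heterozygote-only ("overdominant")
third encoding would break neither the statistic nor the search and could be
added behind the same interface, but it is out of scope here.

## The association test

Association between a pattern's support and the labels is tested with the
Cochran–Mantel–Haenszel (CMH) statistic over the $C$ covariate strata. With
per-stratum margins $n_j$ (stratum size), $n_{1j}$ (cases), $x_j$ (pattern
carriers) and cell counts $a_j$ (case carriers),

$$T = \frac{\left[\sum_j \left(a_j - x_j n_{1j} / n_j\right)\right]^2}
{\sum_j x_j (n_j - x_j)\, n_{1j} (n_j - n_{1j}) / \left(n_j^2 (n_j-1)\right)},$$

referred to $\chi^2_1$. No continuity correction is applied — the discrete
testability machinery below requires the uncorrected statistic, and this
matches the convention of the significant-pattern-mining literature. Strata
with no variance ($x_j \in \{0, n_j\}$, $n_{1j} \in \{0, n_j\}$, or
$n_j \le 1$) contribute nothing; if every stratum is degenerate, $T = 0$ and
$p = 1$. With $C = 1$ the statistic reduces to $\frac{n-1}{n}$ times the
uncorrected Pearson $\chi^2$.

### Minimum attainable p-values

Because the test is discrete and conditions on the margins, each pattern has
a **minimum attainable p-value** that depends only on its support: $T$
depends on the $a_j$ only through $\sum_j a_j$, whose achievable extremes are
the corner splits $a_j^U = \min(x_j, n_{1j})$ and
$a_j^L = \max(0, x_j - (n_j - n_{1j}))$. The minimum attainable p-value is
the $\chi^2_1$ survival function at the larger corner statistic. Patterns
whose minimum attainable p-value exceeds the current threshold can never be
significant — they are *untestable* and need not count against the
correction (Tarone's argument).

### The descendant envelope

Every pattern generated from $P$ by extending intervals has a support that is
a superset of $P$'s, so descendant carrier counts live in the box
$x_j \le x'_j \le n_j$. The **envelope** is a certified lower bound on the
minimum attainable p-value over that whole box. If the envelope exceeds the
current threshold, no descendant can ever be testable and the subtree is
pruned.

We compute the bound by maximizing the two corner statistics over the
cartesian product of per-stratum candidate counts
$\{x_j,\ n_{1j},\ n_j - n_{1j},\ n_j\}$ (clamped to the box) — the kinks and
endpoints of the per-stratum corner statistics. Each single-stratum corner
statistic is unimodal in $x'_j$ with its maximum at one of these candidates,
which makes a *separable* Cauchy–Schwarz bound
($(\sum_j u_j)^2 / \sum_j v_j \le \sum_j u_j^2 / v_j$) provably valid; the
joint candidate-product search (the default, `envelope_tight = TRUE`) is
sharper and is validated against exhaustive enumeration of the full
descendant box in the test suite rather than assumed. The bound is
monotone along descent (the box only shrinks), so a pruning decision made at
the current threshold stays valid as the threshold later tightens.

## FWER control

Both procedures maintain a threshold $\delta$ on a geometric grid
$\delta_i = \alpha\, \gamma^i$ (default $\gamma = 0.9$; only "geometric" is
essential — finer ratios buy a slightly tighter final threshold for a little
more bookkeeping, and the grid resolution bounds how exactly two
implementations with different constants can agree).

* **Tarone**: maintain $\delta \cdot |T(\delta)| \le \alpha$ where
  $T(\delta)$ is the set of processed patterns with minimum attainable
  p-value $\le \delta$. Insertions can only grow $|T(\delta)|$, so once a
  grid level is infeasible it stays infeasible; the final threshold is the
  largest feasible grid value regardless of processing order.
* **Westfall–Young**: pre-draw $K$ label permutations (default
  $K = 10^4$; the calibration experiments use $K = 100$ for budget) and
  track, per permutation, the minimum p-value over all processed patterns.
  The threshold is the largest grid value at which the estimated FWER
  $\widehat{\mathrm{FWER}}(\delta) = \frac1K \#\{j : \min_P p_P^{(j)} \le \delta\}$
  stays $\le \alpha$. Internally the running minima are kept on the
  $\chi^2$-statistic scale (a running maximum per permutation), which avoids
  $K$ survival-function evaluations per pattern; the two scales are
  monotonically equivalent.

Permutations are drawn **within covariate strata**, preserving every
$n_{1j}$. This keeps all CMH margins fixed under permutation, so a pattern's
minimum attainable p-value and envelope are identical for the observed and
all permuted labelings — one testability/pruning decision covers all $K+1$
label vectors at once, which is what makes pruning sound in permutation
mode.

Patterns that appear in several interactions would be counted once per
canonical key; since interaction gene-sets are deduplicated and each
pattern class is keyed by its full gene set, identical hypotheses cannot in
fact recur, and the output is deduplicated defensively.

## The search

Per interaction and encoding assignment, the miner walks the interval
configurations breadth-first by total length. Level one holds all
single-marker-per-gene placements. A child extends exactly one gene's
interval one marker rightward, and gene $i$ may be extended only while all
lower-indexed genes still have length-1 intervals; under this rule every
configuration has exactly one generating parent, so no cross-level
deduplication is needed and, with pruning disabled, an interaction with gene
sizes $l_1 \dots l_k$ generates exactly
$\prod_i l_i (l_i + 1) / 2 \times 2^k$ patterns (additive mode). A child's
support is its parent's support OR one freshly binarized marker column;
supports are packed 64 samples to a machine word, so the OR and the
stratified counts are word-parallel.

Within a BFS level the state updates are batched: all of a level's
statistics are computed vectorized, the threshold is updated with the whole
batch, and the pruning test `envelope > delta` is applied at the
end-of-level threshold. Because the envelope is monotone and the threshold
only decreases, this prunes a (weak) superset of what strictly sequential
processing would prune at that point and provably never discards a pattern
that could still become significant — the oracle-equivalence tests confirm
the final threshold and discovery set are bit-for-bit those of an exhaustive
no-pruning search.

Only **closed** patterns are reported: a pattern is dropped from the output
(never from the correction) when some immediate interval-shrink leaves its
support unchanged, since the shorter pattern describes the same carrier set.
Closedness is assessed against interval-shrink predecessors within the same
interaction and encoding; encoding flips and gene drops belong to other
pattern classes (other interactions), which keeps the check $O(2k)$ per
reported pattern and matches the per-class definition of a sub-pattern.

An optional per-gene interval cap `max_interval_len` bounds the quadratic
blow-up in SNPs per gene; the calibration experiments set it to 3, the upper
end of the planted interval lengths.

## The synthetic-data generator

`simulate_dataset()` reproduces the study design used for calibration:

* a gene network from the Erdős–Rényi $G(n, m)$ model (defaults: 75 genes,
  100 edges);
* per-gene SNP counts uniform on $[3, 10]$; i.i.d. genotypes per marker with
  minor-allele frequency uniform on $[0.1, 0.4]$ (Bernoulli in binary mode,
  Binomial(2, maf) in additive mode);
* a planted meta-marker: a connected subgraph of `k_star` genes (default 3)
  grown by uniform random neighbor additions, one interval per gene with
  length uniform on $[1, 3]$ (these two constants are our documented
  choices), a single planted encoding, and the OR-aggregated carrier
  indicator $z_i$;
* labels: carriers are cases with probability $0.5 + \rho/2$; non-carriers
  with the probability $q$ that keeps the expected prevalence at $0.5$,
  so $\rho = 0$ makes labels independent of genotypes and the association
  grows monotonically with $\rho$;
* a covariate drawn independently of everything (uniform over 2 classes by
  default), so the CMH test is exercised with real strata under a null
  confounding structure.

Balancing requires $q \in [0, 1]$, i.e. $\rho \le (1 - \pi)/\pi$ for carrier
fraction $\pi$; with up to $3 \times 3$ planted markers OR-ed at these
allele frequencies, $\pi$ is often large and draws can be infeasible at
moderate $\rho$. The generator fails fast with the bound in that case, and
the power experiments draw replicates conditional on feasibility by
deterministic seed escalation — effectively conditioning the study on
planted patterns rare enough to be shiftable, which is also the regime in
which a case/control association study is informative. Where a whole
$\rho$ grid is compared, the same feasible seed is reused across the grid so
genotypes and truth are paired and only labels differ.

What the generator does *not* emulate: linkage disequilibrium (markers are
i.i.d., so there is no within-gene correlation structure), population
stratification or kinship (the covariate is independent noise rather than a
confounder), and quantitative phenotypes. Passing calibration on this design
therefore says nothing about robustness to LD-driven redundancy or to
confounding beyond what CMH conditioning removes; on real data the covariate
must actually encode the population structure (e.g. clusters on kinship
principal components) for the conditioning to do its work.

A `count_true_positives()` helper scores a mining result against the planted
truth by **marker-set overlap** — any significant pattern sharing a marker
with the planted set counts once. An exact-match rule would understate
partially recovered signals; overlap counting matches how hits are tallied
in the power experiments.

## Numerical and design choices

* Thresholds move only downward on the geometric grid; insertion uses the
  grid level of the minimum attainable p-value with a $10^{-9}$ relative
  epsilon so that values lying exactly on a grid point stay on it.
* Degenerate strata and all-degenerate tables short-circuit to $T = 0$,
  $p = 1$ rather than dividing by zero.
* Ties in the output are ordered by p-value, then by the pattern's canonical
  key (genes | encodings | intervals), so equal-p rows are deterministic.
* The problem sizes of the calibration suite (20–30 genes, 300–1000 samples,
  50–200 replicates, $K = 100$) are scaled-down versions of the full design;
  they were chosen as the smallest sizes at which the qualitative contrasts
  (power vs $\rho$, order $k$, encoding) are comfortably visible.
* `mine()` is deterministic given its inputs and `seed`; the permutation
  draw is the only source of randomness.

## Worked example

```{r example}
sim <- simulate_dataset(n_genes = 10, n_edges = 12, n_samples = 250,
                        k_star = 2, rho = 0.4, seed = 81)
ints <- connected_subgraphs(sim$network, k_max = 2,
                            nodes = names(sim$dataset$gene_map))
res <- mine(sim$dataset, ints, alpha = 0.05, fwer = "tarone")
glance(res)
head(tidy(res))
count_true_positives(res, sim$truth)
```

## Known limitations

* One encoding per gene interval: pinpointing a per-marker encoding is
  outside the pattern class (the general form explodes combinatorially and
  its correction obliterates power).
* Interactions are mined as given; the package enumerates connected
  subgraphs and filters protein complexes but does not select among them —
  that choice encodes domain knowledge and belongs to the user.
* FWER only; false-discovery-rate control would raise power for large
  interaction families but changes the guarantee.
* Missing genotypes are rejected, not imputed; imputation is preprocessing.
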