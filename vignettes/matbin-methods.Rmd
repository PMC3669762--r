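---
title: "Methods: composition-based binning and community statistics in matbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-based binning and community statistics in matbin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matbin)
```

# The problem

Shotgun metagenome assemblies of low-complexity communities — the motivating
case is high-temperature phototrophic microbial mats, where a handful of
populations (filamentous anoxygenic phototrophs, cyanobacteria,
purple-sulfur bacteria, Chlorobi) dominate — yield scaffolds whose source
organism is unknown. Oligonucleotide usage is species-characteristic:
scaffolds from one population share a "genome signature" in their 3–6-mer
frequencies that is far more discriminating than G+C content alone. matbin
bins scaffolds by that signature, summarizes the bins, relates community
structure to site geochemistry, and profiles functional-category abundance
across sites.

# Composition features

For each scaffold and each word length $k \in \{3,\dots,6\}$, all $4^k$
words are counted in sliding windows of step 1; windows containing any
non-ACGT symbol are skipped. Frequencies divide each count by the number of
**valid windows** $n_k$ of that length, so each per-$k$ block is an exact
probability simplex. The convention "normalize to scaffold length" leaves
the denominator ambiguous (raw length vs window count); we use valid
windows because it makes the simplex property exact on assemblies with `N`
runs, and for long N-free scaffolds the two differ by
$\mathcal{O}(k/L)$.

Strand handling: by default a word and its reverse complement are counted
separately (nothing indicates the original analyses pooled strands); a
`collapse_revcomp` flag pools each word with its reverse complement onto a
canonical key, which makes feature vectors exactly strand-symmetric and is
the common modern convention.

G+C content is $(G+C)/(A+C+G+T)$ with ambiguous bases excluded from both
numerator and denominator; a sequence with no unambiguous base has
undefined (NA) G+C. The G+C spectrum is a 1-percentage-point histogram over
$[0,100]$ (bin width configurable; the display resolution of read-level
spectra is not standardized), stratified by taxon label with an
"unassigned" stratum, and strata totals always conserve the input count.

# Consensus k-means binning

Scaffolds shorter than 10 kb are removed first (`min_scaffold_length`
default 10000): short scaffolds have noisy word frequencies, and the
analysis targets dominant, well-assembled populations.

One **trial** is a Euclidean Lloyd k-means run from a k-means++
initialization, governed entirely by a per-trial seed derived
deterministically from the master seed, $k$, and the trial index
(`derive_seed`). Design details that affect reproducibility:

* the Monte-Carlo trials *are* the restarts — one initialization per trial;
* assignment ties break to the lowest cluster index;
* a cluster emptied during iteration is re-seeded from the point farthest
  from its assigned center;
* each trial runs in a canonical row order (rows sorted by their sums, then
  leading coordinates) so that the seeded draws attach to *points* rather
  than input positions; permuting the input rows therefore permutes the
  output labels exactly, and the support matrix permutes identically.

The **support matrix** pools all `(k, trial)` runs:
$S_{ij}$ = fraction of runs in which $i$ and $j$ share a cluster. It is
symmetric with unit diagonal by construction. Whether the original analysis
required the support level at every $k$ separately or pooled across the
$k$ range is not stated; pooling is implemented because it yields a single
network, and single-$k$ mode (`k_values = 8`, the default, matching the
published network figure) sidesteps the question. Range mode
(`k_values = 4:12`) reproduces the methods-section protocol.

**Demarcation** builds a graph with an edge wherever
$S_{ij} \ge$ `support_threshold` (default 0.90) and reports connected
components with at least `min_cluster_size` (default 10) scaffolds;
smaller components are returned as unbinned. Components match the way such
support networks are displayed and read.

## Behavior you should expect (and what a green test shows)

With $k$ larger than the number of distinct populations, k-means *splits*
populations, and which split occurs varies per trial. Pairwise support
inside a population is then well below 1 for distant pairs — but
near-neighbours keep support ≈ 1, so connected components still recover
whole populations. Two consequences, both observed on the synthetic world
and asserted in the acceptance suite:

* clusters that do form are essentially pure (ARI 1.0 against planted
  labels over the clustered scaffolds), but a substantial fraction of
  scaffolds can remain unbinned at $k=8$ with only 3 planted populations;
* with *heavy* oversplitting (e.g. $k=8$ on 2 populations), support dilutes
  below the threshold everywhere and no clusters form at all. For the
  two-population recovery scenario we therefore run $k=4$, the low end of
  the conventional range. When the number of dominant populations is
  unknown, choose $k$ near (or below) your best estimate — consensus
  support degrades gracefully when $k$ is too small (populations merge into
  shared clusters at high support, still separable by threshold) and
  abruptly when $k$ is far too large.

The cluster count is *not* guaranteed monotone in the support threshold
once the minimum-size filter exists (a fragmenting component can
transiently produce two above-threshold pieces); what is guaranteed — and
property-tested — is refinement: raising the threshold never merges
clusters. The monotone count is nevertheless observed, and asserted, on the
stated synthetic world.

Bin summaries report the conventional units: scaffold count, median length
(kb), mean ± SD of per-scaffold G+C percent (sample SD, $n-1$), total
sequence (Mb), coverage mean ± SD when every member is annotated, site
composition, and the majority taxon label.

# Ordination

`pca` is covariance PCA (SVD of the column-centered matrix) — word
frequencies share a scale, so correlation scaling is off by default, with a
`scale.` flag for matrices whose variables differ in scale (e.g.
functional categories). Axis signs are fixed deterministically (largest
|loading|, or |score| for PCoA, positive) so plots and tests are
reproducible. Requesting more axes than the rank truncates with a message.

`pcoa` is classical metric scaling: Gower double-centering of
$-\tfrac12 D^2$, symmetric eigen-decomposition, scores
$v_j\sqrt{\lambda_j}$. Negative eigenvalues (possible for non-Euclidean
input such as Gower dissimilarities with missing data) are dropped, with
their summed magnitude recorded — the simplest defensible choice; no
Lingoes/Cailliez correction is applied.

# Environmental fitting

`gower_distance` implements the mixed-type coefficient: numeric variables
contribute $|x_i-x_j|/\mathrm{range}$, categoricals contribute 0/1
mismatch, and a variable's weight is zero for a pair when either value is
missing or the numeric range is zero; a pair with no comparable variable is
an error. Values below a detection limit, reported as `"<x"`, parse to
$x/2$ (midpoint substitution, recorded per cell), and `"nd"` becomes
missing.

`fit_env_variables` projects each variable onto ordination scores: numeric
variables score the squared multiple correlation of the least-squares
projection, factors the among-centroid fraction of the total score sum of
squares — both identical to the vegan `envfit` statistics, which the test
suite uses as an independent oracle. Significance uses the add-one
permutation estimator $p = (1 + \#\{r^2_{perm} \ge r^2\})/(1 + N_{perm})$
with 999 permutations by default, shuffling the variable across sites under
a seeded stream; $p$ is therefore bounded below by $1/(N_{perm}+1)$, and
$P(p \le 0.05) = 0.05$ exactly under the null, which the acceptance suite
verifies empirically (1000 null simulations).

The ordination substrate is the analyst's choice. For the *planted
gradient* recovery test we fit variables onto an ordination aligned with
the latent site ordering (the community response the gradient drives), not
onto the PCoA of the environmental table itself: Gower range-normalizes
every variable, so in an ordination *of the table* all variables contribute
equally by construction and "which variable ranks first" would be a coin
flip rather than a recovery question.

# Diversity estimators

All estimators consume one vector of per-species counts (zeros ignored):

* **Chao1**: $S_{obs} + f_1^2/(2f_2)$; when $f_2=0$, the bias-corrected
  $S_{obs} + f_1(f_1-1)/2$. (The always-bias-corrected variant used by some
  software differs when $f_2>0$; the classic form is implemented.)
* **ACE** with the conventional rare/abundant cut at 10:
  $S_{abund} + S_{rare}/C + (f_1/C)\,\gamma^2$,
  $C = 1 - f_1/N_{rare}$, $\gamma^2$ floored at 0; if every rare species is
  a singleton ($C=0$) it falls back to Chao1 with a message.
* **Shannon** $H' = -\sum p_i \ln p_i$ in nats (base flag available);
  **reciprocal Simpson** $1/\sum p_i^2$, an effective species number in
  $[1, S_{obs}]$.
* **Fisher's α** solves $S = \alpha\ln(1+N/\alpha)$ by bracketed
  root-finding plus Newton polishing to residual $<10^{-9}$; an
  all-singleton sample has no finite solution and returns `Inf` with a
  warning.
* **Rarefaction** is the analytic hypergeometric expectation
  $E[S_m] = \sum_i \left(1 - \binom{N-n_i}{m}/\binom{N}{m}\right)$,
  computed with log-binomials for stability, and is verified against
  Monte-Carlo subsampling in the tests.

# Functional profiles

Category × site matrices support relative abundance (column
normalization; a zero site column is an error naming the site), row
standardization (per-category z-scores across sites; constant rows carry no
contrast and are dropped with a message; the operation is idempotent), PCA
with sites as observations, and agglomerative clustering. Two clustering
recipes circulate for such profiles — Pearson-correlation distance with
average linkage, and Euclidean distance with complete linkage — and the
published descriptions of the motivating analyses disagree between figure
caption and methods text. Both are implemented; the programmatic default is
Euclidean/complete, and the CLI takes an explicit `distance:linkage`
choice. Both linkages are monotone, so dendrogram heights never invert.

# The synthetic world

The generators state, once, the world the tests run in:

* **Genome models** are order-$m$ Markov chains ($m \le 5$, default 2 —
  binning exploits exactly the 3–6-mer statistics an order-2/3 chain
  controls). Each context's conditional distribution is the base
  distribution (G+C split evenly between G and C) perturbed
  log-normally with SD `bias_strength` and renormalized *within* the G/C
  and A/T pairs, so every context emits G+C with exactly the target
  probability: stationary G+C equals the target by construction, while
  higher-order word statistics differ between models. `bias_strength`
  defaults to 0.5 — enough that two same-G+C models are separable from
  10 kb scaffolds, the regime the motivating study describes for
  distinguishing same-G+C genera.
* **Scaffold lengths** are lognormal (median 15 kb, $\sigma = 0.7$ on the
  log scale) truncated to 1–130 kb, echoing the observed range of real mat
  assemblies; about 40% of scaffolds fall below the 10 kb analysis filter,
  which is deliberate — the filter must have work to do.
* **Communities** default to 60 scaffolds per population, three populations
  at G+C 35/50/65%.
* **OTU counts**: log-series sampling is the sequential urn process with
  new-species probability $\alpha/(\alpha+i-1)$, whose expected richness is
  exactly $\alpha\ln(1+N/\alpha)$ — the model under which Fisher's α is
  consistent, giving a parameter-recovery test with known truth. The
  lognormal mode draws $S_{true}$ relative abundances with
  $\sigma_{\log}=1$.
* **Environmental matrices**: sites on a latent gradient in $[-1,1]$; the
  planted variable is gradient × `effect_axis` plus Gaussian noise
  (SD 0.5); other numerics are pure noise, factors random. `effect_axis`
  0 is the null world, 3 the "large effect" world.
* **Functional matrices**: 52 categories × 12 sites, three contiguous site
  groups, per-(group, category) log-mean offsets $N(0,1)$ (typical e-fold
  shifts) on lognormal category baselines, Poisson counts.

Every generator routes all randomness through one seeded stream
(`with_seed`) and restores the caller's RNG state; truth tables always
accompany generated data.

What the synthetic world does **not** emulate: real assemblies' chimeric
scaffolds, repeat-induced composition anomalies, coverage–composition
correlation, within-population strain variation, codon-level constraints of
real coding sequence, and read-level error models. A green bin-recovery
test therefore establishes that the consensus machinery separates
populations whose word statistics differ at the planted effect size — not
that any particular real community would bin as cleanly.

# Numerical choices and degenerate inputs

* Per-trial seeds: Lehmer-style integer hash of (master seed, k, trial),
  always in $[1, 2^{31}-2]$, so runs are reproducible and parallelizable
  without shared state.
* k-means ties → lowest cluster index; empty cluster → re-seed from the
  farthest point; iteration cap 100.
* Frequencies for a word length with zero valid windows are an all-zero
  block, flagged, not an error; `k_max` longer than the sequence likewise.
* Gower with a zero-range numeric variable: the variable is uninformative
  and carries zero weight everywhere.
* Constant variables in `fit_env_variables`: $r^2 = 0$ with a message and
  no p-value.
* PCoA of an all-zero distance matrix returns zero axes.
* ARI of two trivial (single-cluster) partitions is defined as 1.

# Known limitations

* Consensus support needs $k$ within roughly a factor of two of the true
  population count; far larger $k$ dilutes support below any fixed
  threshold (see above). The package reports unbinned scaffolds rather than
  forcing them into bins.
* Component-based demarcation can chain two populations through a single
  high-support bridge pair; the support network export exists so such
  bridges can be inspected.
* The envfit $r^2$ for factors is undefined for factors with a single
  observed level (treated as constant).
* No coverage-aware (hybrid) binning: composition only, by design.
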