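---
title: "Methods: repeat ratios, phylogenetic regression and integration indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat ratios, phylogenetic regression and integration indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeat2shape)
```

This vignette documents the models behind `repeat2shape`, the choices that
were genuinely open when the package was designed, and what the test suite
does and does not establish about real data.

## The scientific question

The RUNX2 transcription factor carries a tandem polyglutamine (polyQ) +
polyalanine (polyA) repeat whose length ratio (Q/A) modulates
transcriptional activity and, in several mammal clades, correlates with
facial length. The package asks that question for phyllostomid bats and for
New/Old World monkeys at three levels of rigor: naive rank correlation,
regression corrected for phylogenetic non-independence, and a fully
generative Bayesian model of correlated trait evolution; a fourth strand
relates Q/A ratios to the magnitude of morphological integration of the
skull.

## Repeat extraction

A raw amplicon (or database protein) is screened by requiring two conserved
anchor motifs flanking the repeat domain; the screen mirrors the exclusion
rule applied to sequencing data, where a read without both reference
markers cannot be scored. Anchor matching is a Hamming-distance search
(`Biostrings::matchPattern`, substitutions only), with the mismatch budget
as configuration. The published analysis does not print its marker motifs,
so the package ships defaults — `MRIPV`, the N-terminal start of the RUNX
P2-promoter isoform, and `PSTSR`, a conserved motif downstream of the
repeat in human RUNX2 — and records the anchors used in every extraction
audit. Users aligning their own amplicons should set anchors from their
alignment; all results in this package's tests use the defaults, which is
sufficient because the simulator builds sequences around the same
configuration.

Within the domain, the polyQ count is the number of glutamines in the
maximal glutamine run and likewise for alanine. By default runs must be
pure ("in tandem"); an opt-in `max_interruptions` tolerates interior
non-target residues, which never count toward the run, because real RUNX2
polyQ tracts can be interrupted. Whether a study counts the longest pure
run or the interrupted tract is a genuine ambiguity; both are supported and
the default (pure) is the stricter reading. The reported polyQ run must
start before the polyA run — a domain with the tracts reversed is malformed
rather than merely unscored, since it indicates mislocated anchors.
Coordinates are 0-based half-open throughout. Nucleotide input is
translated in all three frames (ambiguous codons to `X`, internal stops
flagged but not fatal); the frame containing both anchors wins, ties to the
lowest frame.

## Geometric-mean size correction

Each specimen's palate length, palate width and zygomatic breadth are
divided by the geometric mean of its five ventral cranial measurements
(palate length and width, skull length and width, zygomatic breadth). The
divisor is fixed to exactly those five, matching the published
standardized columns. GM division removes isometric size:
`standardize(c * record) = standardize(record)` for any `c > 0`, a property
asserted in the tests, along with the AM–GM inequality on every record.
Species aggregation is an unweighted mean over adult specimens (adults are
specimens with a fused basisphenoid–basioccipital joint; the flag is taken
as given in the input table). The bat data had one specimen per species, so
aggregation only matters for user-supplied multi-specimen tables.

One known data wrinkle: the source's running text gives a nectarivore
palate-length/GM range of 0.83–0.90 while its table prints 0.91 for
*Anoura geoffroyi*. The packaged fixture stores the table values verbatim;
the discrepancy is documented here rather than resolved.

## Spearman correlation

`spearman_cor` computes the Pearson correlation of mid-ranks, the
tie-corrected form of Spearman's rho (identical to the classical
`1 − 6Σd²/(n(n²−1))` when there are no ties — a tested property). The
p-value method follows the sample size: full enumeration of all `n!`
permutations for `n ≤ 8` (40 320 permutations, evaluated by one matrix
product), seeded Monte Carlo permutation with the add-one estimator for
`9 ≤ n ≤ 12`, and the t approximation on `n − 2` df above that. The
published p-value method is unstated; these defaults mean the six-species
New World monkey group gets an exact p while the 31-bat group uses the
same t approximation as standard software. All p-values are two-sided, and
no multiple-testing correction is applied (none was applied in the source
analysis; the report simply lists raw p-values).

### What the packaged dataset can and cannot reproduce

The fixture stores the published table at its printed precision (2 decimal
places). From it, the bat correlations reproduce to well within ±0.02
(−0.509 vs −0.51; 0.557 vs 0.55), as do pooled-primate palate width and the
New World monkey palate length. Pooled-primate palate length computes to
0.419 against a printed 0.44, and the Old World monkey values to 0.495/0.187
against 0.58/0.29. Those gaps cannot be closed from the printed data: the
primate measurements underlying the publication carry more precision than
the table (shifting ranks in these small, tie-heavy groups), and several
Q/A ties there are exact (identical counts), so no added precision breaks
them. The corresponding acceptance assertions are therefore expected to
fail with the packaged fixture, and the discrepancy is reported as is
rather than tuned away.

## PGLS with Pagel's lambda

Under Brownian motion the cross-species covariance is `σ²C`, with
`C[i, j]` the shared root-to-MRCA path length. Pagel's λ multiplies the
off-diagonal of `C`, interpolating between independence (λ = 0, the OLS
limit) and pure Brownian motion (λ = 1). `pgls_fit` profiles λ over [0, 1]
with `optimize` (tolerance 1e-6) and evaluates both endpoints explicitly,
because boundary optima are common in comparative data (and pervasive in
the published fits, which report λ of 0 or 1 for most models; printed
values like 994 are λ × 1000, while this package reports λ on [0, 1]). ML
is the default objective, matching the common default of comparative
packages; REML is available by flag. Coefficient tests use the GLS residual
variance on `n − 2` df; R² compares the GLS residual sum of squares with a
phylogenetically weighted intercept-only model, so adjusted R² can be
negative. Fixed-λ fits are cross-checked in the tests against
`nlme::gls` with `ape::corPagel`, and the star-tree case collapses to
`lm` at machine precision.

The published PGLS and Bayesian tables are not bit-reproducible because the
study's dated trees are unpublished; the package treats trees as inputs.
Correctness is instead established by parameter recovery on simulated
ground truth: λ estimated at its generating boundary values on 100-tip
trees, slopes recovered, and the likelihood verified against a dense
Kronecker-product multivariate-normal oracle on all small trees.

## Bayesian Brownian-motion correlation

The generative model treats the two traits (Q/A ratio and a standardized
palate trait) as bivariate Brownian motion on a fixed dated tree with rate
covariance Σ; the trait matrix is matrix-normal with row covariance Σ and
column covariance C. The reference implementation of this analysis class
jointly samples divergence times from sequence data; here the tree is
conditioned upon, which preserves the correlation contract (posterior of
`r`, and `pp = Pr(r > 0)`) while keeping time estimation out of scope.

Priors: inverse-Wishart(I₂, ν = 4) on Σ — the smallest proper choice with a
finite mean, weakly centred on the identity — and an improper flat prior on
the 2-vector root state, which is marginalized analytically (it enters the
likelihood only through the GLS root estimate, leaving a `|Σ|^{-(S-1)/2}`
marginal). The sampler is random-walk Metropolis on `(log L₁₁, L₂₁, log
L₂₂)` of the Cholesky factor Σ = LL′, with the log-scale Jacobian included;
because the marginal likelihood depends on the data only through the 2 × 2
GLS cross-product matrix, each MCMC cycle is O(1) after one Cholesky of C.
Defaults are 30 000 cycles, 10% burn-in, proposal SD 0.15 (acceptance
around 0.2 in typical runs), and a minimum effective-sample-size floor of
300 (`coda::effectiveSize`) mirroring the convergence rule of the source
analysis — a chain below the floor refuses to report and raises a
diagnostic error carrying its trace. With the flat root prior this
posterior is conjugate (inverse-Wishart with scale `I + A` and df
`ν + S − 1`), and the exported `bm_correlation_exact` samples it directly;
the test suite uses it as an independent oracle for the Metropolis sampler,
and recovery tests confirm posterior means within 0.15 of generating
`r ∈ {−0.6, 0, 0.6}` and `pp > 0.95` at `r = 0.9` on 100-tip trees.

## Integration indices

From a species' phenotypic covariance or correlation matrix `M` (correlation
matrices are the recommended kind for cross-species comparability):

* **ICV** — the coefficient of variation of the eigenvalues,
  `sd(λ)/mean(λ)`, using the population SD by default (the convention of
  the integration literature; sample SD by flag). Identity ⇒ 0; a p × p
  all-ones matrix ⇒ `sqrt(p − 1)` (closed form, tested).
* **Flexibility** — mean cosine between unit selection gradients β
  (uniform on the sphere) and responses `Mβ`: the capacity to respond in
  the direction selection pushes. Identity ⇒ exactly 1.
* **Constraints** — mean |cosine| between `Mβ` and the leading eigenvector
  (the line of least resistance); the absolute value is used because
  eigenvector sign is arbitrary. Rank-1 ⇒ exactly 1; identity ⇒ the
  analytic expectation `Γ(p/2)/(√π Γ((p+1)/2))` of |cos| between random
  directions, which the tests verify.

The skewer draw protocol — `set.seed(seed)`, a p × n standard-normal
matrix, column normalization — is part of the contract, so identical seeds
give identical indices; n = 1000 skewers is the default (the sources the
index definitions descend from do not restate their settings), and the
Monte Carlo error scales as `1/√n`, a tested property. Both indices are
invariant to scaling of `M`.

The published per-species bat index values live in a supplementary file
not shipped here, so the package does not assert the published
index-vs-Q/A correlations (ICV −0.6, flexibility 0.7, constraints −0.6);
given those values as a CSV, `integration_indices` + `indices_vs_qa`
reproduce that analysis. The tests instead pin the indices to their
analytic and oracle targets on synthetic matrices with known structure.

## Synthetic data

The simulators define the conditions under which the estimators are
validated:

* **Yule trees** — pure-birth with per-lineage rate `birth_rate`
  (default 1): backward construction with Exp(kλ) inter-event intervals
  for k = n..2 and uniform random joins; the expected root-to-tip depth
  `Σ 1/(k·birth_rate)` is verified over 200 replicates. Pure-birth (rather
  than birth–death) is the simplest ultrametric generator adequate for
  Brownian-motion testing.
* **Brownian traits** — one matrix-normal draw per tree via Cholesky
  factors of Σ and the λ-transformed C; moment-matched against `Σ ⊗ C`
  over 500 replicates. Recovery tests use 100-tip trees, the scale at
  which λ and `r` are identifiable with useful precision; the real
  datasets (31 and 13 species) sit below that, which is precisely why the
  published Bayesian/PGLS numbers are direction-level results.
* **Specimens** — a single-factor model `ΛΛ′ + ψI` around positive trait
  means (default 20 mm, the scale of small-mammal cranial measurements),
  truncated positive by resampling (not clipping, to preserve the MVN
  shape; 100-attempt cap). The exact generating matrix accompanies the
  sample so integration indices have known targets.
* **Sequences** — `anchor + polyQ + polyA + anchor` with optional padding
  and linker; nucleotide mode back-translates with seeded synonymous
  codons (CAG/CAA for Q, GCN for A). Repeats are constructed, not evolved:
  the simulator makes no attempt at realistic substitution processes,
  which is out of scope.

Every simulator is a pure function of its configuration and seed, and
ground truth travels with the data (a `manifest` attribute), so recovery
tests have no hidden state.

## What passing tests do and do not show

The suite establishes correctness of the machinery: exact agreement with
enumeration, closed-form and dense-oracle targets; parameter recovery at
simulation scale; byte-reproducibility of seeded pipelines (problem sizes
used: 100-tip trees with 20 replicates for λ recovery, 30 000-cycle chains,
500-replicate moment checks). It does not establish that the biological
association holds beyond the packaged dataset, nor can it validate the
anchor defaults against unpublished primer sets, the printed-precision
limits discussed above, or any result that depends on the unpublished
trees and supplementary index values. Ornstein–Uhlenbeck or multi-rate
models, tree inference, and divergence-time estimation are explicit
non-goals.
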