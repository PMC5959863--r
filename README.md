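# repeat2shape

Comparative analysis of RUNX2 glutamine/alanine tandem-repeat ratios and
craniofacial shape across phyllostomid bats and primates.

RUNX2 is a master transcription factor of osteoblast differentiation. Just
upstream of its DNA-binding runt domain sits a tandem amino-acid repeat: a
polyglutamine (polyQ) tract followed by a polyalanine (polyA) tract. The
ratio of the two repeat lengths (the **Q/A ratio**) tunes RUNX2
transcriptional activity and has been linked to facial length evolution in
several mammal lineages. This package implements the full analysis chain
used to test that association in New World leaf-nosed bats (Phyllostomidae)
and in New and Old World monkeys:

1. **Repeat extraction** (`extract_qa`): locate the Q/A domain between
   conserved flanking anchor motifs (Hamming-tolerant search, screening out
   sequences missing either anchor), count the tandem Q and A runs, and
   compute Q/A = q / a.
2. **Size correction** (`standardize_specimens`): divide each specimen's
   palate length, palate width and zygomatic breadth by the geometric mean
   (GM) of its five ventral cranial measurements, removing isometric size.
3. **Rank correlation** (`spearman_cor`): tie-corrected Spearman's rho
   (Pearson correlation of mid-ranks) with an exact permutation p-value at
   small n, seeded Monte Carlo permutation at moderate n, and the t
   approximation on n − 2 df otherwise.
4. **PGLS** (`pgls_fit`): generalized least squares y = Xβ + ε,
   ε ~ N(0, σ²V(λ)), where V(λ) multiplies the off-diagonal of the
   Brownian-motion tree covariance C by Pagel's λ ∈ [0, 1]; λ is estimated
   by profiling the (RE)ML likelihood with boundary values evaluated
   exactly.
5. **Bayesian Brownian-motion correlation** (`bayes_bm_correlation`): two
   traits evolve as correlated Brownian motions on a fixed dated tree with
   rate covariance Σ (2 × 2); with an inverse-Wishart prior on Σ and the
   root state marginalized under a flat prior, a random-walk Metropolis
   sampler on the log-Cholesky factors of Σ yields the posterior of the
   evolutionary correlation r = Σ₁₂/√(Σ₁₁Σ₂₂) and pp = Pr(r > 0 | data).
   An exact conjugate sampler (`bm_correlation_exact`) provides an
   independent cross-check.
6. **Morphological integration** (`icv`, `random_skewers_flexibility`,
   `constraints_index`): the eigenvalue coefficient of variation
   ICV = σ(λᵢ)/λ̄ of a phenotypic matrix, and random-skewers indices —
   flexibility = E[cos(β, Mβ)] and constraints = E[|cos(Mβ, e₁)|] over
   unit selection gradients β uniform on the sphere.

The packaged dataset (`load_qa_palate_data()`) holds the published
comparative table: 31 phyllostomid bats and 13 primates with GM-standardized
palate traits and Q/A repeat counts. Simulators (`simulate_yule_tree`,
`simulate_bm_traits`, `simulate_specimens`, `synthesize_runx2_sequences`)
generate every input format with known ground truth, so each stage is
testable offline.

## Worked example

```r
library(repeat2shape)

d <- load_qa_palate_data()
bats <- d[d$group == "bats", ]
spearman_cor(bats$qa_ratio, bats$palate_length_gm)
#> Spearman rank correlation: rho = -0.509, p = 0.003484 (t-approximation, n = 31, ties present)
spearman_cor(bats$qa_ratio, bats$palate_width_gm)
#> Spearman rank correlation: rho = 0.557, p = 0.001139 (t-approximation, n = 31, ties present)
```

Higher Q/A ratios go with relatively shorter (rho = −0.51) and broader
(rho = 0.56) palates across the 31 bat species. The repeat extractor
round-trips a synthesized sequence with known counts:

```r
seqs <- synthesize_runx2_sequences(data.frame(species_id = "Artibeus_watsoni", q = 21, a = 9))
extract_qa(seqs)[, 1:5]
#>         species_id q_count a_count qa_ratio passed_screen
#> 1 Artibeus_watsoni      21       9 2.333333          TRUE
```

Phylogenetic estimators recover known simulation truth (traits generated
with Brownian rate correlation 0.6 on a 100-tip Yule tree):

```r
tr <- simulate_yule_tree(100, birth_rate = 1, seed = 1)
traits <- simulate_bm_traits(tr, matrix(c(1, 0.6, 0.6, 1), 2), seed = 2)
fit <- pgls_fit(setNames(traits$y, traits$species), setNames(traits$x, traits$species), tr)
fit
#> PGLS (ML): lambda = 1.000, adj R2 = 0.308, n = 100
#>             estimate        se          t            p
#> intercept -0.1362321 0.4885974 -0.2788229 7.809683e-01
#> slope      0.5745810 0.0856400  6.7092599 1.269813e-09

m <- rbind(x = setNames(traits$x, traits$species), y = setNames(traits$y, traits$species))
bayes_bm_correlation(m, tr, seed = 3)
#> Brownian-motion correlation posterior: mean r = 0.555, pp = 1.000
#>   min ESS = 1495, acceptance = 0.18, cycles = 30000 (seed 3)
```

`run_pipeline()` chains the stages (simulate / extract / standardize /
correlate / pgls / bayes_pcm / integration) from a single configuration
list or YAML file and writes CSV reports plus a JSON manifest recording
seeds, input checksums and per-stage status; identical configurations give
byte-identical outputs.

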