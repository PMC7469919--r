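---
title: "Methods: tensor-decomposition-based unsupervised feature extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensor-decomposition-based unsupervised feature extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfe)
```

## The model

`tdfe` analyses a four-way expression tensor $x_{ijkm}$ over genes $i$,
tissues $j$, treatments $k$ and replicates $m$. Each sample fiber (fixed
$j,k,m$) is standardized to zero mean and sum of squares $N$ over genes,
so every sample contributes equally to the decomposition and gene-mode
loadings are centred by construction. Higher-order SVD then factorizes

$$x_{ijkm} = \sum_{\ell_1 \ell_2 \ell_3 \ell_4}
  G(\ell_1,\ell_2,\ell_3,\ell_4)\,
  u_{\ell_1 j}\, u_{\ell_2 k}\, u_{\ell_3 m}\, u_{\ell_4 i},$$

where each factor matrix holds the left singular vectors of the
corresponding mode unfolding and $G$ is the multilinear projection of the
data onto all four factors. Nothing in the factorization knows about
treatments being drugs or controls, or about anatomical tissue groups —
any such structure has to emerge from the data, which is the point of the
approach: with 24 tissues there are millions of two-way partitions, and no
supervised method can test them all.

The first vector of each mode is, in practice, near-uniform: it captures
the part of expression shared by all tissues, treatments or replicates.
Interpretation therefore starts at the second vector. Tissue-mode vectors
whose large loadings concentrate on a few tissues define tissue-group
contexts; treatment-mode vectors 2 and 3 span the plane in which drug
treatments separate from control-like conditions. For a chosen context
$\ell_1$, the gene-mode vectors carrying its drug response are those with
the largest $|G(\ell_1, \ell_2, 1, \ell_4)|$ for $\ell_2 \in \{2, 3\}$ —
$\ell_3$ is fixed at 1 because the first replicate-mode vector is constant
across replicates, and a reproducible effect should not depend on the
replicate contrast.

Gene selection treats the loadings of a selected gene-mode vector as
draws from a zero-mean Gaussian (the standardization constraint forces
zero-mean fibers) and converts them to upper-tail chi-squared P-values,

$$P_i = P_{\chi^2}\!\left[> \sum_{\ell_4}
  (u_{\ell_4 i}/\sigma_{\ell_4})^2\right],$$

with one degree of freedom per vector and $\sigma_{\ell_4}$ the
population-form standard deviation of the vector about zero. When two
vectors carry one context (see below), the squared standardized loadings
add, and the degrees of freedom become 2; this is the standard
multi-vector extension and reduces to the single-vector rule at one
vector. P-values are Benjamini–Hochberg corrected (`stats::p.adjust`) and
genes with adjusted $P$ strictly below 0.01 are selected.

The Gaussian assumption is an approximation: loadings of a singular
vector are bounded and weakly dependent, and for signal vectors the
planted genes are exactly the non-Gaussian part being hunted. Its
practical consequence — calibration under the null — is what the test
suite checks (Kolmogorov–Smirnov distance of null P-values from
uniformity, and the fraction of null genes surviving BH at 0.01).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `log_transform`, `pseudocount` | `TRUE`, 1 | work on $\log_2(x+1)$; raw counts are heavy-tailed and the chi-squared machinery assumes roughly Gaussian loadings. Both modes are supported and recorded in the run manifest. |
| `dominance` | 0.5 | a tissue joins a context when its loading magnitude reaches this fraction of the vector's largest; the grouping is a judgement call in the underlying method (made by eye on loading plots), so the full loading vector is always reported for manual override. |
| `l2_candidates`, `l3` | `c(2, 3)`, 1 | treatment-mode vectors scanned in the core; replicate-mode vector fixed to the between-replicate-constant one. |
| `max_vectors`, `vector_ratio` | 2, 0.75 | a second gene-mode vector joins a context only when its core score reaches 75% of the best one — with two near-tied core entries, both vectors carry the context and the chi-squared combination uses df = 2. |
| `threshold` | 0.01 | adjusted-P cutoff, strict inequality. |
| `include_singletons` | `FALSE` | single-tissue contexts describe one organ, not a tissue group; they are reported but skipped unless opted in. |

The first gene-mode vector is excluded from core-guided selection by
default (`exclude_first = TRUE` in `select_ell4()`): it mirrors the
contrast-free first vectors of the other modes — it typically has large
core weight yet describes the expression profile common to all samples,
not a response.

## The synthetic generator

`generate_dataset()` draws counts as
$\mathrm{round}(2^{\,b_i + t_g\cdot 1[\cdot] + d_g\cdot 1[\cdot] + \varepsilon})$
with per-gene baseline $b_i \sim N(6, 2)$ on the $\log_2$ scale (median
count 64, spanning the dynamic range of bulk RNA-seq), tissue effect
$t_g$ applied to planted genes in the group's tissues under all
treatments, drug effect $d_g$ added in treated (non-control) conditions
only, and i.i.d. replicate noise $\varepsilon \sim N(0, 0.5)$. A
log-normal-with-rounding model is used rather than a negative binomial:
the pipeline standardizes per sample and never uses count likelihoods, so
the simpler model suffices.

The default `drug_tissue_spec()` mirrors the 24-tissue x 18-treatment x
2-replicate layout of the multi-tissue mouse drug study deposited as GEO
GSE142068, with four control-like conditions (APAP, FivePercentSucrose,
Sofosbuvir, WT.No.treated) and three planted groups of 50 genes each: a
neuronal group (Brain, Eye, PituitaryG, Testis), a muscular group (Heart,
SkMuscle) and a gastroenterological group (Pancreas, Stomach). Nominal
effects are a drug effect of 2 and a tissue effect of 3 ($\log_2$ fold
changes). Two roster notes: the deposit's own tissue list names Spleen
twice and omits Testis while its neuronal group includes Testis; the
roster here uses 24 unique names with Testis included.

Each group also carries an `effect_scale` multiplier (defaults: neuron
1.0, gastro 1.0, muscle 0.75). This is deliberate. With exactly equal
effects, the muscular and gastroenterological groups (2 tissues x 50
genes each) would have exactly degenerate singular values, and the factor
vectors of a degenerate pair are arbitrary rotations of one another — the
decomposition would return ±45° mixtures of the two groups no matter how
little noise there is. Real tissue groups never respond with exactly
equal strength, so distinct scales are the realistic default; the exact
tie is a measure-zero artifact a simulation should not manufacture.

What the generator does **not** emulate: the real study's library sizes
and gene count, per-drug effect heterogeneity (all treated conditions
shift planted genes equally, so the drug-diversity direction of the
treatment plane is pure noise here), overdispersion beyond the log-normal
noise, and correlated gene modules outside the planted sets. Passing
tests therefore demonstrate that the machinery recovers planted low-rank
structure at realistic effect sizes and noise — not that real data meet
the model's assumptions.

## Numerical choices

* **Standardization** uses the population ($1/N$) variance so the
  sum-of-squares constraint holds exactly; a zero-variance fiber is an
  error naming the offending sample, never a silent skip.
* **Sign convention**: every singular vector is flipped so its
  largest-magnitude component is positive. The Tucker sum is
  sign-ambiguous per vector pair; a fixed convention makes runs and tests
  bit-reproducible. Core entries are reported under this convention and
  magnitude comparisons use absolute values. Exactly tied singular values
  have no canonical order; the underlying LAPACK order plus the sign
  convention makes the output deterministic for a given input.
* **Economy ranks**: each factor matrix is the economy-size left singular
  matrix of its unfolding — the gene factor is $N \times r_4$ with
  $r_4 \le |J||K||M|$ (864 in the study layout), never $N \times N$. All
  mode ranks are kept full, so the decomposition is exact.
* **Treatment split**: 2-means on the $(u_{2k}, u_{3k})$ plane, with
  Lloyd iterations started from every pair of distinct points and the
  lowest within-cluster sum of squares kept. At 18 points this is
  effectively exhaustive and fully deterministic. Initializing from the
  single farthest pair was considered and rejected: when the (noise)
  direction $u_{3k}$ contains an outlier inside the control cluster, the
  farthest pair lies within one true cluster and Lloyd converges to a
  wrong local optimum.
* **Pooled validation tests**: every $x_{ijkm}$ with $i$ in the selection
  is one observation — no per-gene averaging. The t-test is two-sided
  Welch (pool sizes and variances differ by construction); the Wilcoxon
  test is the rank-sum form with normal approximation, appropriate for
  large, continuous, post-standardization pools.

## Design choices where the design was open

* **Two vectors per context.** When two core entries for one context are
  nearly tied (within `vector_ratio`), both gene-mode vectors are used
  with df = 2 rather than a union of two df = 1 selections; the
  chi-squared sum is the standard combination, reduces correctly to one
  vector, and is monotone in each loading. The union rule can be emulated
  by two explicit `select_genes()` calls.
* **Same-pair duplicate contexts.** A tissue pair may dominate two
  adjacent tissue-mode vectors (as Pancreas/Stomach does in the
  motivating study); both contexts are kept first-class, and the overlap
  table quantifies how much their selections agree.
* **Strict threshold** (`< 0.01`), not `<=`, matching the selection
  rule's wording in the method's literature.
* **Duplicate gene symbols** in a count file keep the row with the
  largest total count (deterministic, common practice); genes dropped at
  harmonization are logged, never silent.

## Problem sizes in the test suite

Unit tests use tensors up to 50 x 8 x 6 x 2 and simulations of 200–500
genes; the end-to-end recovery checks use the full default simulation
(2000 genes, 24 x 18 x 2 samples), which decomposes in about a second.
The null-calibration checks use 2000 Gaussian loadings across 20 seeds,
and the pooled-test calibration 200 small null tensors. These sizes were
chosen to exercise every code path at full fidelity while keeping the
suite fast enough to run habitually.

## Known limitations

* Selection rests on the Gaussian-loading approximation; heavy-tailed
  loading distributions inflate the selected set. The null-calibration
  tests bound this under the generator's model only.
* Exactly degenerate singular values (equal-strength groups) cannot be
  disentangled by any rotation-free decomposition, as discussed above;
  near-degenerate groups mix partially.
* Tissue-group identification by a dominance fraction is a heuristic
  stand-in for expert reading of loading plots; the full loadings are
  exported so a user can override any grouping.
* No between-sample normalization (TMM, size factors) or batch
  correction is applied; the per-sample standardization makes samples
  comparable in scale but does not model composition effects.
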