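---
title: "Multiplex-detection MIL: model, training, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex-detection MIL: model, training, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A whole slide image (WSI) is a gigapixel scan of a stained tissue section.
Clinically one wants a slide-level call — metastasis present or absent, or
which tumor subtype — but annotating individual patches is impractical, so
the natural framing is multiple instance learning (MIL): a slide is a *bag*
of patch feature vectors \(F \in \mathbb{R}^{n \times d}\) with a single
label, and the patches ("instances") are unlabeled. The core difficulty is
finding the *critical instances* that trigger the bag label, and the main
obstacle is tumor heterogeneity: one subtype presents as several distinct
phenotypes, so any single retrieved exemplar instance under-represents the
class.

`mdmil` addresses this with a *multiplex detection* strategy: two kinds of
queries jointly attend over the bag. An **internal query (IQ)** is built
from the bag's own most-confident instances, so it adapts to each slide; a
**variational query (VQ)** is a trainable per-subtype embedding optimized
over the whole training set, so it carries global class knowledge. Their
attention maps are mixed convexly, and a memory-based contrastive loss
pulls the per-subtype representations of all slides of one class together
in feature space, explicitly counteracting phenotype scatter.

## Model

Per bag, with \(N\) subtypes and hidden width \(d'\):

1. **Instance scoring.** A linear head on the *raw* features gives
   per-instance class probabilities \(P = \mathrm{softmax}(\mathrm{cls}_1(F))\)
   (row-wise). This stream is supervised through the pooled instance loss,
   so the scores stay calibrated to the bag labels.
2. **Deep projection layer (DPL).** FC → LayerNorm → ReLU → FC maps each
   instance to \(d'\) dimensions, compacting the transferred features into
   tighter clusters before any attention. The projected bag \(F'\) feeds
   the aggregation stream only; the scoring head deliberately sees raw
   features (the two streams are parallel, not stacked).
3. **Internal query generation.** For subtype \(i\), rank instances by
   column \(i\) of \(P\), take the top \(K_1 = \max(1, \lfloor r_1 n
   \rfloor)\), and compute the confidence factor
   \(cf_i = \bar m_i - \sigma_i\) (mean minus population standard
   deviation of those top probabilities). If the unique best subtype
   satisfies \(cf_{\max} - \beta > cf_j\) for every other \(j\), it is
   *reliable* and its query averages the projected features of its top
   \(K_1\) instances; all other subtypes (or all subtypes, when the gate
   fails) average only their top \(K_2\), a deliberately conservative
   fallback that admits less noise.
4. **Dual-query cross-attention (MDCA).** Pre-normalized IQ, VQ and
   \(F'\) are projected to \(Q_1, Q_2, K, V\); per head, two attention
   matrices \(mt_1, mt_2\) (softmax over instances of scaled dot products)
   are mixed as \(m' = \alpha\, mt_1 + (1-\alpha)\, mt_2\), applied to
   \(V\), concatenated over heads, projected, and residual-added to IQ.
   This collapses the instance dimension from \(n\) to \(N\) in one step,
   so everything downstream is cheap regardless of slide size.
5. **Token refinement.** A post-LN feed-forward block, multi-head
   self-attention across the \(N\) subtype tokens (disentangling their
   representations), and a second feed-forward block produce the subtype
   representations \(f_{\text{subtypes}}\); their mean is the bag
   representation, classified by a final linear-softmax head into \(P_2\).

### Training objective

\[ L = L_{CE}(\text{maxpool}(P_1), y) + L_{CE}(P_2, y) + \alpha_{\text{loss}} L_{CL} \]

The instance term max-pools \(P_1\) per class over instances and
renormalizes before the log (the alternative — scoring the single globally
maximal instance — is available as `instance_pooling = "global_max"`). The
contrastive term uses a memory bank of one L2-normalized center per class,
initialized from the forward pass over the training split (average of each
class's labeled subtype representation, then normalized) and updated after
every optimizer step by \(c_k \leftarrow m\,c_k + (1-m)\,f\). The loss is
the softmax cross-entropy of \(\langle f, c_j \rangle / \tau\) with the
true class as target, with \(f\) the true-class row of
\(f_{\text{subtypes}}\), L2-normalized.

All gradients are derived by hand and verified against central finite
differences (relative error below 1e-4 in the test suite); the discrete
choices of the forward pass (top-K membership, the reliable gate, the
pooled arg-max) are locally constant and treated as constants in the
backward pass.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r1`, `r2` | 0.05 / 0.01 (detection), 0.1 / 0.01 (subtyping) | top-K ratios; `r1` sizes the confident aggregate, `r2` the conservative fallback. `r1` tracks the expected positive-instance fraction of the data. |
| `beta` | 0 | confidence-gate margin in \([-1, 1]\). Positive values demand a clearer winner before trusting the big aggregate; negative values (with `beta_class`) compensate a systematically under-scored subtype in imbalanced detection data. |
| `alpha_attn` | 0.5 | convex weight of the internal-query attention. `alpha_gated = TRUE` instead uses `alpha_hi`/`alpha_lo` (0.7/0.3) depending on whether a reliable query was found. |
| `d_prime` | 64 | hidden width; must be a multiple of `heads` (8). |
| `tau`, `momentum` | 0.07 / 0.999 | contrastive temperature and memory momentum. |
| `alpha_loss` | 0.5 | weight of the contrastive term. |

## The synthetic generator

The generator emulates the structure the method targets, not histology
itself: bags of variable length whose instances are isotropic Gaussian
draws around background or phenotype cluster means, with
`ceil(prevalence * n)` planted critical instances per positive bag and a
per-instance uniform choice among the class's phenotypes (heterogeneity).
Cluster means sit at `cluster_separation * noise_std` from the origin in
random directions, so separation is expressed in noise units; at the
default separation 6 with `d = 64` the instance clusters are
Bayes-separable, which is verified in the tests by a nearest-centroid
oracle on bag means.

Two presets mirror the regimes the method is aimed at: `camelyon_like`
(detection: 2 classes, negatives background-only, 5% prevalence in
positives, 159:111-style imbalance) and `tcga_like` (subtyping: 3 classes,
80% prevalence, three phenotypes per class, 111:489:284-style imbalance).
Both default to 330 bags of 80–120 instances at `d = 64` split 200/50/80 —
sizes chosen so a full 30-epoch CPU run of the package finishes in about a
minute, which is the configuration the acceptance checks train. What
passing these checks shows is that the architecture, losses and training
loop are implemented correctly and can recover planted structure; it does
not show histology-level performance, since real WSI bags have correlated
instances, non-Gaussian feature geometry, batch effects and much larger
`n` and `d`.

## Numerical and design choices

- **K clamping.** \(K = \max(1, \lfloor r n \rfloor)\): the floor makes K
  deterministic, the clamp keeps one-instance aggregation well-defined for
  tiny bags.
- **Ties.** Top-K ranking breaks probability ties by ascending instance
  index (stable), which is what makes the whole forward pass exactly
  permutation-equivariant and testable as such. A tied maximal confidence
  factor yields no reliable class.
- **Gate quantifier.** The margin test is strict and must hold against
  every other subtype's confidence factor.
- **σ divisor.** The confidence factor uses the population form (divisor
  \(K_1\)).
- **Scoring-head input.** `cls1` consumes raw features, not the DPL
  output; the projected features feed only aggregation and attention.
- **Memory re-normalization.** Centers are re-normalized after every
  momentum update, not only at initialization; without this the inner
  products in the contrastive logits drift in scale as training proceeds.
  The representation \(f\) is likewise normalized before the similarity.
- **FFN internals.** Standard two-layer post-LN block, expansion 4, exact
  GELU (\(x\Phi(x)\)); one MDCA + one MHSA block, not stacked.
- **MDCA residual** is added after the output projection (standard
  post-attention placement).
- **α policy.** A fixed scalar (0.5) is the default because it is the
  directly testable reading; the gated mode ties α to the reliability of
  the internal query for data where that signal is informative.
- **Optimizer.** Adam, lr 2e-4, decoupled weight decay 1e-5, cosine decay,
  one bag per step (variable bag length precludes trivial batching);
  checkpoint selection by validation AUC with ties broken by accuracy and
  then by the earlier epoch. τ = 0.07 and momentum 0.999 follow the
  conventions of momentum-contrast methods.
- **Degenerate inputs.** Empty bags, all-background slides, single-class
  evaluation sets, zero-norm representations and non-finite losses all
  raise explicit errors rather than propagating silently.
- **Splits.** Stratified at the slide level by largest-remainder
  apportionment per class, with remainder ties resolved toward the split
  furthest below its global share, so both per-class and total counts
  track the requested 60/15/25.
- **Container.** The delimited-text layout (one CSV per bag + manifest)
  serializes features with 17 significant digits, which round-trips IEEE
  doubles bit-exactly.

## Limitations

- The feature extractor for real slides is pluggable but not bundled: the
  provided extractor is a deterministic random projection suitable for
  pipelines and tests, not a learned encoder.
- Pure-R training is practical at the synthetic scale (tens of thousands
  of instances); real-WSI scale (\(n \sim 10^4\) per bag, \(d = 1024\))
  works through the same code paths but is considerably slower than a
  GPU tensor-library implementation.
- The model is set-based by design and discards spatial context; tasks
  that need neighborhood structure (e.g. survival from micro-environment)
  are out of scope.
- The saturation rule is the only tissue filter; no stain normalization
  or segmentation is provided.
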