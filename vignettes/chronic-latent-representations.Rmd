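---
title: "Latent representations of chronic patients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent representations of chronic patients: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data model

`ehrlatent` implements a phenotyping workflow for chronic-disease populations
coded in electronic health records. Each patient is a binary vector
$\mathbf{x} \in \{0,1\}^D$ over a fixed vocabulary of truncated clinical
codes: ICD9-CM diagnoses reduced to their 3-character stem (the part before
the decimal point) and ATC drug codes reduced to their first five characters
(levels 1–4). A bit is 1 if the code was recorded for the patient at least
once in the observation year. The default vocabulary spans $D = 2{,}263$
positions (1,517 diagnosis + 746 drug codes), diagnosis block first, each
family in lexicographic order.

The workflow is: compress $\mathbf{x}$ to a low-dimensional latent
representation with a denoising autoencoder (DAE); cluster the latent
vectors; pick the number of clusters with cluster-validity indices;
characterize each cluster through presence-rate profiles, correlations with
the reference groups, cross-tabulations and age summaries; and map synthetic
single-code and multi-code patients into a joint 2-D embedding to read off
which codes drive each phenotype.

Hospital EHR extracts of this kind are confidential, so the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes, and every downstream stage is exercised against it.

## The synthetic cohort generator

The generator emulates four Clinical Risk Groups (CRGs): CRG-1000 (46,835
healthy patients), CRG-5192 (12,447 hypertensive), CRG-5424 (2,166
diabetic) and, in the second case study, CRG-6144 (3,179 multimorbid:
diabetes + hypertension). The labelled CRGs hide latent sub-phenotypes:
CRG-5424 mixes a biguanide-treated (75%) and an insulin-dependent (25%)
diabetic profile, and a small pregnancy/delivery bundle spans CRG-5192 (8%;
pregnancy-induced hypertension is classified under the hypertension CRG)
and CRG-1000 (2.5%). Case study 1 therefore carries five latent groups;
case study 2 six.

Each sub-phenotype is a vector of per-code Bernoulli presence rates:

* a **lead diagnosis** at rate 0.85 (`250` for diabetics, `401` for
  hypertensives, `V27` for deliveries);
* **lead drugs** at 0.6–0.85 (`A10BA` biguanides, insulins `A10AB`/`A10AE`
  — near-universal in the insulin-dependent group, which they define —
  `C09AA` ACE inhibitors, `B03AA` iron);
* a bundle of **secondary comorbidity and co-medication codes** at 0.3–0.55
  (e.g. lipid disorders `272`, retinopathy `362`, statins `C10AA`,
  antihypertensive combinations `C03AA`/`C07AB`/`C08CA`, and
  combination-therapy markers `A10BD`/`C09BA`/`C10BA` plus hypertensive
  kidney disease `403` specific to the multimorbid group);
* **shared acute codes** every group carries at 0.05–0.12 (respiratory
  infections, unspecific findings, analgesics `N02BE`/`M01AE`) — healthy
  patients have *only* these, keeping their whole profile below 0.15;
* a **low background rate** on every remaining code, 0.002 at baseline and
  scaled by morbidity (×0.5 healthy, ×1 chronic, ×1.5 multimorbid), so an
  average healthy patient accrues 2–4 incidental codes per year and a
  multimorbid one 15–20 codes in total.

Code bits are independent Bernoulli draws given the sub-phenotype and a
per-patient **severity factor**: chronic phenotypes draw severity uniformly
from \[0.5, 1\] and scale their treatment/comorbidity code rates by it
(mean-preserving, and never the defining lead codes), so every chronic
group contains a realistic tail of mildly affected, sparsely coded
patients. Ages are normal (truncated at zero) with older means for the
chronic groups and a young pregnancy group; sex is Bernoulli with an
all-female pregnancy bundle.
These rates were fixed once, from the qualitative shape of published per-CRG
profiles (a few codes between 0.3 and 0.85 over a long low-rate background)
and from what one year of claims realistically contains; they are the
package's study conditions, not estimates of any hospital's true rates.

What the generator deliberately does **not** model: within-patient
correlation between codes beyond group membership (real comorbidities
co-occur in the same patients, not just in the same group), longitudinal
structure across years, and code frequencies (bits, not counts). Tests that
pass on these cohorts therefore demonstrate that the pipeline recovers
marginal presence-rate structure; they cannot demonstrate robustness to
correlated or drifting real-world coding behaviour.

Class imbalance is handled as in the emulated study design: random
under-sampling of every CRG to the minority CRG size (2,166), giving
balanced cohorts of 6,498 (case 1) and 8,664 (case 2), followed by a
seeded 75/25 train/test split with `floor` rounding — reproducing test
subsets of exactly 1,625 and 2,166 patients.

## The denoising autoencoder

The representation model is a three-layer autoencoder,

$$\mathbf{h} = \mathrm{ReLU}(\mathbf{W}\tilde{\mathbf{x}} + \mathbf{b}), \qquad
\hat{\mathbf{x}} = \sigma(\mathbf{W}'\mathbf{h} + \mathbf{b}'),$$

with untied weights, $d = 20$ hidden units by default, trained to
reconstruct the *clean* vector $\mathbf{x}$ from a stochastically corrupted
$\tilde{\mathbf{x}}$ under mean binary cross-entropy. Corruption picks
`round(nu * D / 100)` distinct positions per sample (default level
$\nu = 10$, i.e. 10% of features) and either zeroes them (zero-masking
noise, ZMN) or sets each to a fair coin flip (salt-and-pepper noise, SPN,
the default). Corruption is the only regularizer — no weight decay — and is
resampled freshly for every mini-batch of every epoch.

Optimization choices the underlying study leaves open were fixed as
follows, and are plain `dae_config()` parameters:

* mini-batch gradient descent, batch 128, initial learning rate 0.05;
* reduce-on-plateau: learning rate × 0.5 after 5 epochs without
  validation improvement; early stopping after 10 such epochs; at most 300
  epochs;
* a 10% validation split carved from the training matrix. Validation
  corruption is drawn **once** and frozen so that the validation denoising
  loss is comparable across epochs; the returned weights are those of the
  best validation epoch;
* Glorot-uniform initialization, zero biases, all randomness under one
  seed — identical seed and data give bit-identical weight trajectories.

Latent representations are extracted by encoding the *uncorrupted* matrix:
corruption is a training-time device only. On the default case-1 cohort the
validation loss falls to roughly 0.02 nats/feature, far below the
$\log 2 \approx 0.693$ of an uninformative constant-0.5 predictor.

## Clustering and choosing the number of clusters

Two clustering methods run on the latent matrix, both under Euclidean
distance:

* `kmeans_cluster()` — Lloyd's algorithm with k-means++ seeding, best of 10
  restarts by within-cluster sum of squares. The per-iteration inertia
  trace of the winning restart is retained (it must be non-increasing, and
  the tests assert it). Empty clusters are re-seeded at the farthest point.
* `ahc_ward()` — agglomerative hierarchical clustering under the Ward
  criterion, computed by `stats::hclust(method = "ward.D2")` and cut at k;
  the merge history (pairs and heights) is kept. The test suite checks the
  partitions against an exhaustive brute-force Ward agglomerator on small
  instances.

Three cluster-validity indices score each candidate k:

* **silhouette** — mean over samples of $(b-a)/\max(a,b)$; singletons
  contribute 0;
* **Davies–Bouldin** — mean over clusters of the worst
  $(s_i+s_j)/d_{ij}$ ratio; coincident centroids give an infinite index
  with a warning;
* **BIC** — the spherical-Gaussian (x-means style) formulation
  $-2\log L + p \log n$ with one pooled variance and
  $p = kd + k$ free parameters; a variance floor ($10^{-9}$) guards
  degenerate single-point clusters. Lower is better; on a smoothly
  decreasing curve the **elbow** is the k with the largest second forward
  difference, ties toward smaller k, and a curve with no positive curvature
  returns the smallest interior k with a warning.

`select_n_clusters()` tabulates all three indices for both methods and
selects k* by majority among the preferred method's (default: Ward)
silhouette argmax, Davies–Bouldin argmin and BIC elbow. When all three
disagree the silhouette's choice wins; remaining ties break toward smaller
k. This is a deliberately fixed, automatic rule: the emulated study partly
used judgment for its second case study, which no index formula reproduces.

The number of clusters is selected on the *training* latent
representations; the *test* subset is then clustered afresh with Ward at k*
for characterization. (A nearest-centroid transfer of train clusters would
be the alternative; refitting was chosen because the clusters are
characterized on test data in the emulated design. Both give the same
partitions on cleanly separated cohorts.)

## Cluster characterization

`compute_profile()` is the presence-rate profile (column means) of a
patient subset; an exact identity — the profile of a union of disjoint
subsets is the patient-count-weighted mean of the subset profiles — is
asserted in the tests. `top_codes()` ranks the top five codes per family
(descending rate, ties lexicographic). `profile_pcc()` computes the Pearson
correlation between two profiles separately over the diagnosis block and
the drug block (the two-value convention used for cluster-vs-CRG tables); a
whole-vector value is also returned. `cross_tabulate()` and `age_summary()`
produce the cluster-vs-CRG counts/row-percentages and the five-number age
summaries. Age and sex never enter representation learning or clustering —
the model matrix has exactly the D code columns.

## Synthetic patients and trajectories

A *simple* synthetic patient is a one-hot vector at one target code; the
*complex* patients for an ordered code list (descending presence rate in
the source cluster) are the indicators of the first 2, 3, …, N codes —
each nests the previous one. Encoding them with the trained DAE and
embedding them **jointly** with the cohort in one t-SNE run places each
synthetic patient in the patient map; the ordered complex-patient
positions trace a health-status trajectory as codes accumulate.

t-SNE has no native out-of-sample projection and the emulated study does
not say how its synthetic patients were mapped; joint embedding (appending
the synthetic rows before fitting) is this package's documented choice, and
synthetic patients are excluded from clustering and profiling. The t-SNE
itself is implemented in the package (`tsne_embed()`): exact $O(n^2)$
affinities with per-point bisection to the target perplexity (default 30),
early exaggeration ×12 for 250 iterations, momentum 0.5 → 0.8, adaptive
gains, learning rate 200, 1,000 iterations by default, seeded initial
layout — adequate for the few thousand points these analyses embed.

## Numerical choices and degenerate inputs

* Reconstruction probabilities are clipped to $[10^{-7}, 1-10^{-7}]$
  inside the cross-entropy.
* `corrupt()` rejects non-binary input; `train_dae()` with
  `max_epochs = 0` returns the initialized untrained model.
* Codes are uppercased before matching; duplicate raw codes collapsing to
  one truncated code set a single presence bit; unknown codes are dropped
  with a reported count by default (or rejected on request).
* ICD9-CM E-codes keep their 4-character stem: the rule is "everything
  before the decimal point", applied as written.
* Equal-rate ties in `top_codes()` and equal-cost choices in the selection
  rule break deterministically (lexicographic / smaller k).

## Problem sizes used by the tests

The acceptance-level checks run the full design: cohorts of 61,448 and
64,627 patients generated at $D = 2{,}263$, under-sampled to 6,498 / 8,664,
DAE trained on 4,873 / 6,498 patients, k selected over 2–10. Unit tests use
reduced instances chosen for speed with the same structure: a 92-code
vocabulary containing all signature codes, cohorts of a few hundred
patients, $d = 5$–8 latent units, and brute-force oracles on n ≤ 30. The
trajectory checks embed a few hundred points at perplexity 15–20.

## Known limitations

* Within-group code independence (beyond the severity factor) is a
  simplification; real comorbidity correlation will make latent clusters
  elongated rather than spherical, and the spherical-Gaussian BIC
  correspondingly less calibrated.
* The cluster-number rule is fully automatic, and mean-silhouette
  maximization structurally favours merging a clinically *intermediate*
  group into a neighbour: a multimorbid population that shares both the
  hypertension and the diabetes bundle sits between those clusters, so the
  silhouette curve is nearly flat across the last candidate splits and the
  majority rule can settle one below the generating number of groups even
  when clustering *at* that number recovers the groups almost perfectly.
  Borderline index curves can also flip between adjacent k across seeds.
  When the indices disagree, inspecting the returned `cvi_table` (and the
  cluster-vs-CRG cross-tabulation at the competing k) is more informative
  than the single k* number.
* The non-signature vocabulary positions are placeholders: real code
  identities matter only for the signature codes the generator elevates.
* Exact t-SNE is quadratic in points; embedding much beyond ~5,000 points
  calls for a Barnes–Hut implementation, which this package does not
  provide.
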