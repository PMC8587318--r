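---
title: "Clustering-guided hierarchical activity recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-guided hierarchical activity recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harclust)
```

## The problem

Wearable-sensor activity recognizers are usually *flat*: one classifier
decides among all predefined activities in a single step. When two
activities produce similar inertial signals — go-upstairs vs.
go-downstairs, sitting vs. lying — the flat decision boundary is dominated
by the easy separations (static vs. dynamic) and under-serves the hard
ones. A *hierarchical* recognizer fixes this by re-deciding among a small
set of mutually confusable activities with a dedicated second-level model.
The catch is knowing **which** activities are confusable without relying on
prior domain knowledge.

`harclust` answers that question from the data itself, by clustering.

## The confusion index

Let $D = (X, Y)$ be a labeled training set over the ordered activity set
$L$, and partition its samples into $k$ clusters (default $k = |L|$). For a
cluster $C$, its *majority activity* $L_i$ is the activity contributing the
most members of $C$. Every member of $C$ whose true activity is $L_j$ then
counts toward the *cluster confusion index* $\mathrm{conf}_C(L_j \to L_i)$,
and summing over all $k$ clusters gives the *activity confusion index*

$$\mathrm{conf}(L_j \to L_i) \;=\; \sum_{c=1}^{k} \mathrm{conf}_c(L_j \to L_i),$$

organized as the $|L| \times |L|$ confusion matrix $CM$ (source activity in
rows, cluster-majority activity in columns). The matrix conserves mass: its
entries sum to the number of clustered samples, and row $j$ sums to the
number of samples labeled $L_j$. Column-normalizing gives the confusion
ratio

$$\eta(L_j, L_i) \;=\; \frac{CM_{ji}}{\sum_{j'} CM_{j'i}},$$

the share of the samples drawn into $L_i$-majority clusters that truly
belong to $L_j$. The *confusing set* of an activity at threshold $\theta
\in (0, 1]$ is

$$S(L_A) \;=\; \{\, L_B \neq L_A \;:\; \eta(L_B, L_A) \ge \theta \,\}.$$

Three conventions make this well defined on real data, all of which are
visible in the packaged UCI-HAR confusion matrix
(`ucihar_confusion_fixture()`):

* **Majority ties** are broken by the earliest activity in the ordered
  label set. The argmax alone does not decide ties, and reproducibility
  requires a deterministic rule.
* **All-zero columns** (an activity that is never a cluster majority —
  walking and sitting in the packaged matrix) yield $\eta = 0$ for the
  whole column rather than 0/0; that activity simply acquires no
  confusers.
* The threshold comparison is **$\ge$**, so $\theta$ values that equal a
  ratio exactly keep the corresponding confuser.

Diagonal entries are stored (a cluster's majority members are counted like
everyone else) but excluded from confusing sets by the $L_B \neq L_A$
guard.

## The two-level recognizer

Training composes four steps (`fit_pipeline()`):

1. `partition()` — cluster the training features into $k$ groups;
2. `activity_confusion_matrix()` — tally $CM$;
3. `confusing_sets()` — threshold $\eta$ at $\theta$;
4. `train_hierarchical()` — fit the top-level classifier on all
   activities, and for every $L_A$ with $S(L_A) \neq \emptyset$ a
   second-level classifier on exactly the training samples whose true
   label lies in $\{L_A\} \cup S(L_A)$, with the full feature vector and
   no reweighting. That restriction-by-true-label is the minimal reading
   of "distinguish $L_A$ and $S(L_A)$"; no resampling or feature
   selection is layered on top.

Prediction routes each sample through the top-level model first; when the
top-level label has a second-level model, that model's decision is final,
otherwise the top-level label stands. Exactly two levels are used — the
construction is not applied recursively, and a singleton confusing set
simply yields a binary second-level model. Top and second levels may use
different classifier families (the *P–Q* pairings, e.g. naive Bayes on
top with a linear SVM below); when the families coincide the second level
reuses the spec verbatim.

Two structural consequences are worth knowing and are asserted in the test
suite: if every confusing set is empty the hierarchical model predicts
identically to the flat model, and a routed final label always lies in
$\{$top label$\} \cup S($top label$)$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| $\theta$ | 0.01 | minimum confusion ratio for set membership; the empirical working point. Small $\theta$ densifies the hierarchy, $\theta$ near 1 collapses it to the flat model. A broad band (roughly 0.01–0.05) behaves similarly. |
| `cluster_count_offset` | 0 | $k = |L| +$ offset. $k = |L|$ matches the presumed number of modes in the data. |
| clustering `algorithm` | k-means | also k-medoids (PAM) and Ward agglomerative. |
| clustering `metric` | euclidean | cosine and correlation are implemented by row-normalizing (resp. row-centering then normalizing) before Euclidean k-means — the standard spherical-k-means equivalence; for k-medoids the transformed pairwise distances are used directly. Ward linkage is defined for Euclidean geometry only, so requesting it with another metric is an error, never a silent substitution. |
| `n_restarts` | 10 | k-means/k-medoids restarts under an explicit seed. |
| classifier families | NB / 1-NN / linear SVM (cost 1) / unpruned tree | conventional instantiations: 1 neighbor with Euclidean distance, linear kernel, Gini impurity with unlimited depth. |

Feature scaling is off by default — published HAR feature tables arrive
normalized — with an optional z-score switch for other data.

## Numerical choices

* **k-means initialization** uses k-means++ seeding with
  `n_restarts` seeded restarts, keeping the lowest within-cluster sum of
  squares; the winning restart's initial and final objective are exposed
  on the returned partition, so the objective-non-increase invariant is
  directly checkable. Empty clusters (possible in degenerate geometries)
  are repaired by reseeding the vacant cluster with the sample farthest
  from its centroid, keeping the cluster count at exactly $k$; the repair
  is logged.
* **Determinism**: all randomness (restarts, tie-breaking in nearest
  neighbors, synthetic draws) flows from explicit integer seeds; a fixed
  seed reproduces assignments, models and predictions byte for byte.
* **Metrics** are macro-averaged: precision and recall are unweighted
  means over the training label set, and F1 is the harmonic mean of macro
  precision and macro recall — *not* the mean of per-class F1 scores,
  which is a different quantity. Macro averaging is an explicit assumption
  (recall can exceed accuracy under it, which matches the reported
  behavior of such recognizers, whereas micro averaging would force them
  equal). Classes absent from a test fold contribute a guarded 0 with a
  warning.
* **Degenerate inputs** fail loudly: non-finite features, a correlation
  metric on a constant row (named), $k$ larger than the sample count,
  single-class training data, feature-width mismatches at prediction
  time.

## The synthetic benchmark

`synthetic_spec()` / `generate()` emulate the core premise — activities
with different semantics but similar sensor readings — with
class-conditional spherical Gaussians and *planted groups*: class means
inside a group sit on a regular simplex with pairwise distance
`within_group_separation` × `noise_sd`, group centers on a simplex with
pairwise distance `between_group_separation` × `noise_sd`. The layout is
deterministic (group centers span the first $G-1$ dimensions, within-group
offsets the next $\max_g |g| - 1$), so recovery experiments never depend
on seed-dependent geometry. The defaults plant two groups of three
activities (dynamic: walking / go-upstairs / go-downstairs; static:
sitting / standing / lying) with within-separation 1, between-separation
8, noise 1, and 300 training / 150 test samples per class — a regime where
groups are unmistakable but group members genuinely overlap.

`dim` defaults to 6: three structural dimensions (one group axis plus a
two-dimensional within-group simplex) and three pure-noise dimensions.
Keeping the ambient dimension small is a deliberate choice: at
within-group separation of one noise standard deviation the planted mean
geometry is a modest share of total variance, and burying it under many
more isotropic noise dimensions would make any clustering-based analysis
insensitive by construction rather than by the method's merits.

**What recovery means.** `planted_confusion_sets()` returns the map
expected under ideal recovery: every activity linked to exactly its
groupmates. The package's recovery experiments report this *strict*
per-activity equality, and separately the *group-structure* criterion
(every derived link stays inside a planted group and every activity is
linked into its group as source or target). The two differ in a specific,
instructive way: at within-separation 1 the variance-optimal $k$-means
solution occasionally gives one group only two effective majority
activities — two clusters share a majority, the third activity never
names a cluster, its confusion column is all zero, and its own confusing
set comes out empty even though its groupmates still list it. Group
structure is recovered essentially always in this regime; strict
per-activity equality is recovered in roughly four of five seeds. This is
a property of the clustering objective at heavy overlap, not of the
confusion accounting.

**The entangled pair.** With purely spherical classes a flat classifier
has little headroom for routing gains, so the generator offers
`entangle_pair = TRUE`: two appended dimensions in which the first two
activities of the first group share a strong latent factor (inducing
correlation ≈ 0.9 between the two dimensions) and differ by a mean offset
along a *non-eigen* direction of that covariance. A diagonal-covariance
naive Bayes sees only the weak marginal shift and confuses the pair; a
linear decision rule can project against the correlation and separate it
cleanly. A literal XOR-style sign-flip construction was rejected because
it is not linearly separable and would therefore say nothing about a
linear-kernel second level. This is the configuration under which an
NB-top / linear-SVM-second hierarchy reliably beats flat naive Bayes —
on the package's benchmark the margin is three to five accuracy points,
with the hierarchical model winning in essentially every seed.

**What the benchmark does not emulate:** raw tri-axial waveforms,
windowing, autocorrelated noise, heavy-tailed or subject-specific
variation, class imbalance. Passing recovery tests here shows the
confusion accounting and routing machinery work as specified; it does not
certify accuracy on any particular real deployment.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run entirely on generated data
plus the packaged confusion matrix. The standard experiment sizes are 20
seeds × 1800 training samples (6 classes × 300) for recovery, and 20
seeds × 1800/900 train/test samples for the hierarchical-vs-flat
comparison; property tests use smaller draws (tens of samples per class)
since they check exact identities rather than rates.

## Known limitations

* The confusion measurement is only as good as the partition: with $k =
  |L|$ and heavily overlapped groups, a class can fail to claim any
  cluster majority (see above), leaving its own confusing set empty.
  Raising $k$ or using the offset convention mitigates this at the cost
  of finer-grained, noisier columns.
* Confusing sets are estimated from the *training* partition; they are
  not re-validated on held-out data.
* Exactly two levels; no probability-calibrated routing or reject
  option.
* The UCI-HAR loader consumes the published precomputed feature tables;
  the package does not extract features from raw inertial signals.
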