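# harclust

Clustering-guided hierarchical activity recognition for wearable-sensor
feature tables.

Human-activity recognizers trained in one step (*flat* models) struggle
exactly where it matters: pairs of activities whose inertial signatures
overlap, such as go-upstairs vs. go-downstairs or sitting vs. lying.
`harclust` discovers those confusable pairs **from the data**, with no
prior domain knowledge, and uses them to build a two-level recognizer
that re-decides the hard cases with dedicated second-level classifiers.

It is aimed at researchers and engineers working with windowed
accelerometer/gyroscope feature tables (rows = windows, columns =
real-valued features, one activity label per row), including the
UCI-HAR smartphone benchmark layout.

## The method

1. **Partition** the labeled training set $D = (X, Y)$ into $k$ clusters
   (default $k = |L|$, the number of activities; k-means, k-medoids or
   Ward agglomerative; Euclidean, cosine or correlation metric).
2. **Confusion accounting.** Each cluster is named by its majority
   activity $L_i$; a member truly labeled $L_j$ counts toward the
   activity confusion index
   $\mathrm{conf}(L_j \to L_i) = \sum_{c=1}^{k}\mathrm{conf}_c(L_j \to L_i)$,
   collected into the $|L| \times |L|$ matrix $CM$.
3. **Confusing sets.** Column-normalize to ratios
   $\eta(L_j, L_i) = CM_{ji} / \sum_{j'} CM_{j'i}$ and threshold:
   $S(L_A) = \{ L_B \ne L_A : \eta(L_B, L_A) \ge \theta \}$
   (default $\theta = 0.01$).
4. **Two-level recognizer.** A top-level classifier over all activities,
   plus, for every activity with a non-empty confusing set, a
   second-level classifier over $\{L_A\} \cup S(L_A)$. Predictions route
   through the top level and are refined by the matching second-level
   model. Top and second levels may use different families (naive Bayes,
   1-NN, linear SVM, decision tree).

See `vignettes/clustering-guided-recognition.Rmd` for assumptions,
numerical conventions and design rationale.

## Worked example

The package ships a reference activity confusion matrix for the six
UCI-HAR activities (7352 training windows, k-means with $k = 6$):

```r
library(harclust)
cm <- ucihar_confusion_fixture()
cm
#> activity_confusion: 6 activities, 7352 samples
#>               walking go-upstairs go-downstairs sitting standing lying
#> walking             0         629           597       0        0     0
#> go-upstairs         0         822           251       0        0     0
#> go-downstairs       0         137           849       0        0     0
#> sitting             0           1             0       0     1236    49
#> standing            0           0             0       0     1374     0
#> lying               0          10             0       0      164  1233

confusing_sets(cm, theta = 0.01)
#> confusing_set_map (theta = 0.01):
#>   S(walking) = {}
#>   S(go-upstairs) = {walking, go-downstairs}
#>   S(go-downstairs) = {walking, go-upstairs}
#>   S(sitting) = {}
#>   S(standing) = {sitting, lying}
#>   S(lying) = {sitting}
```

Reading the output: 629 of the 1599 windows that fell into
go-upstairs-majority clusters are truly walking
($\eta = 629/1599 \approx 0.39$), so walking is a confuser of
go-upstairs; the walking and sitting columns are all zero, so those two
activities keep their top-level decision. Second-level models are built
for the four activities with non-empty sets.

End to end on the synthetic planted-group benchmark (two confusable
groups of three activities; `entangle_pair` plants a correlated pair
that defeats naive Bayes but not a linear SVM):

```r
spec <- synthetic_spec(entangle_pair = TRUE, seed = 42)
draw <- generate(spec)
model <- fit_pipeline(draw$train, part_spec = partition_spec(seed = 42),
                      theta = 0.02,
                      top_spec = classifier_spec("naive_bayes"),
                      second_spec = classifier_spec("svm_linear"))
evaluate(model, draw$test)
#> metrics_report: accuracy 0.6156  precision 0.6151  recall 0.6156  F1 0.6153

evaluate(train_flat(draw$train, classifier_spec("naive_bayes")), draw$test)
#> metrics_report: accuracy 0.5822  precision 0.5826  recall 0.5822  F1 0.5824
```

The hierarchy lifts flat naive Bayes by about three accuracy points by
re-deciding the routed, confusable windows with the linear SVM. Accuracy
is the fraction correct; precision/recall/F1 are macro-averaged (F1 = the
harmonic mean of macro precision and macro recall).

A thin CLI over the same functions lives at `inst/cli/harclust`
(subcommands `simulate`, `analyze-confusion`, `train`, `predict`,
`evaluate`, `sweep`; see `?run_config`).

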