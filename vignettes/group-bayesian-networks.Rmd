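---
title: "Group Bayesian networks: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group Bayesian networks: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large biomedical tables — cohort questionnaires, laboratory panels, imaging
summaries — mix hundreds of quantitative and qualitative variables that come
in highly redundant blocks (anthropometry, lipid panels, blood counts, ...).
A Bayesian network over all raw variables is hard to learn and hard to read:
structure learners spend their statistical budget on the very strong
within-block dependencies and rarely connect blocks to each other, and the
resulting graphs are too large to interpret. `groupnets` instead learns a
*group Bayesian network*: variables are first clustered into groups of
similar variables, each group is compressed into a single synthetic
representative, and a discrete Bayesian network is learned among the group
representatives plus a *separated* outcome of interest (and, optionally,
separated confounders such as age or sex). The grouping is then refined
adaptively, but only where it matters for the outcome.

## Variable clustering and group representatives

Mixed variables are clustered agglomeratively. The *homogeneity* of a
cluster is the first eigenvalue of its PCAmix factorization: quantitative
columns are standardized (zero mean, unit population variance), each
qualitative variable is expanded into centered indicator columns divided by
the square root of the category proportion, the blocks are concatenated and
the leading eigenvalue of `Z'Z / n` is taken. Equivalently, homogeneity is
the sum over member variables of the squared correlation (quantitative) or
the correlation ratio eta-squared (qualitative) with the cluster's first
principal scores; it ranges from 0 to the cluster size. Each merge joins
the pair of clusters that loses the least homogeneity, and that loss is the
merge height. Losses are recomputed exactly for every candidate pair
(O(p^3)-ish, fine for a few hundred variables); ties are broken by the
lexicographically smallest pair of member names so dendrograms are
reproducible. Because this criterion is not of Lance–Williams form,
occasional height reversals are possible; reported heights are the
cumulative maximum of the raw losses (both are stored) and cutting works by
merge order, which coincides with cutting by height when heights are
monotone.

A cluster's representative is its first PCAmix component by default
(`representative = "pc"`), or the *medoid* member
(`representative = "medoid"`): the member minimizing the total dissimilarity
`1 - association^2` to the others (squared correlation, eta-squared, or
squared Cramér's V depending on the kinds involved). Representatives store
their centering/scaling constants, category proportions and coefficients so
that held-out rows are projected exactly as training rows were. Scores are
oriented so the first member's first loading is nonnegative; principal
directions are otherwise sign-ambiguous and serialization would not be
reproducible. Singleton quantitative groups reduce to the standardized
variable itself; singleton qualitative groups keep their levels directly as
node states — a one-column qualitative block would otherwise be forced
through a lossy one-dimensional score.

The *aggregation levels* — the homogeneity loss removed when moving from
`k - 1` to `k` groups — help choose the initial group count; the `"auto"`
setting takes the largest second difference of that curve (the elbow),
which should be treated as a starting point, not an oracle. The refinement
below assumes the initial grouping is fine enough that the relevant direct
relations can be represented at all.

## Discretization

Representatives are often multimodal (they reflect discrete latent
structure), so they are discretized with a density-approximative rule
before structure learning: a Gaussian kernel density estimate (Silverman's
`bw.nrd0` bandwidth, 512-point grid spanning one bandwidth beyond the data
range) is computed on the standardized scores; a *significant peak* is a
local maximum with height at least 10% of the density maximum and
prominence (height above the higher flanking minimum) at least 5% of the
maximum. With two or more significant peaks, a one-dimensional k-means with
k equal to the peak count, initialized at the peak locations, is run and
bin boundaries are the midpoints between sorted final centroids; with a
single peak the sample quartiles are used (four bins). Boundaries that
would leave an empty training bin are dropped. Bins are right-open
intervals `[b[i-1], b[i])` — a value exactly on a boundary belongs to the
upper bin — and fitted maps are stored so held-out folds are binned with
training-fold boundaries. Vectors need at least 8 observations and
non-zero variance.

## Structure and parameter learning

All variables entering the network are discrete (group bins, separated
qualitative levels, or separated quantitative variables discretized with
the same rule). The score is the decomposable BIC of a categorical network,

  sum_jk N_ijk log(N_ijk / N_ij.) - q_i (r_i - 1)/2 log N

per node (higher is better; written as penalized log-likelihood and
maximized). Search is greedy hill climbing over single-arc additions,
deletions and reversals, accepting strictly improving moves only — strict
improvement plus a finite move set guarantees termination and, given a
seed, determinism. At each local optimum the best structure found so far is
perturbed by random legal arc changes (10% of its current arc count, at
least 1) and the climb restarts; 10 restarts by default.

To suppress false-positive arcs, structure learning is repeated on
nonparametric bootstrap resamples of the rows (`B = 200` by default). Arc
*strength* is the inclusion frequency in either direction, *direction* the
conditional orientation frequency. The inclusion threshold is chosen
adaptively: among the observed strengths (and 0), the threshold minimizing
the L1 distance between the strength vector and its thresholded 0/1
idealization is selected, smallest value on ties. Retained arcs are
oriented by majority direction; a directed cycle, should one arise from
averaging, is broken by dropping its weakest arc. Parameters are then fit
on the averaged structure by Bayesian estimation with a uniform prior and
imaginary sample size 1, so unseen parent configurations yield uniform
columns rather than zeros.

Structures are compared as completed partially directed acyclic graphs
(CPDAGs): v-structures are kept directed, the standard orientation-closure
rules are applied, and remaining edges are undirected. The implementation
is validated against exhaustive enumeration of Markov equivalence classes
on all DAGs with up to four nodes.

## Prediction and the refinement objective

Class probabilities of the target are estimated by likelihood weighting
with *all* non-target nodes fixed as evidence. With full evidence the
posterior factorizes over the target's Markov blanket, which makes an exact
single-node posterior available as well; the likelihood-weighting estimate
is the same quantity plus multinomial sampling noise, and the test suite
checks their agreement on random networks. Rows whose evidence has zero
probability under the model receive a uniform posterior with a warning.

The refinement objective for a binary outcome is the class-weighted
cross-entropy H = -sum_i w_i log p_i, where p_i is the predicted
probability of row i's *observed* class and w_i = 1 / (2 #\{j : o_j =
o_i\}), so each outcome class contributes total weight 1/2 regardless of
imbalance. Without this reweighting the search would favor models that
simply predict the majority class. (A literal class-proportion weighting
w_i = #\{o = o_i\}/N, which overweights the majority class, is available
behind `literal_weights = TRUE` for comparison, but contradicts the
equal-share intent and is not the default.) For targets with more than two
observed classes the same inverse-frequency construction is applied, each
class again receiving an equal total share. Because p_i is a Monte-Carlo
estimate, the loss is itself stochastic: it is recomputed over `runs = 20`
independent likelihood-weighting runs and summarized by its mean and its
(min, max) band.

Refinement (hill climbing over groupings) starts from the `k`-group cut:
every splittable group in the target's Markov blanket (optionally widened
to a moralized-graph distance via `max_distance`) is split into the two
children of its dendrogram node, the structure search is warm-started with
the incumbent structure (both halves inherit the split group's arcs), and
the candidate with the lowest loss is accepted *only if it falls below the
lower end of the incumbent's uncertainty band*. This acceptance rule makes
the accepted-loss sequence strictly decreasing and the loop provably
finite. The loss is evaluated in-sample during refinement; generalization
is measured separately by the cross-validation harness, which refits
clustering, binning and structure on training folds only. Refinement-level
random restarts are not implemented (only structure-level restarts are);
ties among candidate splits go to the smallest group id, and per-candidate
sub-seeds are derived deterministically from the run seed.

## The two-layer simulator

Ground-truth data are generated from a two-layer model: layer 1 is a DAG
over latent group variables sampled uniformly from all labelled DAGs by a
Markov chain (propose a random ordered pair; remove the arc if present,
add it if acyclicity allows; burn-in 10 n^2 proposals, validated by a
chi-square uniformity check over all 25 labelled 3-node DAGs), with
conditional probability columns drawn from a symmetric Dirichlet(1) —
uniform on the simplex — and 3 states per variable by default. Each group
emits `group_size` observed children; a child is discrete with probability
`frac_discrete_children`. A discrete child copies its parent's state with
probability 1 - eps and otherwise takes a uniformly random other state, so
its misclassification rate against the parent is exactly eps. A continuous
child has state-specific means 0, 1, ..., r-1 and Gaussian noise with
sigma = -1 / (2 qnorm(eps)), which sets the adjacent-state Bayes error to
eps and makes the noise level comparable across child kinds. Noise lives in
the emission (measurement) layer; the latent layer is noise-free.

The *network baseline* mimics inferring groups from a detailed network:
a structure is learned over all layer-0 variables, greedy-modularity
hierarchical community detection is run on its moralized skeleton, the
dendrogram is cut at every level and the cut closest to the true grouping
under the partition metric is kept — a deliberately charitable choice for
the baseline. Its group arcs are projected through the *true* grouping:
one arc between groups whenever at least one detailed arc crosses them,
majority direction on conflicts, lexicographic collapse on exact ties.

## Evaluation metrics

Groupings are compared by variation of information (conditional entropy in
both directions, natural log units): zero exactly for identical partitions,
symmetric, and a true metric. Structures are compared by the structural
Hamming distance between CPDAGs — each missing, extra or differently
oriented edge counts one — normalized by the ground-truth edge count.
Discrimination is summarized by AUROC (rank statistic with midrank tie
correction) and AUPRC (trapezoidal precision-recall integral over the
positive class's recall). Cross-validation is stratified by target class —
the data could otherwise produce single-class folds — and the fold
assignment depends only on the seed, so compared methods see identical
folds. To compare a learned group network with the latent truth, learned
groups are mapped onto true groups by majority member overlap before the
SHD is taken.

## Problem sizes and study settings

The package's own simulation study (`run_simulation_study`) and test suite
run at desk scale: 10 groups of 5 children, 500 training rows, 20
replicates per scenario, bootstrap `B = 50` with 2 restarts for the study
arms, and one randomly chosen discrete child per replicate as the
prediction target (held-out error on 200 fresh rows). Model-building
defaults remain `B = 200`, 10 restarts, imaginary sample size 1; the study
grid, replicate count and learner settings are all configurable upward.

## Known limitations

* One-dimensional representatives can collapse latent states. With 3-state
  latent groups and mostly-discrete children, the first PCAmix component
  sometimes projects two latent states close together; the representative's
  density then genuinely has two modes, the peak-initialized binning yields
  two bins, and one latent state becomes indistinguishable. In the
  simulator this is visible as held-out prediction error rising above the
  emission noise level as noise grows (at eps = 0.1 the gap is small, at
  eps = 0.2 it reaches ~0.1 extra error). Multi-dimensional or multi-bin
  representatives would remove the collapse but are out of scope.
* The simulator's children have exactly one latent parent and two layers;
  real data have overlapping blocks, latent confounding and missingness
  patterns that the generator does not emulate, so passing simulation
  checks demonstrates correct mechanics and favorable behavior under the
  modeled conditions, not performance guarantees on arbitrary cohorts.
* Residual missing values are imputed by median/mode before clustering —
  a simple stand-in, adequate after the 20% missingness filter but not a
  principled missing-data treatment.
* The refinement objective covers binary (or small categorical) targets
  only; continuous outcomes would need a different loss.
* `iss = 0` disables prior smoothing and yields maximum-likelihood tables;
  unseen parent configurations then produce undefined columns, so the
  default `iss = 1` is recommended except in controlled experiments.

## A minimal workflow

```r
library(groupnets)

D <- read_mixed_table("cohort.csv")          # mixed CSV with header
D <- impute_simple(filter_missing(D, 0.2))   # drop >20%-missing, impute
H <- cluster_variables(D, exclude = c("outcome", "sex", "age"))
aggregation_levels(H)                        # pick k at the elbow

M <- refine(D, H, k = 15, target = "outcome",
            separated_extra = c("sex", "age"))
predict(M, D)                                # class probabilities
model_to_json(M, "model.json")
export_group_network(M, "model.graphml", "graphml")
```

The same pipeline is scriptable through `exec/groupnets`
(`cluster`, `learn`, `refine`, `predict`, `simulate`, `evaluate`), each
subcommand writing its artifact plus a manifest with the full configuration
and seed.
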