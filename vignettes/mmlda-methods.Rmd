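---
title: "Multi-modal topic modeling of disease omics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal topic modeling of disease omics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mmlda` soft-clusters human diseases from several classes of disease-omics
annotations at once — altered expression (Ae), biomarkers (Bm), genetic
variation (Gv), microbiota (Mb), or any other tagged association list. The
model is a multi-modal extension of latent Dirichlet allocation: diseases
play the role of documents and omics features the role of words, but each
modality keeps its own vocabulary and its own topic–feature distributions,
while all modalities of a disease share a single topic-weight vector.

For disease $d$, token $i$ of modality $(\cdot)$:

$$
\theta_d \sim \mathrm{Dirichlet}(\alpha), \qquad
\phi_k^{(\cdot)} \sim \mathrm{Dirichlet}(\beta^{(\cdot)}),
$$
$$
z_{di}^{(\cdot)} \sim \mathrm{Multinomial}(\theta_d), \qquad
w_{di}^{(\cdot)} \sim \mathrm{Multinomial}(\phi^{(\cdot)}_{z_{di}}).
$$

The shared $\theta_d$ is the "cross-referencing" that distinguishes this
from running one LDA per modality or concatenating vocabularies: evidence
from every modality moves the same topic weights, so a disease's microbiota
can sharpen the topics that explain its expression changes, without the two
vocabularies ever being mixed.

## Estimation

The sampler is the explicit (uncollapsed) Gibbs scheme over the model's
full conditionals:

* token assignments: $p(z = k \mid w = v) \propto \theta_{dk}\,\phi^{(\cdot)}_{kv}$;
* topic weights: $\theta_d \mid z \sim \mathrm{Dirichlet}(\alpha + n_d)$
  with counts pooled over all modalities;
* feature weights: $\phi^{(\cdot)}_k \mid z, w \sim \mathrm{Dirichlet}(\beta +
  m^{(\cdot)}_k)$;
* each imputed token of a held-out modality: $w' \sim \phi^{(\cdot)}_{z}$.

We keep the uncollapsed form rather than a collapsed sampler because the
imputation mechanism consumes the explicit $\phi$ draws, and because the
conditionals above are the model's defining equations. Initialization sets
$\theta$ and $\phi$ to uniform distributions, topic assignments to uniform
draws, and imputed tokens to uniform vocabulary draws (a categorical draw
from a uniform $\phi$). Updates are systematic-scan in a canonical order
(modalities, then diseases, then tokens, in corpus order), and one seeded
RNG stream drives everything, so a run is exactly reproducible.

Defaults: $\alpha = \beta = 0.1$ elementwise, 5000 sweeps. The topic
distribution stabilizes within roughly 1000–2000 sweeps on corpora of this
shape, so averaging starts after a burn-in of 2000 by default; both numbers
are configuration. Posterior means of $\theta$ and $\phi$ are averages of
the post-burn-in draws.

### Missing-modality imputation

Holding out one (disease, modality) block replaces the removed tokens with
$n'$ imputed slots. $n'$ is drawn once at initialization from
$\mathrm{Binomial}(V, \hat p)$ with $\hat p = \overline{n}/V$, the mean
observed per-disease token count of that modality over $V$; the binomial
with both parameters free has no stable maximum-likelihood solution, and
fixing the size at $V$ matches the support (a disease cannot carry more
distinct features than the vocabulary holds). Zero draws are rejected so
the disease stays scoreable. The *likeliness* of feature $v$ is the number
of post-burn-in sweeps in which any slot sampled $v$, divided by the number
of averaged sweeps; with several slots it can exceed 1, and only its
ranking and thresholding are consumed downstream. Imputed tokens feed back
into the $\phi$ count statistics by default (the conditional for $\phi$
sums over all tokens); `include_imputed_in_phi = FALSE` exposes the
alternative reading.

### Choosing the topic number

For each modality we build the disease graph whose edge weights count
shared features, run weighted Louvain modularity optimization (resolution
1.0) twenty times with distinct seeds, take the modal community count, and
use the maximum over modalities as $K$. Mode ties break toward the larger
count: with the sparse 0.1 prior an overshoot leaves near-empty topics and
is benign, while an undershoot forces distinct feature blocks into one
topic. Isolated diseases count as singleton communities.

## Evaluation and latent discovery

Leave-one-modality-out evaluation removes one modality of one test disease
at a time (all other diseases keep everything), scores the full vocabulary
by likeliness, labels each item by its presence in the removed block, and
summarizes with the trapezoidal AUC. The binarization cut-off is the
threshold maximizing the Youden index $TPR - FPR$; ties break toward the
highest threshold, the most conservative positive set. A threshold admits
every item scoring at or above it.

Latent features are the thresholded predictions filtered twice: features
already recorded for the disease are removed (they are correct
re-predictions, not discoveries), and features *derived from* apparently
related diseases are removed, where "derived from" uses the strict rule — a
feature is dropped if any carrying disease matches the name-pattern list
(`carrier_rule = "all"` gives the lenient variant). The package ships the
cardiovascular/renal pattern list used for chronic kidney disease and
myocardial infarction targets; patterns are case-insensitive substrings and
a trailing `**` wildcard is accepted. Latent similarity then counts, for
each training disease, how many latent features it carries.

The generic annotation-enrichment step tests each category with a 2×2
chi-square (Yates continuity correction, the standard choice for 2×2
tables) and adjusts p-values across categories with Benjamini–Hochberg. The
background universe is always an explicit argument — results change
materially between a measured-feature background and a genome-wide one, so
the package never picks one silently.

## The path classifier

Directed pathway graphs with KEGG-style identifiers are reduced to *paths*:
simple node sequences from a drug-target node to any node with outdegree 0,
enumerated depth-first in sorted-neighbor order. Real pathway graphs
contain cycles, and unbounded enumeration is infinite, so extraction caps
path length (default 30 nodes) and path count (default 10⁴, with a
warning). Path relatedness is the normalized Levenshtein similarity
$1 - d(N, M)/\max(|N|, |M|)$ with unit edit costs over whole identifiers.

Two feature constructions feed the per-label classifiers:

* **Method A** — similarities of each path to every path rooted at a target
  of the label, reduced by PCA; components are kept to 99% cumulative
  variance, and the centering/loadings are frozen at training time.
* **Method B** — for each drug target, the rows of its paths' similarity
  matrix against all paths are correlated (Pearson), clustered by
  average-linkage on the distance $1 - r$, and cut at 0.2; one reference
  pool is then sampled per (start node, cluster) pair, capped at
  $\lceil 500/n \rceil$ paths per pair over $n$ distinct pairs. Features
  are raw similarities to the sampled references.

Each label gets ten gradient-boosted tree models, each trained on an
independent 1:1 under-sample of the majority class; a path is called
positive when at least 6 of the 10 models score it at or above 0.5.
Hyperparameters (`max_depth` in {3, 5}, learning rate in {0.1, 0.3}) are
chosen once per ensemble on a 20% validation split of a balanced
downsample. The 9:1 training/holdout split is stratified by label and made
at the path level, once, globally.

One training-time correction matters: a training path that is itself a
reference column has similarity exactly 1 to itself. That entry identifies
"is a reference" rather than anything about the label, and tree ensembles
will key on it — in our planted-motif experiments they scored every
held-out positive as negative while fitting the training set perfectly. The
self entry is therefore replaced by the path's best non-self similarity
before fitting; prediction-time queries are never references, so prediction
is untouched.

## What the synthetic generators emulate

`generate_corpus()` draws corpora from the model's own generative process:
$\theta^\ast \sim \mathrm{Dirichlet}(\alpha_{gen})$, per-modality
$\phi^\ast_k$ drawn from $\mathrm{Dirichlet}(\beta_{gen})$ and interpolated
by a `separation` parameter between the uniform distribution (0 — no
signal of any kind) and the draw confined to the topic's own vocabulary
block (1 — disjoint per-topic vocabularies). Token counts per
disease/modality are uniform on a small range (default 8–15); real
association databases are heavier-tailed, but uniform counts keep recovery
experiments interpretable. Repeated feature draws collapse to one token,
matching the association-list data model. Ground truth is returned for
recovery tests.

The generators do **not** emulate: synonymous disease naming, ontology
structure, cross-modality correlation beyond the shared topics, annotation
noise, or the heavy-tailed degree structure of real disease–gene networks.
A recovery AUC on these corpora is evidence the machinery works where its
assumptions hold, not a performance claim about DisGeNET-scale data.

`generate_pathway_fixture()` plants label–motif associations: each drug
target roots paths built from private prefix nodes, and paths of labeled
drugs run into the label's motif — a shared node chain ending at an
outdegree-0 node — with probability $1 - $`noise_rate`. Ending the motif at
a sink means depth-first extraction returns exactly the planted paths (a
shared mid-path motif would cross-multiply prefixes and continuations);
back-edges inside prefixes add cycles without creating new root-to-sink
simple paths. The default condition is 200 targets with one path each:
with several paths per target, per-start labels are learnable from start
identity alone, which would leave residual skill even in the
`noise_rate = 0.5` no-signal condition.

`generate_hidden_twin_corpus()` plants the full latent-similarity
scenario in tiers — a common feature block the target already carries
(filtered as known), a mid tier of weakly-carried known features (these
pull the Youden threshold down into the score tier where single-carrier
features live), a twin-exclusive block carried by one same-topic disease
(the planted latent signal), and a decoy feature carried only by a disease
named to match the pattern list.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: recovery corpora of
$D = 60$, $K = 3$, three modalities of $V = 50$ at separation 0.9 (signal)
and 0 (chance), fitted for 1500 sweeps with burn-in 500, scored over 20
test diseases; topic-number selection on 45-disease three-block corpora;
the twin corpus at $D = 40$ for 2000 sweeps; and classifier fixtures of 200
paths with holdout F1 averaged over three fixtures (a 20-path holdout
quantizes a single F1 in steps of roughly 0.09). Sweeps are vectorized
over tokens, so a 1500-sweep fit takes on the order of a second.

Numerical details worth knowing:

* every $\theta$/$\phi$ row is an exact normalization of positive gamma
  draws; an (astronomically unlikely) all-zero gamma vector falls back to
  uniform rather than NaN;
* a token whose conditional weights are all zero (possible only with
  degenerate hand-built $\phi$) raises an error rather than silently
  renormalizing;
* model serialization writes 17 significant digits, which round-trips IEEE
  doubles exactly — a reloaded model reproduces the imputation ranking bit
  for bit;
* Youden and mode ties have fixed, documented directions (highest
  threshold; larger count), so reruns are stable across platforms.

## Known limitations

* Disease-name merging is exact-string (after possessive normalization and
  an optional user synonym map); no terminology service is consulted.
* The binomial slot-count model is a pragmatic reading of an
  under-specified step; the slot count only scales likeliness, so ranking
  is insensitive to it, but absolute likeliness values are not comparable
  across modalities with very different vocabularies.
* Louvain community counts on dense weighted graphs can drift with the
  resolution parameter, which is fixed at 1.0.
* The classifier treats each label independently; co-occurring labels and
  off-target effects are out of scope.
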