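---
title: "Topology-aware two-sample tests for pathway expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware two-sample tests for pathway expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathGGM)
```

## The model

Most gene-set analyses treat a pathway as an unstructured list of genes.
pathGGM instead keeps the pathway's wiring: the two experimental
conditions are modelled as a pair of graphical Gaussian models (GGMs)

$$
\mathcal{M}_i(G) = \{\, Y \sim N_p(\mu_i, \Sigma_i),\;
\Sigma_i^{-1} \in S^+(G) \,\}, \qquad i = 1, 2,
$$

sharing one undirected graph $G$: $S^+(G)$ is the set of symmetric
positive definite matrices with zeros at the non-edges of $G$, so a
missing edge encodes conditional independence of two genes given the
rest of the pathway.  Log-scale expression is taken as approximately
normal.  $G$ is *fixed in advance* by biology, not learned from data:
the pathway diagram is oriented into a DAG $D$ (inhibition and
(de)phosphorylation arrows become plain directed edges; undirected
interactions are oriented by a hint column or, by default,
lexicographically), and $G = D^m$ is the moral graph of $D$ — parents
of a common child are "married" and directions dropped.

Two null hypotheses are tested.

1. **Equal strength of relations**, $H_0 : K_1 = K_2$ with
   $K_i = \Sigma_i^{-1}$.  The likelihood ratio statistic is
   $$-2\log\lambda = \sum_{i=1}^{2} n_i
   \log\frac{\det \hat K_i}{\det \hat K},$$
   where $\hat K_1, \hat K_2$ are the graph-constrained estimates from
   each arm and $\hat K$ the estimate from the pooled covariance
   $S = \{(n_1-1)S_1 + (n_2-1)S_2\}/(n_1+n_2-2)$.  Its asymptotic null
   distribution is $\chi^2_{p+r}$ with $p$ vertices and $r$ edges of
   $G$.
2. **Equal means**, $H_0 : \mu_1 = \mu_2$, tested *after* deciding on
   covariance homogeneity: if hypothesis 1 is not rejected the test
   assumes a common constrained $\Sigma$; otherwise it is the
   graph-constrained Behrens–Fisher problem with separate constrained
   covariances.  Both variants are likelihood-ratio tests referred to
   $\chi^2_p$.

Because a rejection of either global hypothesis says nothing about
*where* in the pathway the change lives, both tests are repeated on
every maximal clique of a triangulated (chordal) version $D^t$ of $G$.
On a clique the constrained model is saturated, so the covariance test
reduces to the classical unconstrained two-sample LRT
(df $= c(c+1)/2$ for a clique of size $c$), and the mean test can even
be *exact* (Hotelling $T^2$ with its $F$ reference) whenever the
clique's covariance test does not reject.

## Constrained estimation

The constrained MLEs are computed by iterative proportional scaling
(IPS): starting from the independence fit, cycle over the maximal
cliques of $G$ and update
$K_{CC} \leftarrow K_{CC} + S_{CC}^{-1} - (\Sigma_{CC})^{-1}$ so that
each fitted clique marginal matches the input matrix.  At convergence
the fitted covariance equals the input on every edge and on the
diagonal, while the concentration is exactly zero elsewhere.  For
chordal graphs the same estimate has a junction-tree closed form (sum
of padded clique-inverse blocks minus separator blocks), implemented in
`decomposable_mle()` purely as an independent cross-check of the IPS
iterate — the tests always use IPS.

Numerical choices:

* IPS convergence: maximum absolute change of any fitted covariance
  entry below `tol = 1e-8`, at most `max_iter = 5000` sweeps; cliques
  are visited in lexicographic order for reproducibility, and
  non-convergence is flagged, never silent.
* Positive definiteness is declared when the smallest eigenvalue
  exceeds $p \cdot \epsilon_{mach} \cdot \lambda_{max}$.
* All determinants are log-determinants from Cholesky factors.
* Divisor conventions: the covariance-equality statistic follows the
  printed form exactly — $(n_i - 1)$-divisor sample covariances, the
  $(n_1+n_2-2)$-divisor pool, and $n_i$ weights in the statistic.  The
  mean tests are genuine likelihood-ratio tests and therefore feed the
  maximum-likelihood ($n_i$-divisor) scatters to IPS; with these inputs
  $\mathrm{tr}(\hat K_i W_i) = n_i p$, so the statistic reduces to a
  log-determinant contrast.  Data are always mean-centered per
  condition — expression data are not zero-mean, and the pooled formula
  presumes centering.
* The heterogeneous common-mean fit alternates a generalized
  least-squares mean update
  $\hat\mu = (\sum_i n_i \hat K_i)^{-1} \sum_i n_i \hat K_i \bar y_i$
  with IPS refits of the two covariances, until the mean moves by less
  than `1e-7` (at most 100 alternations).  Referring the resulting LRT
  to $\chi^2_p$ is a design choice (the reference distribution for the
  constrained Behrens–Fisher LRT is not settled); the simulation
  checks below show it holds its level at the sample sizes used.

## Triangulation

Moral graphs of real pathways are usually not chordal, so
`triangulate()` adds fill edges by greedy minimum-fill elimination with
ties broken by vertex label.  No algorithm is canonical here — any
triangulation is valid, but the clique list (hence the clique-level
p-values) depends on it, so the heuristic is deterministic and recorded
in the graph's metadata, and fill edges are logged by the pipeline.
Greedy min-fill keeps cliques small, which matters because a clique of
size $c$ needs $n_i > c$ samples for its unconstrained covariance
estimate.

## Small samples: shrinkage and permutation

When the smaller arm has at most $p$ samples the sample covariance is
singular and the IPS input is replaced by an analytic shrinkage
estimator: $(1-\lambda) S + \lambda \,\mathrm{diag}(S)$, with the
data-driven intensity
$\lambda^* = \sum_{i\neq j}\widehat{\mathrm{Var}}(s_{ij}) /
\sum_{i\neq j} s_{ij}^2$ truncated to $[0,1]$ (variances preserved,
off-diagonals shrunk; the diagonal target keeps the estimator inside
$S^+$ of the complete graph and positive definite).  The chi-squared
asymptotics do not cover shrinkage-based statistics, so the null
distribution is then estimated by permuting condition labels over the
pooled samples, with the add-one p-value
$(1 + \#\{stat_b \ge stat_{obs}\})/(1 + B)$.  The pipeline applies the
permutation reference to **both** global statistics on the shrinkage
path — the mandate is explicit for $-2\log\Lambda$, and the mean
statistic's $\chi^2_p$ reference is equally unjustified at $n < p$, so
treating it asymptotically would be inconsistent.  Each arm is shrunk
with its own intensity and the pooled input is the usual weighted
combination of the two shrunken matrices.

## Multi-gene nodes

Pathway nodes backed by several gene rows are collapsed before
analysis, by either of two documented rules, chosen per node in the
mapping file: **first_pc** (complexes) takes the leading principal
component of the members' centered expression over the pooled samples —
the sign is fixed so the first member's loading is nonnegative, an
arbitrary but reproducible convention — and **representative**
(multi-gene enzymes) keeps the member with the largest absolute
two-sample score, by default the pooled-variance t statistic; the score
function is pluggable so an external per-gene statistic can be supplied
instead.  Pathway nodes with no expression row are dropped with a
warning and the graph shrinks accordingly, rather than aborting the
analysis.

## What the simulation module emulates

`random_chordal_ggm()` builds a random chordal graph (Erdős–Rényi draw,
then min-fill triangulation) and a concentration matrix with random
partial correlations of magnitude 0.2–0.4 on the edges, made positive
definite by diagonal dominance and rescaled to unit variances.
`type1_error_study()` then draws *both* arms from this single model —
every clique-level null is true by construction — and records the
number $m$ of clique rejections per run.  The distribution of $m$
quantifies the joint type-I behaviour of the uncorrected, mutually
dependent clique tests; no multiple-testing correction is applied
across cliques by design, and $m$'s null distribution is the honest
summary of what an uncorrected report can show.

The default design uses $n_1 = 37$, $n_2 = 41$, $\mu = 0$, 1000 runs
and a 35-vertex graph with about 30 cliques (edge density 0.06 before
triangulation), the configuration of the two-condition studies this
method targets.  The covariance $\Sigma$ is synthetic: in the original
studies it was estimated from one condition of a real dataset, which is
not shipped here, so only the direction and order of magnitude of the
published summaries (mean $m$ around 1.5 at $\alpha = 0.05$ over 30
cliques, vanishing probability of more than nine rejections) are
reproducible — and are, in the acceptance checks.  Per-run seeds are
drawn once from the root seed, so the study is bit-reproducible end to
end and any single run can be replayed.

What the synthetic generator does *not* emulate: heavy-tailed or
skewed expression, batch effects, dependence between the two arms, and
model misspecification of the graph itself.  Passing calibration tests
on these fixtures therefore demonstrates correctness of the statistics
under the stated model, not robustness to violations of it; the robust
Wald variants suggested in the literature for elliptical data are out
of scope.

## Problem sizes used in the checks

The test-suite and acceptance studies run at deliberately moderate
sizes chosen to estimate each property with adequate Monte-Carlo error:
null calibration of the covariance test at $p = 6$, $n = 100$/arm, 2000
replicates; the Behrens–Fisher level check at $p = 4$, 1000 replicates;
power checks at 500 replicates; the clique-count study at its full
design (1000 runs).  Oracle comparisons (IPS vs. closed form, cliques
vs. brute force, chordality vs. induced-cycle enumeration) use graphs
of up to 10 vertices where exhaustive enumeration is feasible.

## Known limitations

* Exactly two conditions; more groups would need a different LRT
  decomposition.
* The graph is trusted as given; no goodness-of-fit test of the
  topology itself is performed.
* Asymptotic p-values are anti-conservative at small $n$ relative to
  the clique size; the per-clique exact test mitigates this only for
  the mean test under homogeneity.
* Tied vertex labels across pathway and expression files are the join
  key; no identifier mapping (e.g. probe-to-gene) is provided.

## A worked run

```{r, eval = FALSE}
pw <- system.file("extdata", "synthetic_pathway.tsv", package = "pathGGM")
ex <- system.file("extdata", "synthetic_expression.tsv", package = "pathGGM")
lb <- system.file("extdata", "synthetic_labels.tsv", package = "pathGGM")
mp <- system.file("extdata", "synthetic_mapping.tsv", package = "pathGGM")
res <- run_full_analysis(pw, ex, lb, mapping_file = mp,
                         config = analysis_config(seed = 1))
res
res$clique_report
write_report(res, "demo_out")
```

The shipped demo dataset is synthetic (see `data-raw/make_extdata.R`):
condition B flips the sign of the MAPK-related partial correlations and
shifts MAPK and TF1 upward, so the global covariance test rejects, the
mean test runs on its heterogeneous branch and rejects, and the
clique table localizes the mean signal to the MAPK/TF cliques.
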