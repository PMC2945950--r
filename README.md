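# pathGGM

Topology-aware two-sample tests for pathway expression, built on
graphical Gaussian models.

## The problem

Gene-set methods usually ask whether the genes of a pathway are, as a
group, differentially expressed — treating the pathway as a flat list.
But a pathway diagram also fixes *which genes talk to which*, and a
disease state can change the **strength of those connections** without
moving any mean, or vice versa.  pathGGM is for analysts comparing a
known signaling pathway between two conditions (e.g. mutation carriers
vs. non-carriers) who want both questions answered, and localized.

## The method

The pathway is oriented into a DAG *D* (inhibition and
(de)phosphorylation arrows become plain directed edges) and moralized
into an undirected graph *G* = *D*<sup>m</sup>.  Each condition is
modelled as a graphical Gaussian model sharing *G*:

&nbsp;&nbsp;ℳ<sub>i</sub>(G) = { Y ~ N<sub>p</sub>(μ<sub>i</sub>, Σ<sub>i</sub>), Σ<sub>i</sub><sup>−1</sup> ∈ S<sup>+</sup>(G) },&nbsp; i = 1, 2,

so missing edges are conditional independences.  Graph-constrained
covariance estimates come from iterative proportional scaling (IPS);
on decomposable graphs a junction-tree closed form serves as an
independent cross-check.  Two tests follow:

1. **Strength of relations** — H₀: K₁ = K₂ (equal concentration
   matrices), by likelihood ratio
   −2 log λ = Σᵢ nᵢ log(det K̂ᵢ / det K̂), asymptotically
   χ²<sub>p+r</sub> (p vertices, r edges).
2. **Differential expression** — H₀: μ₁ = μ₂, assuming a common
   constrained Σ if test 1 did not reject, otherwise as the
   graph-constrained Behrens–Fisher problem; both are LRTs referred to
   χ²<sub>p</sub>.

Both tests are then repeated on every maximal clique of a triangulated
*D*<sup>t</sup>, where they reduce to classical two-sample tests
(exact Hotelling T² for the mean when the clique's covariances are
homogeneous), giving a per-clique table that localizes the signal.
For n &lt; p there is a shrinkage-covariance entry point with
permutation null distributions, and a simulation module characterizes
the joint type-I behaviour of the dependent clique-level tests (the
distribution of the per-run rejection count *m*).

## Worked example

A small synthetic dataset ships with the package: a 12-node
signaling-style pathway, 30 + 35 samples, where condition B flips the
MAPK-related partial correlations and shifts MAPK/TF1 expression.

```r
library(pathGGM)
pw <- system.file("extdata", "synthetic_pathway.tsv",    package = "pathGGM")
ex <- system.file("extdata", "synthetic_expression.tsv", package = "pathGGM")
lb <- system.file("extdata", "synthetic_labels.tsv",     package = "pathGGM")
mp <- system.file("extdata", "synthetic_mapping.tsv",    package = "pathGGM")

res <- run_full_analysis(pw, ex, lb, mapping_file = mp,
                         config = analysis_config(seed = 1))
res
#> Pathway GGM analysis (A vs B, n = 30/35)
#>   p = 12 vertices, r = 17 moral edges
#>   H0 K1 = K2:      p = 0.04208 (asymptotic_chi2)
#>   H0 mu1 = mu2:    p = 0.0009827 (heterogeneous, asymptotic_chi2)
#>   cliques: 6  rejections: m_cov = 0 , m_mean = 3
```

The covariance-equality test rejects (p = 0.042): the wiring strength
differs between conditions, so the mean test runs on its heterogeneous
(Behrens–Fisher) branch and also rejects (p = 0.00098).  The clique
table then shows where:

```r
res$clique_report[, c("clique", "p_cov", "p_mean", "mean_method")]
#>          clique     p_cov       p_mean mean_method
#> 1 ADAP,GTP,KIN1 0.1676490 2.573045e-01       exact
#> 2 ADAP,RTK,SCAF 0.1401350 4.541182e-01       exact
#> 3 GTP,KIN2,MAPK 0.1583275 4.128745e-03       exact
#> 4  LIG,PHOS,RTK 0.1918260 3.897525e-01       exact
#> 5  MAPK,TF1,TF2 0.4787834 6.484667e-05       exact
#> 6   OUT,TF1,TF2 0.2274051 2.798149e-03       exact
```

The mean signal concentrates exactly in the MAPK/TF cliques (rows 3, 5,
6) while the upstream receptor cliques stay null; at these sample sizes
the per-clique covariance tests are individually underpowered even
though the global test rejects — which is the point of running both
levels.  `write_report(res, "out/")` writes the global and clique
tables, the three graphs (edge lists and GraphML), the run log and the
effective configuration; reruns are byte-identical.

A thin command-line wrapper with `convert`, `cliques`, `test` and
`simulate` subcommands is installed at
`system.file("cli", "pathggm.R", package = "pathGGM")`.

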