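---
title: "Methods: topology-based pathway impact analysis with interaction-strength weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology-based pathway impact analysis with interaction-strength weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wspia)
```

## The model

Pathway impact analysis asks whether a signalling pathway is affected
by a two-condition contrast, using two sources of evidence that an
over-representation test alone ignores: how many differentially
expressed genes (DEGs) the pathway carries, and how their fold-changes
propagate through the pathway's signed topology.

**Evidence 1 — over-representation.** Let $m$ be the number of measured
genes (the reference set is what is on the array, not a nominal
genome), $t$ of which lie on the pathway; let $h$ be the number of DEGs
among the $m$, and $r$ the number of DEGs on the pathway. Under random
DEG placement, $r$ follows a hypergeometric law and

$$P_{NDE} = P(X \ge r) = 1 - \sum_{x=0}^{r-1}
  \binom{t}{x}\binom{m-t}{h-x}\Big/\binom{m}{h}.$$

**Evidence 2 — perturbation propagation.** Each gene's perturbation
factor is its own signed log fold-change $\Delta E(g_i)$ (zero for
non-DEGs) plus what flows in from direct upstream genes:

$$PF(g_i) = \Delta E(g_i) + \sum_{j} \beta_{ij}\, w_{ij}\,
  \frac{PF(g_j)}{N_{ds}(g_j)},$$

where $\beta_{ij} \in \{+1,-1\}$ is the interaction sign,
$N_{ds}(g_j)$ the number of downstream targets of $g_j$, and $w_{ij}$
the interaction intensity: constant 1 (SPIA), the Pearson correlation
of the two genes' expression (PSPIA), or the mutual information of
their binarized expression (MSPIA). Collecting the coefficients into a
matrix $M$ with $M_{ij} = \beta_{ij} w_{ij} / N_{ds}(g_j)$ on edges,
the fixed point is the solution of $(I - M)\,PF = \Delta E$, obtained
by a direct dense solve. The pathway statistic is the total *accumulated*
perturbation $t_A = \sum_i \left(PF(g_i) - \Delta E(g_i)\right)$ — the
part owed to topology, not to the genes' own changes.

$P_{PERT}$ is a bootstrap tail probability for $t_A$: each iteration
draws $r$ fold-changes without replacement from the genome-wide DEG
fold-change pool, places them on $r$ uniformly chosen measured pathway
genes, and recomputes $t_A$. Because $t_A$ is linear in $\Delta E$,
the null values are inner products with a precomputed coefficient
vector $q = \mathbf{1}^\top (I-M)^{-1} - \mathbf{1}^\top$, which makes
the bootstrap cheap even at thousands of iterations. The null is
median-centred and compared two-tailed, with add-one smoothing
$(k + 1)/(B + 1)$ so the p-value is never zero; ties count against the
pathway (conservative).

**Combination.** $P_G = c - c\ln c$ with $c = P_{NDE} \cdot P_{PERT}$.
This is the distribution function of a product of two independent
uniforms evaluated at $c$, so under the joint null $P_G$ is itself
uniform; the suite verifies this with a Kolmogorov–Smirnov check.
$P_G$ values are Benjamini–Hochberg adjusted across the analysed
pathways (Bonferroni available), with the conventional significance
threshold FDR < 0.01.

**Reduction property.** With every $w_{ij} = 1$, PSPIA and MSPIA are
definitionally SPIA. The implementation shares one code path for all
three methods, and the suite asserts bit-identical
$\{P_{NDE}, t_A, P_{PERT}, P_G\}$ under forced unit weights.

## Assumptions

* Expression values are already normalised and on a log scale; the log
  fold-change is a plain difference of group means.
* DEG calling and weight estimation are treated as independent of the
  topology; the hypergeometric null additionally assumes genes are
  called DE independently of one another (violated in the presence of
  strong co-expression — see *Limitations*).
* Pathways are gene-only networks: compound nodes and relations that
  are not clear activation/expression or inhibition/repression are
  dropped during KGML parsing (counts reported per pathway).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | raw Welch-t p-value threshold for DEG calling |
| `iterations` | 2000 | bootstrap iterations; p-value resolution 1/(B+1) |
| `fdr_threshold` | 0.01 | significance cut on BH-adjusted $P_G$ |
| `mi_log_base` | 2 | MI in bits; the base only rescales all MI weights |
| `abs_weights` | FALSE | use $|w|$ so that $\beta$ carries all sign information |
| `weight_samples` | "all" | samples entering weight estimation (both conditions pooled) |
| `seed` | 1 | top-level seed; per-pathway streams derived from it |

Where the underlying procedure leaves a choice, the defaults are:

* **DEG test.** A Welch two-sample t-test on raw p-values. Moderated-t
  shrinkage is deliberately out of scope; the DEG caller is an
  interchangeable front end and the threshold applies to raw, not
  adjusted, p-values (configurable through `alpha`).
* **Signed Pearson weights.** The propagation multiplies
  $\beta_{ij} w_{ij}$, so a negative correlation flips the effective
  edge sign. The formula is applied literally; `abs_weights = TRUE` is
  the escape hatch for users who want the curated sign to win.
* **MI scale.** Binary plug-in MI in bits, not normalised to $[0,1]$.
  Pearson and MI weights therefore live on different scales; they are
  never mixed within one run, so only the relative weighting within a
  method matters.
* **Binarization.** Per-gene median across all samples, ties mapped to
  1 ("overexpressed"); the median is the only label-free, scale-free
  threshold, and a per-gene mean variant is available.
* **Pooled weight estimation.** Correlation/MI are computed across all
  samples by default — the conventional co-expression choice that
  maximises $n$ — and can be restricted to either condition.
* **Degenerate weights.** An edge touching a zero-variance or
  unmeasured gene falls back to weight 1 (plain SPIA strength) with a
  logged count, instead of silently deleting the edge.

## Numerical choices

* **Singularity.** $(I - M)$ is tested with `rcond` against $10^{-12}$;
  a singular system (e.g. a perfectly reinforcing feedback loop with
  unit weights) marks the pathway `skipped_singular` rather than being
  regularised, so no silently altered results are reported.
* **Zero p-values.** Add-one smoothing keeps $P_{PERT} > 0$, hence
  $c > 0$ and $\ln c$ defined.
* **Bootstrap median-centring and tiny nulls.** On very small discrete
  nulls the realised median matters: with four equiprobable atoms whose
  two central values differ, the sample median oscillates between those
  atoms and the p-value does not converge. The oracle test therefore
  uses a chain whose placement null is $\{2, 1, 1, 0\}$ — central atoms
  tied, median stable — making the comparison against exhaustive
  placement enumeration well defined. Real pathways have far richer
  nulls and are unaffected.
* **Determinism.** Every pathway's bootstrap stream is seeded by the
  top-level seed plus a stable polynomial hash of the pathway id (kept
  within 32-bit range), so adding or removing a pathway never changes
  another pathway's $P_{PERT}$, and identical runs are byte-identical.

## The synthetic fixture generator

`fixture_spec()` / `make_pathways()` / `make_expression()` emulate a
small two-group microarray study: by default 10 control vs 12 test
samples, Gaussian log-scale expression (sd 0.5) around a common
intercept, random signed digraph pathways, DE genes shifted by 2 log
units, and edge-adjacent genes correlated at 0.7. Correlation is
induced by one shared latent factor per connected pathway component
(loadings $\sqrt{|\rho|}$, sign-flipped on one endpoint for negative
targets), which is always positive-semidefinite and hits the target
pairwise correlation without constructing a full covariance matrix.
Perturbing a pathway shifts its genes coherently: the sign of the shift
is propagated along the topology and flipped across inhibitory edges,
so the planted signal is exactly the kind of accumulation the
propagation statistic is designed to detect. Generation is a pure
function of the spec; re-runs are byte-identical.

What the generator does **not** emulate: probe-level and batch effects,
heavy-tailed or intensity-dependent noise, realistic pathway topology
(hubs, scale-free degree), overlapping gene sets between pathways, and
correlation that differs between conditions. Passing tests on these
fixtures therefore demonstrate correctness of the statistical machinery
and its calibration under its own assumptions — not robustness to
microarray artefacts.

## Test design notes

The suite's problem sizes are chosen so the full run completes in well
under a minute of propagation algebra: reduction checks on twenty
60-gene fixtures; exhaustive hypergeometric enumeration up to $m = 12$;
one hundred random DAGs ($\le 12$ genes) against an independent
topological forward-propagation oracle; power estimation on fifty
150-gene replicates with four pathways each.

The calibration check runs 200 pathway-replicates of a signal-free
dataset (labels permuted) with independent genes, a DEG alpha of 0.2
and 500 bootstrap iterations. The milder alpha and independent genes
are deliberate: both component p-values are discrete and superuniform
(the hypergeometric through its staircase support, the bootstrap
through add-one smoothing), so the combined $P_G$ is honestly
conservative; a regime with more DEGs smooths the staircase enough that
the empirical false-positive fraction stays within the binomial 99%
band around the nominal level, while gene–gene correlation would
instead test the (known, documented) violation of the hypergeometric
independence assumption rather than the machinery itself.

## Limitations

* Strong co-expression among pathway genes overdisperses the DEG count
  and can make $P_{NDE}$ anti-conservative; this is a property of the
  hypergeometric component shared by the whole method family.
* KGML parsing uses a fixed subtype mapping (activation/expression,
  inhibition/repression); relation types outside it, and all
  compound-mediated links, are dropped and only counted. Curated
  conversions may retain more topology.
* MI from binarized expression on small sample sizes is noisy and
  carries a positive plug-in bias; with few samples the Pearson weights
  are typically the more reliable intensity estimate.
* Pathways whose propagation system is singular are skipped, not
  regularised; their evidence is simply unavailable.
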