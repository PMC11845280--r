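---
title: "Condition-specific interactomes and differential rewiring with netrewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific interactomes and differential rewiring with netrewire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrewire)
```

## The problem

A reference protein–protein interaction network (PPIN) aggregates physical
interactions observed across many tissues and conditions; in any one sample
only a subset of those interactions can actually form, because only some
proteins — and only some isoforms of those proteins — are expressed.
`netrewire` implements a two-stage workflow:

1. **Contextualization.** The reference PPIN is translated into a reference
   domain–domain interaction network (DDIN) and pruned per sample, keeping
   only interactions whose mediating domains are present in each protein's
   *major* (most abundant) transcript.
2. **Differential rewiring.** Two groups of contextualized networks are
   compared pairwise; per-edge alteration counts are tested against a
   binomial null, corrected for multiple testing, and the significant
   alterations are attributed to a minimal set of transcriptomic changes by
   a greedy weighted set cover.

## Stage 1: domain-resolved contextualization

Each protein interaction $(u, v)$ is mapped to the set of domain-family
pairs $(f, g)$ — $f$ carried by any isoform of $u$, $g$ by any isoform of
$v$ — documented in a domain–domain interaction (DDI) library. Every
occurrence instance of an interacting family becomes a node
`protein|family|occurrence` of the reference DDIN, and each PPI records the
domain edges that *back* it. A PPI with no documented family pair receives
a single artificial edge between reserved `DUMMY` domains of its endpoints,
so that interactions of unannotated proteins remain representable; the
dummy is treated as present in every isoform of its owner. We apply this
fallback per edge (a dummy pair backs exactly the PPIs with zero documented
support) so that the condition-specific PPIN is always derivable from DDIN
trimming alone.

Per sample, each protein's major feature is selected from the expression
table:

* **transcript-preferred mode**: the annotated isoform with maximal
  abundance (ties broken lexicographically by transcript id, for
  reproducibility), kept only if its abundance exceeds the expression
  threshold;
* **gene-level mode**: the protein's gene, if its abundance (summed over
  isoforms when the table is transcript-level) exceeds the threshold,
  paired with the *canonical* isoform's domain architecture — the only
  distinguished isoform when transcript resolution is unavailable.

A domain edge survives iff both owners have a major feature and both
families occur in the chosen features' architectures; multiple occurrence
copies of one family rise and fall together. The condition-specific PPIN is
the set of PPIs explained by at least one surviving domain edge — by
construction a subset of the reference, monotone in the threshold.

Two choices here were genuinely open and are package decisions:
"expressed" means abundance *strictly greater* than the threshold (default
1, on the TPM/FPKM scale; the appropriate value is data-dependent), and
transcript-level tables can optionally be length-normalized
(`length_normalize()`: divide by transcript length, rescale to $10^6$)
before selection, converting per-kilobase measures into TPM-like values.

The practical force of transcript resolution is that an isoform switch can
delete an interaction while both proteins stay well expressed:

```{r isoform-demo}
ann <- domain_annotation(
  protein = c("PA", "PB", "PB"), gene = c("GA", "GB", "GB"),
  isoform = c("TA1", "TB1", "TB2"),
  domains = list("PF_A", "PF_B", character()),
  canonical = c(TRUE, TRUE, FALSE)
)
ppin <- ppi_network("PA", "PB")
ref <- build_reference_ddin(ppin, ann, ddi_library("PF_A", "PF_B"))
switched <- expression_table(
  "transcript", c(TA1 = 50, TB1 = 5, TB2 = 50),
  tx2gene = c(TA1 = "GA", TB1 = "GB", TB2 = "GB")
)
# PB's dominant isoform TB2 lacks PF_B: the edge is pruned ...
n_edges(contextualize_sample(ppin, ref, ann, switched,
                             context_options(mode = "transcript"))$ppin)
# ... while gene-level contextualization cannot see the switch:
n_edges(contextualize_sample(ppin, ref, ann, switched,
                             context_options(mode = "gene"))$ppin)
```

## Stage 2: rewiring statistics

For each of the $N = |A|\cdot|B|$ inter-group sample pairs $i$, the
pairwise rewiring probability $P_{\mathrm{rewired}_i}$ is the fraction of
rewired edges (vanished plus appeared) among the edges involved; the null
probability is their average,
$P_{\mathrm{rewired}} = \tfrac{1}{N}\sum_i P_{\mathrm{rewired}_i}$. The
phrase "all edges present in all samples" admits two denominators: we
default to the *per-pair union* $|A_i \cup B_j|$, which makes each term a
self-contained property of its pair and keeps it in $[0,1]$ irrespective of
the other samples; the global-union reading is available via
`denominator = "global"`.

An edge alteration $(u,v)$ observed in $|\Delta(u,v)|$ of the $N$
comparisons is tested one-tailed against the binomial null:

$$p(u,v) = 1 - \sum_{j=0}^{|\Delta(u,v)|-1} \binom{N}{j}
  P_{\mathrm{rewired}}^{\,j} (1 - P_{\mathrm{rewired}})^{N-j},$$

implemented as the binomial survival function
(`pbinom(support - 1, N, P, lower.tail = FALSE)`) rather than the literal
subtraction, which loses all precision to cancellation once the tail drops
below machine epsilon; the test suite verifies agreement with term-by-term
summation across the full grid $N \le 30$. Each altered edge is recorded
once, in its majority direction (ties toward "lost", with a warning — a tie
requires heterogeneous presence within groups); p-values are
Benjamini–Hochberg corrected and alterations with $q \le$ FDR (default
0.05, inclusive) form the differential network.

## Attribution by weighted set cover

The universe to explain is the set of (significant alteration, sample
pair) instances. For an instance of edge $(u,v)$ in pair $(a,b)$, each
endpoint contributes a candidate *reason* when its major feature changed
consistently with the alteration: expression loss (feature in $a$, none in
$b$) for a lost edge, expression gain for a gained one, or an isoform
switch (different major features, both present) for either. The exact
attribution rule is not fixed by the statistic itself; this
endpoint-consistency rule is the package's operationalization, keyed by
(protein, change kind). Instances with no candidate — e.g. an edge flip
with identical endpoints' features — are reported as uncoverable rather
than silently dropped.

Each reason $i$ gets a score $s_i = p_{w_i} \times r_{w_i}$ ($r_{w_i}$ =
covered instances, $p_{w_i}$ = distinct pairs among them) and weight
$w_i = s_{\max} - s_i$, with $s_{\max}$ computed once over the candidate
pool (weights are static across iterations, keeping the stated formula).
Minimizing total weight is solved with Chvátal's greedy heuristic:
repeatedly pick the reason minimizing weight per newly covered instance.
The *ratio* criterion matters: plain minimum weight degenerates because the
best-scoring reason always has weight exactly 0; the cost-effectiveness
form preserves the intent (prefer high-score reasons) while guaranteeing
coverage progress. Ties break deterministically (lower weight, larger new
coverage, lexicographic id). On small instances the suite checks the
classical $H_d$ approximation bound against exhaustive search.

## The synthetic benchmark generator

`generate_scenario()` emulates every input: an Erdős–Rényi reference PPIN
(default 200 proteins at edge density 0.02, a few hundred edges — large
enough for stable rewiring fractions, small enough to run hundreds of
replicates quickly), domain architectures in which a configurable fraction
of edges (default 0.8) has a dedicated library-backed family pair while the
rest fall back to dummy backing, 1–3 isoforms per protein (canonical
carries the full architecture, minors random subsets), and two groups of 3
samples with baseline abundances drawn log-normal
($\mu = \log 50$, $\sigma = 0.5$) above the expression threshold —
log-normal being the conventional abundance model; any strictly positive
law interacts identically with the threshold rule.

Planted alterations are realized as dedicated degree-1 protein pairs
appended to the network, one mechanism each: expression loss/gain switches
the driver protein off in one group; an isoform switch moves the major
isoform to one lacking the sole backing family, with both isoforms above
threshold in both groups. Planting on degree-1 endpoints is deliberate: a
mechanism planted on a hub would rewire *all* of that protein's edges, so
ground truth would no longer map one-to-one onto edges. Background noise
flips whole genes off with probability 0.02 per gene per sample —
at the feature level, not the edge level, so the null process reaching the
statistics is exactly what contextualization produces.

What the generator does **not** emulate: scale-free interactome topology,
real Pfam architectures and their shared-domain correlations, partial
isoform overlap in expression, or count-level measurement noise. Passing
tests therefore certify the algorithms under controlled conditions, not
performance on real interactomes.

## Numerical and degenerate-input conventions

* All outputs are deterministically sorted; a fixed generator seed gives
  byte-identical files.
* Two empty networks have rewiring probability 0; an empty group is an
  error.
* `P_rewired = 0` with an observed alteration gives p-value exactly 0
  (cannot occur when the same pairs define both quantities, and asserted
  nowhere silently).
* Edge weights are read and written verbatim but never enter any
  statistic.
* Duplicate expression rows sum; duplicate network rows collapse keeping
  the first weight.

## Known limitations

The binomial null treats the $N$ pairwise comparisons as independent, but
they share samples: one gene switching off in a single sample of a 3×3
design rewires its edges in all 3 comparisons involving that sample at
once (support 3 of 9). Under sample-level background noise the support
distribution is therefore heavy-tailed relative to the null, and blocks of
tied moderate p-values survive Benjamini–Hochberg: with flip rate 0.02 the
suite's null-calibration check reports significant edges in essentially
every no-signal replicate, and that check is accordingly expected to fail.
This is a property of the statistic itself under dependent noise — the
power side is excellent (planted recall 1.0 at the same noise level) — so
reported differential networks should be read as enriched for, not
guaranteed to be, group-systematic rewiring; replication across designs
with more samples per group weakens the dependence.

The suite's stochastic checks use 200-protein networks, 3×3 samples and
50 replicates per condition, sizes at which all distributional quantities
stabilize while the full suite stays fast.
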