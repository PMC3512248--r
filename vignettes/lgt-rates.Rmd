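---
title: "Counting lateral gene transfers on a dated phylogeny: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting lateral gene transfers on a dated phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtrates)
```

## What the pipeline estimates

`lgtrates` counts *stable* lateral acquisitions of metabolic genes — transfers
that founded a gene lineage still visible in extant genomes — on a reference
("genome") tree whose nodes carry ages in Ga, and divides the count by the age
span of the domain to obtain a rate in events per billion years. The estimate
is deliberately conservative in two directions: genomically linked genes are
merged into single events (one operon transfer, one event) and
duplication-ambiguous clades widen the count into a minimum/maximum interval
instead of inflating the point estimate.

## The Mk1 ancestral-state model

Gene presence is coded 0/1 per genome and evolved under the one-rate Mk
("Mk1") model: a symmetric continuous-time two-state chain with a single rate
`q` for both gain and loss, giving `P(change) = (1 - e^(-2qt))/2` on a branch
of duration `t`. Assumptions worth stating:

* **Symmetry.** Gains and losses share one rate. This is wrong in detail
  (losses of an unused gene are surely faster than horizontal gains), but the
  reconstruction is used only to *nominate* candidate gain edges, which the
  gene trees must then confirm; the symmetric model is the conventional,
  parameter-light choice and makes the likelihood invariant under rerooting
  with the flat root prior (1/2, 1/2), its stationary distribution.
* **Time-scaled branches.** Reconstruction runs on the chronogram, so `q` has
  units of events per Gy. Branch lengths in substitutions per site would
  confound molecular rate variation with trait dynamics.
* **Decision rule.** A node is called *present* when the marginal
  `P(present) >= 0.7`, *absent* when `<= 0.3`, *ambiguous* otherwise.
  Likelihood-pie figures report probabilities, not calls; 0.7 mirrors the 70%
  support convention used for the gene trees and is configurable
  (`present_threshold`, `absent_threshold`). Desktop ancestral-state tools
  use their own call rules (typically a log-likelihood-difference criterion);
  the probability threshold here is this package's declared choice, not a
  reconstruction of any of them.
* **Numerics.** Pruning with per-node rescaling; log-likelihood floored at
  -1e10 so impossible configurations (e.g. `q = 0` with discordant tips)
  propagate as very bad rather than `-Inf`. `q` is fitted on the log scale
  over [1e-8, 1000/depth] with restarts from {0.01, 0.1, 1}/depth.

A gain edge is any edge with a non-present parent and a present child. Tests
verify pruning and marginals against exhaustive enumeration over all
ancestral-state assignments on trees of up to 6 leaves (tolerance 1e-10).

## Confirmation against gene trees

Each candidate gain is checked against the gene's own phylogeny, restricted to
the taxa the reference and gene tree share:

* **Supported conflict** — some branch with support >= 70 implies a taxon
  bipartition incompatible with the induced reference subtree. Either support
  track passes the gate (parsimony bootstrap >= 70 *or* Bayesian posterior
  >= 0.70, stored x100); treating the two tracks as alternatives is the
  either/or reading of the usual "bootstrap or posterior above 70%"
  convention. Compatibility is the classic four-intersection
  test per split; because a tree's splits are jointly compatible, pairwise
  checking against each reference split is exact. An independent graph-based
  oracle (the two sides of a split must span edge-disjoint subtrees) backs
  this in the test suite over a thousand random cases.
* **Alternative rooting** — the clade's unrooted topology matches the
  reference but its basal lineage differs. No support threshold applies: the
  evidence is positional: such clades are typically only moderately
  supported internally, yet the displaced root is what matters.
  Unrooted gene trees cannot yield this verdict.
* **Taxonomic restriction** — a congruent clade confined to a subset of taxa,
  with an ancestral-state gain behind it, still evidences a transfer
  (configurable off). Clades with fewer than four shared taxa cannot be
  tested topologically at all; for them this is the only confirmation route,
  and it is how two-taxon recipients are counted.
* **Unresolved** — at least four taxa but no branch reaching the threshold:
  the gene tree can neither confirm nor contradict. Such events drop to an
  unconfirmed, ASR-only tier that is excluded from minimum counts.

Verdict precedence is supported_conflict > alternative_rooting > congruent.
Paralogous copies of one taxon are collapsed to a single occurrence for the
compatibility test; splits straddled by a paralog pair are skipped, and
duplication structure is handled by the flag mechanism instead.

## Linkage collapsing and duplication flags

Two events merge when their recipient clades are identical *and* some taxon
shows copies of the two genes adjacent in the genome with at most
`max_gap_orfs = 1` intervening ORF (copies separated by a single reading frame
are treated as one operon). Merging is transitive and order-invariant. The
identical-recipient requirement is what keeps, e.g., nitric oxide reductase
separate from the nitrate reductase cluster it is linked to in some genomes:
their recipient clades differ, so linkage alone does not merge them. The
bundled fixtures encode linked subunit pairs with identical taxon sets — a
simplification of slightly ragged real sampling, made so the declared merge
rule applies cleanly.

Duplication flags group events into families. Flagged members count only
toward the maximum; a family with no firm member still contributes one event
to the minimum (some transfer founded the family). For example, the
Sulfolobales oxidases {SoxM firm, SoxB firm, DoxB flagged, FoxA flagged}
give min 2, max 4.

Rates are `round(n / T, 1)` with `T = 3.5` Gy and round-half-away-from-zero;
half-even rounding agrees on every cell of the bundled tables, but one rule
had to be documented and this is it. Category totals are recomputed from summed counts,
never from summed rounded rates.

## Penalized-likelihood dating

When only substitution branch lengths are available, node ages are estimated
by maximizing a Poisson branch-length likelihood minus a roughness penalty:
`sum_e [x_e log(mu_e) - mu_e] - lambda * (sum (r_e - r_parent(e))^2 +
Var(root-child rates))`, with `x_e = length_e * L` and `mu_e = rate_e *
duration_e * L`. Choices:

* `L` (effective alignment length) defaults to 1000 sites; it scales
  confidence, not the location of the optimum.
* `lambda` defaults to 10 and is fixed by configuration; cross-validation is
  out of scope. With clock-like data the optimum is insensitive to `lambda`
  (the tests date strict-clock simulations within 1% at `lambda` 1 and 100),
  and very large `lambda` drives all branch rates to a common value.
* Ages are parameterized as logistic fractions of each node's feasible
  interval, placed root-down, so parent > child (margin 1e-6 Ga) and every
  propagated min/max constraint hold *by construction*; constraints are also
  re-asserted after optimization. Constraint propagation tightens each node by
  ancestral maxima and descendant minima and reports infeasible combinations
  by clade name. Dating refuses to run without a finite maximum somewhere
  above the root — there would be no absolute time scale.
* Optimization is BFGS with a Nelder–Mead polish, 5 jittered restarts, seed
  recorded (default 1).

A pre-dated tree (ages already on the nodes) bypasses this module entirely.
The bundled reference chronogram takes that route: it is an explicitly
synthetic stand-in whose ages are assumptions consistent with the constraint
table, not a dating result — the alignments behind the real age estimates are
not publicly available.

## The synthetic-data generator

`simulate_reference_tree()` draws a birth–death tree conditioned on the number
of survivors (birth 1.0, death 0.2 per lineage per Gy) and rescales the crown
to 3.5 Ga — the assumed age of the archaeal domain. `simulate_gene_history()`
implants gains as a Poisson process with expectation `gamma * root_age`
(default `gamma = 0.6` per Gy, i.e. roughly two expected transfers per gene
over the history of the domain, matching the observed one-or-a-few-per-gene
regime), each landing on an edge with probability proportional to its
duration. Losses prune carrier subtrees at `loss_rate` per lineage per Gy.
Gene trees are *constructed*, not sequence-simulated: each gain clade is the
induced reference subtree of its carriers, strung on a pectinate backbone so
each acquisition is externally rooted, supports 100 before optional
degradation (`s' = (1-noise)*s + noise*U(0,50)`).

Two stated-world restrictions matter for interpreting green tests:

* Gains of one gene land in **disjoint subtrees**: a second gain nested inside
  an already-carrying clade changes nothing observable in presence/absence
  data, so generating it would only make "exact recovery" undefined.
* A recipient clade spans at most **20% of the taxa** (`max_clade_frac`).
  Real recipients in this domain are minor clades (the largest is about a
  tenth of the sampled taxa); a trait blanketing most of the tree pushes the
  symmetric Mk1 reconstruction toward ancestral presence plus losses, which is
  a genuine identifiability limit, not a detector bug. The generator stays
  inside the regime the method is built for.

What a green round-trip establishes: on trees of 32 taxa with no losses and
perfect supports, the detector's firm count equals the implanted gain count
for every tested seed, zero implanted transfers yield zero events, and tandem
gene pairs collapse to single events. What it does not establish: performance
under gene-tree estimation error, paralog misassignment, incomplete taxon
sampling, or ancient transfers erased by subsequent loss — none of which the
generator emulates.

## Known limitations

* No AU (approximately unbiased) topology test: congruence is decided by the
  bipartition-conflict verdict alone; site likelihoods are out of scope.
* Donor identification and transfer direction are not attempted; gene losses
  are not counted.
* Polytomies in the reference are treated as soft (compatible with any
  resolution), which can only make conflict calls more conservative.
* The copper nitrite reductase fixture encodes one event (a single
  monophyletic Halobacteriales clade); an alternative reading with a second
  independent gain inside that clade is possible but not encoded, so the
  summary reports 1.
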