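---
title: "Consolidating Ripple Effects Maps: the meta-REM method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating Ripple Effects Maps: the meta-REM method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarem)
```

## The problem

Ripple Effects Mapping (REM) asks programme stakeholders to draw chains of
activities and consequences — *ripples* — along a timeline. A large
multi-site programme is typically mapped in several workshops with different
stakeholder groups, producing several overlapping hand-drawn maps. Analysing
the programme as a whole requires consolidating them: the same activity may
appear in three maps under three labels, dates are recalled loosely, and a
node whose date cannot be verified cannot be placed on a shared timeline.
`metarem` is the consolidation pipeline; this vignette explains the
procedure it implements, the decisions behind it, and what the packaged
synthetic data does and does not demonstrate.

## The procedure and its assumptions

The pipeline assumes each workshop export has been transcribed into the
two-sheet workbook template: a *node sheet* (one row per activity recorded
on the map: workshop, local id, label, site) and a *ripple-edge sheet*
(one row per arrow, grouped by ripple id). In this package the two sheets
are two CSV tables; no spreadsheet binary is parsed.

**Canonicalisation.** Labels are compared after whitespace collapsing and
case folding, with an alias map expanding abbreviations to full titles.
Alias entries apply at most once and may not chain, which makes
canonicalisation idempotent. Two records are duplicates exactly when their
canonical labels match. Fuzzy matching (normalised Levenshtein similarity
≥ 0.90 by default) is deliberately advisory only: it writes a candidate-pair
review table and never merges, because ambiguous labels are resolved by
member checking — a human judgement the software should not pre-empt. The
same goes for the event/conceptual distinction and the logic-model codes:
they are *inputs* (the coding table), one code per canonical label no matter
how many workshops mention it, never inferred.

**Temporal verification.** Ripples are forward ripples: an arrow's source
may not post-date its target. Verified dates carry month precision
(`YYYY-MM`) or year precision (`YYYY`); a year-only date is placed at the
year's January for binning but compared at year precision, so it is never
flagged against a month within its own year. Violations warn by default and
escalate to an error under `strict = TRUE` — verification is an iterative
triangulation exercise, and a hard failure on the first backwards arrow
would hide the rest of the report.

**Exclusion.** Three categories of nodes cannot enter the meta-map:
conceptual nodes, undatable events, and the *cascade* — dated events whose
ripple linkage runs through an unplaceable node. The default policy works
per ripple: remove unplaceable nodes and their incident edges, then keep a
dated node if a directed path from one of the ripple's origins (no incoming
edge within the ripple, itself dated) reaches it through dated nodes *and*
it retains at least one surviving edge. A node is included overall if it
survives in at least one ripple. The edge-retention clause prunes isolated
survivors: an origin whose only arrow led into a breaker has no placeable
ripple content left.

Two readings of "linked within a ripple to a node that could not be dated"
are defensible: losing only the nodes cut off from the ripple's origin
(reachability), or discarding the whole ripple (`strict_ripple`). The
package defaults to the reachability reading — loss should follow linkage,
not mere co-membership — and keeps `strict_ripple` as an option; its
included set is provably a subset of the default's, and the test suite
asserts that ordering on random instances.

**Merging and binning.** Surviving ripples are merged on canonical ids:
a duplicate-derived node appears once and joins the ripples of all its
provenance workshops, which is what expands ripples across workshops and
makes shared nodes visible. Every node is assigned to one time bin; bins
are contiguous and cover the included date span. Parallel edges (the same
node pair in different ripples) are kept distinct for analytics and only
collapsed — with a multiplicity label — when drawing.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `dedup` | `"exact"` | exact-after-aliasing; fuzzy is review-only |
| `policy` | `"reachability"` | loss follows linkage; `strict_ripple` optional |
| `granularity` | `"month"` | finest precision the date format carries |
| `bin_width` | `"quarter"` | a multi-year programme gives sparse months and coarse years |
| `strict` | `FALSE` | violations warn during iterative verification |
| fuzzy threshold | 0.90 | high bar: candidates are near-identical strings |

Sites are one of `bradford`, `lbth`, `both`, `unknown`; a node attributed to
`both` covers both concrete sites on its own when deciding whether a ripple
is cross-site, and `unknown` contributes nothing.

## The synthetic-workshop generator

`generate_rem_fixture()` builds inputs backwards from the quantities the
pipeline must recover, and returns them with a planted ground truth
(duplicate partition, per-label kind/date/codes, and the four exclusion
sets). Its defaults are the conditions of the packaged case-study replica:
five workshops, 440 records, 74 duplicates, 54 conceptual, 63 undatable,
a 76-node cascade, dates spanning 2019-01 to 2023-10.

The construction is direct rather than iterative. Clean ripples are random
trees over date-sorted labels (a new node attaches to the previous node, or
with probability `branching_prob` to a random earlier one), so dates never
decrease along an edge. The cascade is planted with dedicated subtrees

```
origin -> survivor
origin -> breaker -> dated chain
```

where the breaker is undatable (or conceptual when undatable labels run
out): the origin pair keeps a surviving edge, the chain behind the breaker
is lost, and the chain lengths are sized to hit the cascade target exactly.
Unused undatable and conceptual labels attach as leaves, which break
nothing. Duplicate records are extra appearances of clean-pool labels in
other workshops' ripples, attached wherever dates still run forwards (below
the latest node not after them, else as a new, earlier origin); an
attachment below an excluded chain node is itself dropped by the policy, so
the planted sets stay exact by construction. A fixture that cannot satisfy
its counts is refused with a feasibility error rather than generated
approximately.

The `actearly_replica()` profile additionally plants: themed labels for
nine named projects, research groups and posts, with ripple multiplicities
that put the two theme research groups at the top of the influence ranking;
three alias variants (e.g. `"hwf pilot"`) so the expansion path is
exercised; whitespace-noised raw labels on some duplicate mentions; and
exact logic-model marginals over the 173 included nodes — 12 inputs, 71
activities, 63 outputs, 18 outcomes, 9 impacts; 114 knowledge-and-evidence,
31 research-capacity, 12 coproduction, 9 data-infrastructure, 7
wider-system nodes. Stages are laid along the timeline in logic-model order
(inputs earliest, impacts last), which also plants the narrative feature
that outputs accumulate later in the programme. Tallies are computed over
meta-map (included) nodes: the replica plants its marginals there, and that
is the population the map itself presents.

**What the generator does not emulate.** Real workshop data contains
near-miss labels that only a human can merge, genuinely conflicting date
recollections, site attributions that disagree between workshops (the
package unions them), and cycles drawn by participants thinking in feedback
loops (the package rejects cycles within a ripple). Passing tests on
generated fixtures therefore demonstrate that the pipeline's bookkeeping,
exclusion logic and rendering are correct — not that canonicalisation
decisions on messy qualitative data are easy.

## Numerical and degenerate-input choices

* Dates are integer month indices internally; all ordering and binning is
  integer arithmetic, with no time-zone or calendar library involved.
* Cluster display labels take the alias target when one member matched an
  alias, else the longest member form (ties: lexicographically first), so
  spelled-out titles win over abbreviations.
* Canonical ids are slugs of the canonical label; rare slug collisions are
  disambiguated deterministically by suffix.
* An empty included set is a warning plus an empty map, not an error; a
  cycle within a ripple, a date on a conceptual-flagged label, an alias
  chain, or an accounting-identity violation are hard errors.
* Rendering sorts nodes by canonical id within bins and edges by endpoint,
  making DOT and JSON output byte-identical across runs.

## Problem sizes used in the checks

The packaged checks run the replica (440 records, 52 ripples) through the
full pipeline, verify the exclusion policy against an independent
igraph-based reachability oracle on 1,000 random instances of up to 30
nodes, and check the accounting identities and planted-truth recovery on
200 randomly parameterised fixtures of 18–46 records — sizes chosen to
exercise every branch (branching ripples, duplicate prepends, breaker
conceptual labels, empty workshops) while keeping the whole suite fast.

## Known limitations

* No date imputation: an undatable event is excluded, never estimated.
* No feedback loops: ripples must be acyclic at month granularity.
* No semantic entity resolution; consolidation is lexical plus aliases.
* Influence is ripple membership only — deliberately not a centrality
  measure, as the method stops short of full network analysis.
* The DOT export describes the graph; running a layout engine and producing
  images is out of scope.
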