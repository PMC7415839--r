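---
title: "Intermediate sequence search and transitive alignment generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intermediate sequence search and transitive alignment generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issalign)
```

## The model

Two proteins can be homologous without sharing detectable sequence
similarity. Intermediate sequence search (ISS) exploits transitivity: if a
query Q is confidently similar to an intermediate I, and I to a template T,
then Q and T are related even when a direct Q–T comparison finds nothing.
`issalign` implements a layered ISS in which each search round's hits
become the next round's queries, the last round always targeting the final
(structure-bearing) database, plus an alignment generator that converts a
discovered chain into a query–template alignment usable for template-based
modeling.

Two refinements control the false positives that plain ISS is known for:

1. **Sub-region re-querying.** Database sequences are frequently
   multi-domain. If a whole detected sequence is re-queried, its unrelated
   domains recruit their own relatives, which are false positives with
   respect to the query. `issalign` re-queries only the locally aligned
   hit region, widened by a small extension on each side.
2. **Path-score ranking.** Every query → … → template chain carries a score:
   the arithmetic sum of the E-values of its hits. Among multiple paths to
   one template the smallest sum wins, and final templates are ranked by
   that per-template best score, ascending. The sum is over raw E-values —
   not bit scores, not log-E — because an E-value is the natural per-edge
   "surprise" currency every backend emits; since all per-edge E-values of
   genuinely linked chains are tiny, the sum is dominated by the weakest
   edge, which is the desired behavior for ranking chain credibility.

## Alignment generation by map composition

For each edge of the best path, a Smith–Waterman alignment is computed
between the sub-sequences the search actually used: the full query for the
first edge, otherwise the previous hit's extended sub-region, against the
current hit's extended sub-region. An alignment's gap-free content is a
*residue map* — a strictly monotone partial pairing of positions in two
sequences. The query–template correspondence is the relational composition
of the per-edge maps,

$$M_{QT} = M_1 \circ M_2 \circ \cdots \circ M_E, \qquad
  M \circ N = \{(i,k) : (i,j) \in M,\ (j,k) \in N\},$$

which preserves every per-edge residue pairing by construction — the
defining property of the merge. A multiple-alignment program is *not* used
for merging (and none of its gap heuristics can change a matched pair
here); the multi-row merged view is produced by threading the per-edge
alignments on their shared sequences, which is exact and deterministic.

Transitive alignment occasionally derails — a register shift in one
intermediate hit propagates through composition — but such failures leave
a short aligned region. Therefore the direct Smith–Waterman alignment of
query and template is always computed too, and the alignment with the
larger matched-column count is selected. This gives a guarantee by
construction: the selected alignment never covers fewer residue pairs than
the direct one.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| substitution matrix | BLOSUM62 | scoring for all Smith–Waterman runs |
| gap open / extend | 11 / 1 | affine penalties; a gap of length L costs 11 + (L−1) |
| intermediate layers | 2 | search rounds before the final database (1–2 typical) |
| extension length | 5 (intermediate), 20 (final) | residues added on each side of a hit region before re-use |
| E-value cutoff | 1e-3 (intermediate), 10 (final) | per-layer hit admission |
| max hits per layer | 100 | cap on the branching factor |

The extension defaults (5 for intermediate layers, 20 for the final layer)
follow the setting reported to model best in the evaluation the method
derives from. The Smith–Waterman parameters are the de-facto protein-search
standard; the source work does not state its own, so they are configurable
defaults, not a reproduction constraint. The intermediate cutoff 1e-3 is
deliberately conservative — intermediate hits must be trustworthy because
errors compound across layers — while the final layer may stay permissive
because path scores, not raw admission, drive the ranking.

E-values come from the Karlin–Altschul form `E = K·m·n·exp(−λS)` with the
published gapped BLOSUM62/11,1 constants λ = 0.267, K = 0.041. This is a
calibration good enough for monotone, roughly scaled significance; nothing
in the method depends on its absolute accuracy.

## The synthetic test bed

Real ISS benchmarks need multi-gigabyte UniRef/SCOP databases. The
package's generator instead evolves a seeded chain Q → I1 → … → T from a
random ancestor (Robinson–Robinson residue frequencies): per step,
`round((1−identity)·L)` positions are substituted — replacements drawn with
probability ∝ background × exp(BLOSUM62/2), so synthetic homology remains
detectable by score-based search, unlike uniform mutation — and
Poisson-many indels of geometric length (mean 2) are applied, kept 3
residues from the ends to avoid degenerate local alignments. Every edit is
tracked, so the true residue map of every pair is exact and the composed
ground truth is verified to be chain-consistent on every generated family.
Multi-domain decoys concatenate an intermediate-derived domain with an
unrelated one, reproducing the structure that causes ISS false positives.

The default world is branch identity 0.55 with indel rate 0.02 over length
150: per-edge similarity that any search method finds easily, composing to
a query–template identity around 0.17–0.25 — the remote-homology regime
the method targets. What the generator does *not* emulate: rate
heterogeneity across sites, domain shuffling, compositional bias, and
repeat structure. A green directional test therefore establishes that the
transitive machinery works where edge-wise similarity is honest; it does
not certify performance on pathological real-database content.

## Evaluation metric

Detection accuracy uses truth at the SCOP superfamily level (first three
dot-fields of the sccs code equal) and the truncated ROC area

$$\mathrm{AUC}_n = \frac{1}{nT} \sum_{i=1}^{n} t_i,$$

with `t_i` the number of true positives ranked above the *i*-th false
positive and `T` the number of true homologs in the database, retrieved or
not — so missed homologs are penalized. The published description of the
normalization is ambiguous; this standard form is an explicit assumption.
When a ranking contains fewer than `n` false positives, the missing terms
use the total retrieved true-positive count (unretrieved entries are
treated as ranked after everything). Self-hits are removed before
labeling, and a query with no homolog in the database is skipped with a
warning rather than contributing an undefined score.

## Numerical and design choices

- **Coordinates** are 0-based half-open everywhere internally; the only
  1-based surface is the BLAST tabular adapter, converted on parse. Gap
  symbol is `-`.
- **Traceback determinism**: diagonal over up over left; among
  equal-scoring end cells the smallest (row, column) lexicographically;
  gap runs close as early as possible. Score 0 returns an empty alignment.
- **Gap placement between anchors** in the composed alignment: query
  insertions are emitted before template insertions. The choice is
  arbitrary and documented; matched pairs — the only content downstream
  modeling uses — are unaffected. Residues outside the first/last anchor
  are trimmed (local semantics).
- **Ties**: equal path scores rank the shorter path first, then
  lexicographic subject id; equal aligned-region lengths select the
  intermediate-derived alignment (it embeds remote-homology evidence at
  equal coverage). Both rules exist for determinism; the method's source
  is silent on them.
- **Multiple HSPs** for one sequence pair collapse to the best-E-value one
  everywhere, since a path has one edge per pair.
- **Cycle handling**: a path never revisits a sequence id; distinct paths
  may reuse intermediates freely.
- **Direct hits are always merged** into the candidate set at any depth,
  so ISS can only add to what a plain search finds — this also makes
  reachability monotone in layer count when cutoffs/caps are non-binding.
- An adaptive "extend as far as possible without crossing domain
  boundaries" rule would require domain annotations; the fixed 5/20
  extensions are implemented instead and adaptivity is deliberately not
  guessed.
- The `use_subregions = FALSE` switch in `iss_config()` exists solely for
  the whole-sequence ablation exercised by the false-positive-narrowing
  test; it is not a recommended operating mode. That comparison is made at
  a significant final-layer cutoff (1e-3): at permissive cutoffs both
  routes additionally admit the same noise-level hits, and the narrowing
  then shows in path scores rather than in hit-set membership.

## Known limitations

- The scan backend is exhaustive Smith–Waterman: right for correctness
  testing and small benchmarks, wrong for UniRef-scale databases — use the
  tabular adapter with an external fast tool there.
- Affine-gap alignments cannot reproduce structural alignments containing
  many short gaps; in that regime the direct and the transitive alignment
  both fall short, and selection by aligned-region length cannot fix what
  neither route produces.
- E-value calibration is fixed to one parameter set; scores from the
  tabular adapter are taken at face value from the external tool.
- Path enumeration is exhaustive over admitted hits; with permissive
  cutoffs and large caps the path set grows multiplicatively with depth.
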