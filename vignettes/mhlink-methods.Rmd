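---
title: "Methods: from microbe-host interaction prediction to downstream models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from microbe-host interaction prediction to downstream models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhlink)
```

## The problem

Microbial communities influence host physiology largely through molecular
contact: microbial proteins bind host proteins at the interface (the
extracellular matrix and plasma membrane for extracellular microbes), and
the perturbation propagates through intracellular signalling and
transcriptional regulation until it reaches genes whose expression defines
a phenotype. Experimentally mapping inter-kingdom protein-protein
interactions at community scale is infeasible, so `mhlink` predicts them
from sequence-level evidence and then traces their plausible downstream
routes through a host molecular network, producing concrete, testable
chains from a microbial protein to a host target gene.

The pipeline has four stages, each usable on its own:

1. **Interface prediction** — qualitative domain-domain and domain-motif
   interaction prediction with localization and steric quality control.
2. **Diffusion** — restart-based heat diffusion over a directed multilayer
   network (PPI and transcriptional-regulatory layers), forward from the
   predicted receptors and backward from the target genes, followed by
   min-heat linker selection.
3. **Chain selection** — enumeration of simple receptor-to-target paths,
   restricted to condition-exclusive initiators and to chains whose final
   step is a transcriptional regulatory interaction (TRI).
4. **Interpretation** — hypergeometric over-representation of the final
   model's proteins against term annotations.

## Interface prediction

**Domain-domain.** Two proteins are predicted to interact when they carry a
domain pair with gold-standard evidence of interaction (a DOMINE-style
table). Matching is unordered, and one prediction is emitted per
annotation-level combination, so the output is exactly the exhaustive
enumeration over (microbial annotation, host annotation, gold pair) — a
property the tests verify against an independent brute-force oracle.

**Domain-motif.** A microbial protein carrying a domain known to bind a
short linear motif (SLiM) class is predicted to bind any host protein with
a matching motif instance. Motif classes are regular expressions
(ELM-style); scanning reports every position-distinct match including
overlapping ones, because linear-motif semantics permit overlap. Two
steric conditions gate each instance:

* it must lie inside an intrinsically disordered region — SLiMs are
  generally functional only in disordered segments;
* it must not overlap a folded (globular) domain by even one residue —
  a match buried in a folded domain is sterically implausible.

The disorder requirement is parameterised by `theta`, the minimum fraction
of motif residues with disorder score at least 0.5. The default
`theta = 1` is the strict reading ("the whole motif inside a disordered
region"); because the literature states the rule qualitatively, the
threshold is exposed rather than hard-coded. Globular flags default to
`TRUE` for every domain annotation — a conservative choice; supply a
curated `globular` column to relax it. Steric QC applies only to the
domain-motif route: the domain-domain rationale does not involve motifs.

**Disorder scores.** The disorder interface is pluggable: per-residue
scores can be read from two-column files produced by any external
predictor, or computed with the built-in windowed charge/hydropathy fold
index,

$$FI(i) = 2.785\,\langle H \rangle - |\langle R \rangle| - 1.151,$$

where $\langle H \rangle$ is the mean Kyte-Doolittle hydropathy rescaled
to $[0,1]$ and $\langle R \rangle$ the mean net charge over a window
centred on residue $i$ (K, R: +1; D, E: -1; H: +0.5). Negative $FI$
indicates disorder; the reported score maps $FI$ into $[0,1]$ as
$0.5 - FI/(2 \cdot 3.936)$ so that the conventional 0.5 cutoff coincides
with $FI < 0$. The window default is 51 residues, a typical long-window
setting for separating globular tracts from disordered ones; at sequence
ends the window shrinks symmetrically (half-width $\min(h, i-1, L-i)$),
which keeps the estimate centred instead of biasing it toward one flank.
Ambiguous residues (X) contribute zero hydropathy and zero charge.

**Localization.** Before any prediction, host proteins are filtered to
compartments physically accessible to the microbes
(`allowed_localizations`, default extracellular + plasma membrane, the
extracellular-microbe setting). Proteins without localization evidence are
excluded — absence of evidence is not treated as accessibility. The same
filter can optionally be applied to microbial proteins
(`filter_microbial_localization`), relevant for intracellular contexts.

**Receptor weights.** Each host receptor is weighted by the number of
distinct microbial proteins predicted to bind it (evidence rows and
duplicate annotations do not inflate the count). These weights seed the
forward diffusion.

## Diffusion and linker selection

Shortest-path and neighbourhood methods over-select hubs purely because of
their degree. Diffusion avoids that: heat reaches a node only insofar as
the node is actually reachable from the seeds. We use restart-based
diffusion (personalized-PageRank style), the fixed point of

$$h = r\,s + (1-r)\,(P^{\top} h + d\,s),$$

with restart probability $r$ (default 0.15), seed distribution $s$
(weights normalised to sum 1), row-stochastic transition matrix $P$
spreading each node's heat uniformly over its distinct out-neighbours, and
dangling mass $d$ returned to the seeds so total heat is conserved (the
tests assert $\sum h = 1 \pm 10^{-6}$ on every graph). This kernel was
chosen because it is parameter-light, standard for directed networks, and
closed-form checkable: on the two-node chain $A \to B$ seeded at $A$,
$h(A) = r/(1-(1-r)^2)$, which the tests match to $10^{-8}$. Reverse
diffusion is defined as forward diffusion on the edge-reversed network —
an exact identity, also asserted. Iteration stops when the L1 change drops
below `tol` ($10^{-9}$); non-convergence within `max_iter` (10000) is an
error, not a silent truncation. Edge signs annotate the model but do not
modulate transition probabilities, and target direction signs ride along
as metadata: no signed kernel is defined here, and sign-consistency
scoring of paths is explicitly out of scope.

A **linker** is a node with heat from both sides:
$L(v) = \min(h_{\text{fwd}}(v), h_{\text{rev}}(v))$. The subnetwork keeps
all sources, all targets, and the top
$k = \lceil \alpha\,(|S|+|T|) \rceil$ linker candidates by $L$ (ties
broken lexicographically for determinism), never selecting a zero-score
node even when the budget is unfilled. The budget rule is deliberately
simple and monotone in $\alpha$ (`size_factor`, default 1). The star-graph
test makes the degree-bias claim concrete: a maximal-degree hub that lies
on no source-to-target route has $L = 0$ and is never selected.

## Chains and condition filters

Within the selected subnetwork, all simple directed receptor-to-target
paths with at most `max_chain_length` edges are enumerated by depth-first
search (default 4 edges: receptor, intermediates, transcription factor,
target). When an edge exists in both layers, one chain per layer
assignment is produced, since the terminal layer decides the chain's fate.
Enumeration is tested for exhaustiveness and non-duplication against an
independent all-simple-paths oracle.

Two filters then operate on chains (the chain, not the node, is the
filtering unit; node-level views are derived as the union of surviving
chains):

* **Condition exclusivity.** A chain survives only if at least one of its
  initiating microbial proteins was detected in exactly one study
  condition; initiators detected in both conditions are removed, and a
  chain whose remaining initiators span both single conditions is split
  into per-condition copies. A second pass separates the per-condition
  models: an intermediate node that occurs in chains of both conditions
  drops every chain where it sits at a non-penultimate position. The
  penultimate exemption formalizes "retained when directly regulating a
  target": the closest operational reading of a node-level retention rule
  inside chain-level semantics. Receptors and targets are exempt from the
  sharing rule (targets are shared by design; receptors are handled by the
  initiator rule). The composite filter is idempotent, and commutes with
  the TRI-last filter on sharing-free chain sets.
* **Terminal TRI.** Only chains whose last edge is a transcriptional
  regulatory interaction are kept, confining the step immediately upstream
  of each target gene to regulators that can change its expression.

## Enrichment

The final model's proteins are screened against term annotations with the
one-sided hypergeometric test (Fisher exact, greater — the field default
for over-representation). The background is the set of nodes of the input
multilayer network, not a whole proteome: membership in the network is the
condition under which a protein could have entered the model at all, so a
proteome-wide background would overstate significance. Terms are
intersected with the background before counting; terms with zero study
hits are not tested, and Benjamini-Hochberg correction runs across the
tested terms. The default significance threshold is `q_max = 0.05`. A
Monte-Carlo null simulation (2000 random study sets) checks that the
family-wise rate of any significant term stays at or below the nominal
level. Annotations must arrive pre-propagated; no ontology DAG handling
is performed.

## The synthetic fixture: what it proves, and what it does not

`generate_fixture()` builds a complete input set with planted ground truth
whose recovery is a theorem about the construction, not a probabilistic
hope:

* background sequence is drawn from ten residues that appear in no motif
  pattern and no disorder tract, so each literal motif pattern (a word
  over W/C/M/F) matches exactly at its planted or decoy site and nowhere
  else;
* planted motifs sit at the centre of a poly-charged (K/E/D/R) run
  extending one full disorder window on each side. Within such a run the
  rescaled mean hydropathy is at most about 0.17 and the offset term
  dominates, so $FI < 0$ — every planted motif residue is guaranteed to
  score disordered and the instance passes QC at `theta = 1`;
* decoys are matches of the same patterns placed strictly inside
  globular-flagged domains, so they are guaranteed to fail QC;
* planted signalling paths run receptor to target with a terminal TRI
  edge, and distractor edges are confined to a node partition that is
  never target-co-reachable, so planted intermediates are the only nodes
  with positive min-heat and are all selected at `size_factor = 1` (the
  spec-level budget check at construction time rejects parameter
  combinations where the budget could not cover the intermediates);
* microbes initiating planted paths carry a single alternating condition
  label, so the planted chains survive the condition filter.

Each generated directory is re-read through the package's own parsers and
the planted claims re-derived before the generator returns
(self-validation). The generator is deterministic: one seed, byte-identical
files. Default sizes are 12 microbial and 20 host proteins, 5 planted
domain-motif and 3 domain-domain interactions, 5 decoys, 3 planted paths
of 3 edges, 5 targets, and a 12-node distractor subgraph — small enough
that test runs over 20 seeds finish in seconds, and large enough that
every stage sees non-trivial input, alongside negatives (cytoplasmic
hosts, unused gold pairs, an unmatched motif class).

What passing on fixtures does **not** show: the fixture mimics neither
real metaproteome composition, nor real ELM pattern statistics (real
patterns produce many matches in ordinary sequence, making the disorder
filter's precision data-dependent), nor real network topology
(scale-free degree distributions, dense cross-talk). Results on fixtures
certify the algorithmic contracts — recovery, rejection, determinism —
not expected performance on biological data.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere, validated by one shared
  checker.
* FASTA ambiguity codes U/B/Z/J collapse to X rather than erroring;
  metaproteomic translations contain them routinely.
* Sign conflicts in edge curation (+1 and -1 for the same typed edge) are
  hard errors: contradictory curation must surface, not vanish.
* Empty intermediates terminate the pipeline cleanly
  (`status = "empty_result"`, its own CLI exit code) — an analysis run
  with zero receptors is an answer, not a crash.
* Linker ties and all output orderings are broken lexicographically, so
  reruns are byte-identical; the run manifest records parameters, input
  MD5 hashes and per-stage counts (each filter stage non-increasing).
* Zero-width regex matches advance the scan without being reported.

## Known limitations

* The built-in disorder score is a windowed charge/hydropathy index; it
  does not model pairwise interaction energies as dedicated disorder
  predictors do. For production analyses, precomputed scores from a
  dedicated predictor can be plugged in via score files.
* Predictions are qualitative; no interaction probability or affinity is
  estimated, and no motif-conservation filtering is applied.
* Identifier namespaces are treated as opaque tokens; inputs must arrive
  pre-mapped to a single namespace.
* The diffusion kernel ignores edge signs; activating/inhibiting
  consistency along chains is not scored.
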