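---
title: "Structural annotation of Pack-TYPE transposons: models, parameters and design"
author: "packScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of Pack-TYPE transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pack-TYPE elements are non-autonomous DNA (Class II) transposons whose
internal sequence is mostly captured host coding DNA. Their only reliable
diagnostic features are structural: a pair of inward-facing terminal
inverted repeats (TIRs) recognisable by a short superfamily-specific core
sequence, and a target-site duplication (TSD) — a short direct repeat of
host sequence created on integration, whose length or motif is
characteristic of the superfamily (about 9 nt for MULE, 8 nt for hAT,
5 nt for CACTA, `TA` for Mariner, `TTA`/`TAA` for Harbinger-PIF). packScan
turns these two features, plus the expectation that genuine elements are
repeated in the genome, into an annotation pipeline with three stages:
detection, family clustering, and functional classification.

## Stage 1: approximate TIR search and TSD verification

**Matching model.** A TIR seed is matched by *semi-global* alignment: the
seed must be consumed in full, both ends are free on the genome, and
substitutions and indels each cost 1 (Levenshtein distance). A dynamic
programming scan computes, for every genome position, the minimum edit
distance of an alignment ending there (O(genome × seed) time, in C++);
every window within the budget is then reported. Wildcard bases (N)
mismatch everything, including other Ns — a conservative rule that
prevents assembly gaps from faking TIR or TSD agreement; the N-content
filter downstream removes the pathological cases this rule would
otherwise let through.

**Boundary ambiguity is resolved by the TSD, not by the matcher.** A TIR
copy that diverged from the seed by an indel admits several alignments at
equal or near-equal cost whose genomic spans differ by a base or two.
Early versions of the matcher collapsed these to a single "best" span per
locus; any such rule (leftmost, shortest, longest, lowest-distance-only)
provably commits to the wrong boundary for some divergence patterns —
for example, an insertion inside a terminal homopolymer run is
indistinguishable from a terminal insertion — and because the TSD windows
are flush with the element boundary, a one-base error there turns a valid
TSD pair into a mismatch and silently drops a genuine element. packScan
therefore keeps *every* window within the budget and lets the TSD check
arbitrate: only the span whose flanks actually agree survives, and the
final per-locus deduplication (widest candidate wins, then leftmost, then
query order) reduces the survivors to one element. This also gives the
matcher a clean contract — its output equals a brute-force enumeration of
all qualifying windows — which is how it is tested.

**TSD verification.** The flanks compared are exactly the `tsd_length`
bases immediately 5′ and 3′ of the candidate, and the criterion is the
Levenshtein distance between the two flanks. The windows do not slide:
a real TSD is flush with the element by its formation mechanism, and a
sliding window would multiply chance agreements. Candidates flush with a
contig edge have no flank and are rejected — the TSD filter is mandatory.
For motif superfamilies (e.g. Mariner's `TA`), whether the 5′ flank
equals the motif is recorded for composition summaries, but filtering
remains flank-vs-flank: the motif is an observation about these families,
not part of the detection criterion.

**Key parameters** (defaults are the conventional values for this kind of
analysis): TIR mismatch budget per superfamily (0–10 edits; small budgets
keep the chance-match rate negligible for 8–15 nt seeds); TSD mismatch
budget (0–2 edits; two are generally sufficient for well-preserved
elements); width window 300–15 000 bp (300–5 000 bp is advisable for very
common short seeds).

## Stage 2: clustering into families

Elements with more than 10 % N are removed (strictly greater: exactly
10 % is kept). The remainder are clustered by a greedy centroid pass in
decreasing width order: each element joins the first centroid with which
its pairwise global identity reaches 0.60 on either strand, else founds a
new centroid. Identity is matching columns over alignment columns under
match +1 / mismatch −1 with affine gaps (opening 10, extension 4); the
deliberately expensive gaps keep the identity of unrelated sequences near
0.45–0.50, safely below the 0.60 threshold, whereas liberal gapping would
push random identity above it. Width-descending processing makes the
result independent of input order. Singleton clusters are removed —
genuine transposons are repeated in a genome, and a one-off match is more
plausibly a chance TIR/TSD configuration. Because the orientation of a
non-autonomous element is not defined by its own sequence, the largest
member of each cluster is declared forward and the others take the strand
on which they align better to it (ties stay forward).

## Stage 3: classification and identifiers

Classification consumes nucleotide similarity hits in the standard
12-column tabular form, from either backend or from a user-supplied file:

* `autonomous`: any transposase hit with E < 1e−5 and alignment length
  > 250 bp (length always means alignment length);
* `pack`: otherwise, any coding-sequence hit with E < 1e−5 and alignment
  length > 50 bp (> 250 bp recommended for searches seeded with very
  common 10 bp TIRs, where short chance gene fragments are more likely);
* `non_pack`: everything else — with the caveat that old Pack elements
  whose captured DNA has diverged beyond detectability will land here.

Precedence is strictly autonomous → pack → non_pack, so classification is
monotone: extra hits can only promote an element. The internal backend is
a local aligner (match +1, mismatch −1, gap −2 per base) reporting the
best alignment per query/subject pair on either query strand. Its
E-values follow Karlin–Altschul, `E = K·m·n·exp(−λS)`, with λ = 0.78 and
K = 0.031 obtained by fitting a Gumbel distribution to local-alignment
scores of i.i.d. random nucleotide pairs under this exact gapped scoring;
the ungapped closed form (λ = ln 3) overstates significance once cheap
gaps are allowed and was observed to let chance alignments pass the
1e−5 cutoff. The external backend shells out to `blastn`
(`-max_target_seqs 500 -task blastn-short -word_size 7`); both backends
feed classification identically, and tests assert they agree on
categories for unambiguous inputs. Identifiers are
`<genome>-<superfamily>-<n>` with `n` assigned in sorted genomic order
within each superfamily — a deterministic realisation of
"order of discovery".

## Benchmarking: reversed-TIR decoys and ROC

Outward-facing TIR pairs are unlikely to delimit a real element, so
repeating the first pipeline stage with the forward and reverse seeds
swapped estimates the chance-match rate. Sensitivity is
`identified / total known`; the false-positive rate is
`reversed / correct`. The raw ratio is kept in tables (it can exceed 1);
ROC integration clamps it to [0, 1], sorts points by FPR, anchors the
curve at (0,0) and (1,1), and integrates by trapezoid. "Identified" needs
an overlap criterion, which published benchmarks rarely state; packScan
uses reciprocal overlap ≥ 0.5 with greedy one-to-one matching, exposed as
a parameter.

## Family-level statistics

* **Local hopping.** Class II elements preferentially reinsert near their
  donor locus. For each cluster, the proportion of members within 100 kb
  of another member is compared with the proportion of non-members within
  100 kb of a member, by a one-sided chi-squared test on the 2×2 counts.
  No continuity correction is applied — the genome-wide counts this test
  is meant for are large, and the one-sided conversion (half the
  two-sided p when the effect is in the hypothesised direction, else one
  minus half) is exact without it. Superfamily-level aggregation pools
  the 2×2 counts across that superfamily's clusters before testing;
  degenerate margins return p = 1 with a flag. Element distance is the
  gap between closest ends (0 when overlapping).
* **Orientation concordance** among local same-cluster pairs is the
  fraction inserted in the same chromosomal orientation.
* **TIR k-mer clustering.** The first 80 bp of each forward-oriented
  element (covering the forward TIR) are reduced to their set of distinct
  5-mers; the distance between two elements is the Jaccard complement,
  1 − |shared|/|union|. The alignment-free method this mirrors does not
  publish a closed formula, so the set-based Jaccard form is adopted as
  the simplest metric with the right behaviour (0 for identical prefixes,
  1 for disjoint k-mer sets); k-mers containing N are ignored. Complete
  linkage then orders the elements, and the dendrogram is cut into a
  requested number of groups (six reproduces superfamily-level structure
  in genome-scale data).
* **TSD composition** is the exact-match fraction of 5′ TSDs against a
  motif, with the full frequency table.

## The synthetic-genome simulator

Every stage above is tested against planted ground truth, so the
simulator is first-class code, not a fixture. It emulates exactly the
structures the pipeline assumes:

* i.i.d. background at a configurable GC content (default 0.42,
  plant-like). A Markov background was considered and rejected: the
  TIR-anchored search is insensitive to low-order composition structure,
  and i.i.d. keeps false-match rates analytically estimable.
* planted members: `TSD + TIR(±edits) + internal + inverted TIR(±edits) +
  TSD copy`, the internal sequence derived from a per-family consensus by
  ~2 % substitutions and sparse 1 bp indels, optionally embedding a
  captured fragment copied from a synthetic CDS or transposase reference
  set (one capture event per family, shared by members — families are
  evolutionarily linked);
* TIR divergence applies an exact number of sampled edits (substitution /
  insertion / deletion, validated to land at the requested Levenshtein
  distance) at interior seed positions, keeping the terminal base flanking
  the TSD intact. This is what "compliant" means: a planted element always
  carries a flush, verifiable TSD, so recovery at a budget at least equal
  to the planted divergence is guaranteed and asserted as recall 1.0;
* outward decoys (the same construction with TIR orientations swapped,
  valid TSDs), singleton insertions (family TIRs around a unique internal
  sequence) and N-rich elements (15 % of the internal sequence masked),
  exercising the reversed-TIR benchmark, singleton removal and the
  N filter respectively;
* placement keeps any two units 100 bp apart and units of the *same*
  family more than the width window apart. The latter is structural, not
  cosmetic: two same-family insertions closer than the width window offer
  the scanner a spurious inward TIR pair spanning both (the first
  element's 5′ TIR with the second's 3′ TIR), which for fixed-motif TSD
  families would even carry a valid TSD pair and, being widest, would
  displace both true elements at deduplication. Local-hopping mates are
  instead anchored 16–90 kb from a freely placed family member, in its
  orientation — within the 100 kb hopping window but above the width
  window.

Identical configuration and seed reproduce the genome byte for byte; the
seed is mandatory.

**What the simulator does not model:** nested insertions, sequence aging
gradients, transposition dynamics, compositional isochores, and real
genomic repeat landscapes. Passing against it therefore demonstrates the
correctness of the machinery under its stated assumptions — not
annotation completeness on a real genome, where TIR variation beyond the
budget, fragmented elements and assembly artefacts all reduce recovery.

## Study conditions used by the tests and the acceptance script

* **Default conditions** (`simulationConfig(seed)`): a 1 Mb genome with
  six families of ten members mirroring the main TIR superfamilies —
  CACTA (TSD 5 nt) and MULE (TSD 9 nt) carrying 350/400 bp transposase
  fragments (autonomous), hAT (TSD 8 nt) and Harbinger-PIF (`TTA`) with
  180/120 bp coding fragments (pack), Mariner (`TA`) and a second
  Harbinger-like family fragment-free (non-Pack, MITE-like) — plus 20
  outward decoys, 5 singletons and 5 N-rich elements. TIR divergences are
  0–2 edits with budgets matched per family, and seeds are 8–15 nt, so
  chance candidates are rare and the expected outcome is exact: 60
  elements in 6 clusters, 100 % category agreement, reversed scan ≈ 20.
* **Recovery benchmark** (`benchmarkConfig(seed)` +
  `gradeDivergenceSeries()`): three fragment-free five-member families
  with 15 nt seeds and 9 nt TSDs (the MULE convention, matching the kind
  of element recovery benchmarks are run on) in 250 kb genomes, one
  genome per divergence 0–2, swept at TIR budgets 0–2 with the TSD budget
  fixed at 2. Decoys carry two extra edits, emulating the chance outward
  configurations that only enter at permissive budgets; this makes the
  ROC rise before the FPR does (AUC ≈ 0.985). Short TSDs interact badly
  with a TSD budget of 2 — random 5-mers agree within 2 edits so often
  that wide chance candidates begin to displace real elements at
  permissive TIR budgets — which is a genuine property of the method
  worth knowing, and the reason the benchmark families use 9 nt TSDs.
* **Hopping demonstration** (in `scripts/acceptance.R`): three
  ten-member families in 8 Mb, two of them with 60 % of members anchored
  near a family mate; the pooled one-sided test rejects at p ≈ 1e−7 and
  the planted orientation concordance is recovered.
* Problem sizes were chosen so the whole suite runs in minutes on one
  CPU: matcher-oracle comparisons use 200 random 2 kb sequences at
  budgets 0–3; statistical oracles use 100 random 2×2 tables.

## Numerical and degenerate-input conventions

* All coordinates are 1-based inclusive everywhere, matching GFF3;
  element width is end − start + 1.
* IUPAC ambiguity codes other than N are masked to N on input (with a
  warning) rather than rejected; reference assemblies contain them and
  the N machinery already handles them.
* Empty inputs: an empty genome or candidate set flows through every
  stage as an empty result; empty similarity databases yield empty hit
  tables; an empty prediction set is reported as recall 0 and precision 0
  with an explicit flag; an annotation write of zero records produces a
  valid header-only GFF3.
* Ties are broken deterministically and documented at each site:
  candidate dedup (widest → leftmost → query order), cluster renumbering
  (size → first genomic occurrence), orientation (ties stay "+"),
  identifier order (contig → start).
* FPR ratios above 1 are retained raw in tables and clamped only for ROC
  integration.

## Known limitations

* The greedy centroid clustering reproduces the strategy of the standard
  centroid clustering tools but is a re-implementation; exact cluster
  counts on borderline families may differ from any particular tool at
  the margin.
* The internal aligner reports one best local alignment per
  query/subject pair (no multiple HSPs); for classification, which only
  asks whether any hit clears a threshold, this is sufficient, but its
  hit tables are not a drop-in replacement for a full search tool's.
* Classification inherits the blind spot of similarity search: captured
  fragments diverged beyond detectability classify as non-Pack.
* Genome-scale annotation of real assemblies (multi-hundred-Mb maize-size
  genomes) is outside the tested envelope of the pure-R/C++ scan,
  although the algorithmic cost is linear in genome length per query.
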