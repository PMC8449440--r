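---
title: "Methods: classifying and comparing microsatellite-associated MITEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and comparing microsatellite-associated MITEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitesat)
```

This vignette is the package's own account of the procedures it
implements: the decision rules, their parameters and defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The two element groups and the classification rule

MITEs are short non-autonomous class II transposons bounded by terminal
inverted repeats (TIRs) and normally flanked by a target site
duplication (TSD) created at integration. In genomes where the dominant
MITE families insert into (TA)n microsatellite tracts, a copy's flanks
carry the diagnostic signal:

* an element flanked by dinucleotide microsatellite runs on **both**
  sides is called **mt** (microsatellite-targeting). Integration into a
  tract splits it, so pure repeats on both sides are the expected
  footprint.
* an element with **no** flanking run on either side but a 9- or 10-bp
  duplication immediately left and right of it is called **ml**
  (Mutator-like); 9/10-bp TSDs are the *Mutator* superfamily hallmark.
* everything else is **other** — one-sided tracts, decayed flanks,
  truncated copies near contig ends.

`classify_element()` applies exactly this table. The two evidence types
are in principle not exclusive (a chance 9-mer repeat beside a tract);
mt takes precedence because the ml group is defined from elements
*without* flanking microsatellites.

Classification operates on full-length copies. A hit is full-length
(`classify_full_length()`) when its alignment to the family consensus
misses at most 10 bp at each terminus; "intact" and "full-length" are
synonyms here, and the 10-bp allowance is exposed as `max_missing`.

## Dinucleotide run detection

`find_dinucleotide_runs()` replaces a Tandem Repeats Finder screen with
a transparent primitive: maximal stretches of strictly alternating
letters of a motif class, reported in canonical phase (TA for TA/AT, GA
for GA/AG, CT for CT/TC), with

* `min_units = 8` (16 bp). At match weight 2, a 16-bp perfect
  dinucleotide alignment scores ~30, the usual minimum-score setting for
  a microsatellite screen; below 8 units the i.i.d. false-positive rate
  stops being negligible.
* `max_mismatch_per_run = 0` by default. With a budget, a run may absorb
  single-base interruptions; one imputed base can restore alternation
  only when the characters flanking the gap are equal, which the merge
  step checks.
* overlapping candidate runs of different motifs resolve to the longer
  run, ties to the leftmost.

On an i.i.d. background the expected number of ≥16-bp alternating runs
is of order $L \cdot 4 \cdot (1/4)^{16}$ per motif class — far below one
event per 100 kb, which the test suite verifies empirically. This is why
the generator uses an i.i.d. background: detector false positives are
computable and effectively zero.

A run counts as *flanking* (`profile_flanks()`) when its inner edge lies
within `max_offset = 2` bp of the element terminus. Published analyses
treat runs as "flanking" without defining adjacency; 2 bp absorbs
terminal microhomology without letting nearby but detached tracts count.
The (GA)n-at-5′ / (CT)n-at-3′ asymmetry is computed strand-aware and
reported, but deliberately not used for classification: such tracts are
best explained as post-insertion replication slippage, not targeting.

`detect_tsd()` compares the k bases immediately left of the element with
the k bases immediately right, k = 10 then 9 (longer duplication
preferred), calling at `max_mismatch = 1`. Whether published 9/10-bp TSD
calls allowed a mismatch is not stated anywhere we know of; one mismatch
tolerates a single post-insertion substitution while the binomial tail
keeps the i.i.d. false-call rate near $10^{-4}$ per element.

## Divergence and the Kimura two-parameter distance

Each copy is aligned globally to its family consensus
(`align_global()`): affine-gap Needleman–Wunsch with match +5, mismatch
−4, gap open 10, gap extend 0.5 — the familiar EMBOSS-Needle-style
defaults — computed by the Biostrings alignment engine. A gap of length
k costs `open + k * ext`; ties during traceback are resolved
deterministically by the engine. The suite pins the scores to an
independent exhaustive three-state enumeration for all short pairs.

From columns with a base in both rows (gaps and Ns excluded), p is the
proportion of transition sites (A↔G, C↔T) and q the proportion of
transversion sites, and

$$K = -\tfrac{1}{2}\ln(1 - 2p - q) - \tfrac{1}{4}\ln(1 - 2q).$$

Outside the domain ($1-2p-q \le 0$ or $1-2q \le 0$) the divergence is
saturated; `kimura_distance()` raises an error by default and caps at a
caller-supplied `K_max` only when asked, so saturation is always an
explicit decision. No CpG-adjusted correction is applied — the plain
two-parameter form is the published formula. Conservation is identical
columns over alignment length; coverage is the consensus span of the hit
over consensus length. p and q are recomputed from the element-vs-
consensus alignment rather than from any stored scan alignment, keeping
the module self-contained; copy-vs-consensus (not copy-vs-copy) is the
comparison throughout.

## Clusters

`find_clusters()` chains full-length elements whose inter-element gap
(bases strictly between consecutive copies) is at most `max_gap = 100`.
"Within 100 bp" is read inclusively; the boundary is tested to the base.
Clusters are family-agnostic, since mixed-family clusters are real.
Overlapping or nested hits never arise from the generator and, in real
annotations, indicate fragment double-counting — they break the chain
and are flagged rather than clustered. A cluster is additionally marked
duplication-suspect when consecutive members are ≥ 99 % identical *and*
the spacer sequences around them match — the signature that would
implicate tandem duplication rather than independent insertion.

## Presence/absence variation

**Element level.** The element plus 200-bp flanks is extracted from the
source genome and searched in the target (`search_homolog()`): exact
15-mer anchors, diagonal chaining, then a local alignment of the query
against each candidate window, accepting the best hit with identity
≥ 0.90 *and* query coverage ≥ 0.90. The coverage floor is what stops a
flank-only match from mimicking presence: with the element deleted, the
two flanks still co-locate but 400 matching bases out of a 640+-bp query
leave identity near 0.62. Anchors that are themselves low-complexity
(≤ 2 distinct bases — i.e. inside a microsatellite tract) are dropped,
as are anchors matching more than 100 loci; this is the same reasoning
as dust-masking a BLAST query, and without it a (TA)n-flanked query
seeds at every tract in the genome. Candidate windows are ranked by
anchor support and capped, with early exit on a near-perfect hit; the
suite checks the search against an unanchored whole-genome alignment
oracle. Synteny ("the corresponding position") is enforced through the
query's own flanks rather than a genome-wide synteny map — the flanks
carry the same information at a fraction of the cost.

**Cluster level.** The cluster locus is found through its 200-bp outer
flanks; the window between them is re-annotated by aligning each family
consensus in both orientations; and source and target member lists are
matched by a longest common subsequence in which two members are
compatible when family and orientation agree and their sequences align
at ≥ 90 % identity. The cluster is *present* only when all four
conditions hold: same member number and order, same family and
orientation per member, ≥ 90 % pairwise member identity, ≥ 90 % flank
identity. Otherwise unmatched source members are deletions, unmatched
target members insertions, and an unmatched source/target pair at the
same position is a substitution. LCS ties resolve by genomic order, so
event lists are deterministic. Note that among *identical* copies (zero
divergence) "which member was deleted" is not identifiable in principle;
the generator's cluster fixtures therefore carry enough divergence that
distinct members fall below the pairing floor.

**Read level.** `call_read_pav()` marks an element present when at least
one properly paired fragment span covers the element plus 50 bp on each
side. "Covering" is read as the pair's outer span, not its sequenced
bases: with short reads no single pair's bases can cover a 500-bp
element, so the fragment span is the only consistent reading. Mapping
quality is not filtered by default (the simulated pairs carry none); the
margin is tested off-by-one in both directions.

## Genomic context, expression, methylation

* `window_density()`: 500-kb windows advancing by 100 kb, trailing
  partial windows included; count mode bins interval midpoints, bp mode
  sums overlap. Published density correlations do not state which was
  used; count mode is the default and the tests pin both. With
  step = width, bp-mode window sums equal total interval bp.
* Gene-context categories (upstream / intron / downstream within
  strand-aware 2-kb flanks, intergenic otherwise) are **not** mutually
  exclusive — published per-category percentages can sum past 100 %,
  which only makes sense for non-exclusive counting, so an element may
  be, e.g., downstream of one gene and upstream of the next. Exon
  overlap, absent from the published category set, is kept as a separate
  flag outside the four categories.
* Gene groups: U-MT / D-MT / U-ML / D-ML per flank and class, AWAY when
  no classified element touches flanks or body; every gene is AWAY or
  carries at least one label.
* Expression: RPKM = count × 10⁹ / (length × total mapped), with
  multi-mapped reads counted reciprocally — 1/n to each of n loci.
  "Reciprocal" could also mean a full count at each locus; 1/n conserves
  read totals and is the default, with the raw assignments left
  available for the alternative.
* Methylation: per-site level is C/(C+T); sites with fewer than 4 or
  more than 1000 supporting reads are removed; element level is the mean
  over kept sites, reported per context (CpG, CHG, CHH separately).
* Group comparisons use Welch's unequal-variance t with Satterthwaite
  degrees of freedom — group sizes and variances here are always
  unequal, making the Welch form the conservative reading of a plain
  "t-test".

## The synthetic-data generator

`build_genome()` emulates exactly the structures the rules above key on:

* i.i.d. background at configurable GC (default 0.4, a typical plant
  genome-wide value), so detector false positives are computable;
* two families (defaults 540 bp and 240 bp, inside the 510–570 and
  210–270 bp ranges of the families that motivated the design) with
  perfect TIRs and the first 55 bp of TIR shared between families;
* mt copies planted at the midpoint of a (TA)n tract of 2 × unit_count
  (8–20 units per side by default), ml copies with an exact random
  9/10-bp TSD, "other" copies with neither — and with insertion points
  screened so background joins cannot mimic a TSD, keeping the planted
  class recoverable by construction;
* adjacent clusters: a configurable fraction of mt copies laid down in
  runs (pairs by default) whose inter-element tracts are 16–100 bp. The
  lower bound is 16 bp rather than 2 bp because the flanking-run
  detector at 8 units needs a 16-bp tract: below that, the planted "mt"
  class would be unrecoverable by the package's own rules;
* copy divergence applied to element bodies only, at exact
  `round(p*L)` transition and `round(q*L)` transversion counts, no
  indels — so observed (p, q) equal the grid point within 1/L;
* no nested insertions (real clusters are non-nested);
* a derived genome with recorded deletions (element bases excised,
  flanks healed), substitutions (a different family's copy at the same
  locus) and insertions, for PAV truth;
* read pairs as mapped fragment spans, not sequences — mapping is out of
  scope and the read-level rule only consumes spans;
* optional placement biases (`ml_near_genes`, `mt_far_from_genes`) to
  emulate differential gene proximity of the two classes.

Every random draw runs under a seed recorded in the configuration;
rebuilding with the same configuration is bit-identical.

**What passing tests do and do not show.** The generator's background is
i.i.d. and its tracts are pure; real genomes have decayed tracts,
segmental duplications, and fragmented annotations. Perfect recovery on
synthetic genomes demonstrates that the rules are implemented exactly
and are mutually consistent; it does not calibrate their behaviour on
degraded real-genome signals, where the exposed thresholds
(`min_units`, `max_offset`, TSD mismatch, identity floors) are the
user's levers.

## Problem sizes and numerical choices

The shipped tests run classification on a 2-Mb genome with 500 planted
elements, clustering against a brute-force chaining oracle on 100 random
layouts of up to 200 elements, alignment against exhaustive enumeration
on 100 short pairs, and PAV on 250-kb genome pairs — sizes chosen so the
whole suite completes in a couple of minutes while every rule is
exercised at its boundary (gap = 100 vs 101, 10 vs 11 bp missing,
margin ± 1 bp, K at the domain edge). Alignment-based (p, q) estimates
may differ from the planted values by up to 2/L when mutations cluster
(the optimal alignment can trade a mismatch pair for a short gap);
site-by-site recovery is exact to 1/L by construction.

## Known limitations

* Each annotation row is one hit: fragment re-joining by scan ID is not
  implemented, so heavily fragmented annotations overcount.
* Tri- and tetranucleotide repeats are out of scope for flank
  classification.
* Cluster PAV re-annotation assumes family consensus sequences represent
  the members reasonably (identity ≥ 0.7 to some consensus); wholly
  novel elements inside a target cluster window would be reported as
  insertions of their nearest family or missed.
* The read-level rule is presence-only: it cannot call an element absent
  in an accession with confidence, only fail to find a spanning pair.
* Group labels for accessions are user input; no population structure is
  inferred.
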