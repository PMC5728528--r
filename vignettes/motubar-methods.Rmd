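---
title: "motubar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{motubar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motubar)
```

## The problem

Ecologists reconstructing host–parasitoid food webs need to identify, from a
single mixed tissue sample, both the lepidopteran/sawfly host and the
parasitoid(s) that developed in it. COI metabarcoding can do this in one
sequencing run, but the standard ~658-nt barcode is longer than a 2×300 bp
MiSeq fragment, so the two mates of a read pair never overlap and cannot be
merged. `motubar` implements a complete desk-scale pipeline for this
setting — demultiplexing, quality truncation, de-novo chimera screening,
97% greedy centroid clustering (MOTUs), paired-read consensus taxonomic
assignment with an LCA fallback — together with an evaluation layer (mock
community recovery, a three-method identification-success comparison, and a
BIN-versus-morphospecies reference-library audit) and a synthetic-data
module that makes every stage testable offline.

## The processing model, stage by stage

**Demultiplexing.** Samples are tagged with 7-nt MIDs on the forward read
only. A read is assigned to the unique sample whose MID is within
`max_mid_errors` (default 1) mismatches of its first 7 bases; ties at the
minimal acceptable distance are counted as ambiguous, not guessed. The
widely used fractional budget of "1.5 errors" collapses to an integer
budget of 1 for plain (non-error-correcting) 7-nt tags.

**Quality truncation.** A base is *bad* iff its phred score is ≤ 20 — we
read "maximum unacceptable score of 20" as naming the worst unacceptable
value; the alternative (bad iff Q < 20) shifts every truncation by one
quality level and is not what the source tooling does. A read is cut
immediately before the first run of more than 3 consecutive bad bases.
Pairs are dropped when either truncated mate is shorter than 100 nt; the
classifier needs both mates, so filtering is pairwise.

**Sequence identity.** One definition is used everywhere: semi-global
dynamic-programming alignment (terminal gaps free on either sequence),
scoring +1/−1/−2 per match/mismatch/gap position, identity = matches /
aligned columns with internal gap columns counting as mismatches and
terminal gaps excluded. Score ties are resolved by a fixed additive rule —
fewest aligned columns, then most matches — so the identity of a pair of
sequences is a single well-defined number, independent of traceback
order. IUPAC ambiguity codes match any compatible base.

Two consequences of the free-terminal-gap convention matter in practice:

* *Coverage guard.* Unrelated sequences routinely reach "identity 100%"
  over a chance-matching overlap of a handful of columns, because the
  score-optimal alignment simply trims everything else away. Any
  percentage threshold is therefore paired with a minimum-overlap
  requirement of `min(100 nt, sequence length)` — the same 100-nt floor the
  evaluation layer uses to emulate a blast e-value cutoff — in clustering
  membership, classifier hit definitions and Sanger best-hit search.
* *Register profiles for chimeras.* For a chimera whose minor-parent
  segment is short, the score-optimal alignment to that parent abandons the
  shared coordinate system entirely and the splice becomes invisible. All
  forward reads start at the amplicon 5' end and indel errors are out of
  scope, so chimera match profiles are computed position-wise in amplicon
  register instead of from the DP alignment.

**Chimera screening.** Dereplicated uniques are scanned in abundance order.
Candidate parents must be at least `skew` = 2× as abundant as the query;
each of 4 query chunks nominates up to 4 parents by shared 8-mers, with
near-duplicate parents (≥ 97% in-register identity to one already
nominated) collapsed so that truncated or conspecific variants of the
dominant host cannot crowd a genuine minor parent out of the slots. For
every ordered parent pair the breakpoint maximizing the spliced-model
identity is found from the two match profiles (prefix sums make the scan
linear); ties resolve to the plateau midpoint. A query is chimeric iff the
best model reaches ≥ 99% identity, beats the best single parent by ≥ 1
point, and keeps both segments ≥ 30 nt. Chimeras whose minor segment falls
below 30 nt (often because truncation shortened the read) are *below the
detection floor by design*; they surface later as mate conflicts (below).

**Clustering.** Abundance-ordered greedy centroid clustering at 97%
identity. Assignment is best-hit, not first-hit: each unique joins the
centroid of highest identity ≥ 97% (ties to the earliest-created centroid),
which makes results independent of candidate enumeration order. Clustering
operates on forward reads; reverse mates ride along by read id, and a
cluster's reverse representative is the mate of the first read carrying the
centroid sequence. Per-sample counts of 1 are then zeroed ("singletons"),
and clusters whose total drops to zero are discarded; an alternative
whole-cluster reading (`mode = "total"`) is available behind a flag since
the two readings cannot be distinguished from published totals.

**Paired-read consensus classification.** Both mates are queried
independently (the reverse mate is reverse-complemented on entry); a
reference *matches* a mate at ≥ 80% identity over the guarded overlap — the
80% floor is our choice of where a reference stops counting as a hit at
all, deep enough to keep family-level relatives, and is a prominent knob.
Only references matching both mates are candidates; forward and reverse
identities are averaged, candidates within 0.5 points of the best average
are retained (the window is absolute, applied to the average), and the
assignment is made at the deepest rank where at least 50% of retained hits
share the full lineage prefix down to that rank. Prefix-wise agreement
means homonymous genus names in different families cannot pool. If two
names at a rank hit the fraction exactly, that rank fails and the walk
continues upward — determinism without inventing precision the rule does
not have. Hits are counted per reference record, not per unique taxon,
matching the cited classifier's behaviour.

Two fallbacks exist. If exactly one mate has hits, classification repeats
with that mate alone (`single_read`, labelled in output). If *both* mates
have hits but no reference matches both, the mates point at different
taxa — precisely the signature of a chimera that survived screening — and
the cluster is left unassigned rather than assigned from one mate. Clusters
unassigned against the COI library are retried against a secondary
(bacterial/contaminant) reference set with a wider 10-point window, and
assigned the longest common lineage prefix of the retained hits (LCA).
Categories are then rule-based: Bacteria → putative symbiont; Insecta in
the host orders (Lepidoptera by default) → host; Insecta in Hymenoptera or
Diptera → parasitoid; other cellular life → contaminant.

**Standard-barcoding identification.** A full-length Sanger query is
identified as the best hit's species when its divergence is ≤ 3%; beyond
that, the deepest rank shared by all hits within a 5-point identity band is
returned, capped below species — a single hit inside the band must not
smuggle a species call past the divergence ceiling.

## The evaluation layer

* `match_recovery()` scores a mock community: a specimen is recovered iff
  some MOTU representative aligns to its Sanger barcode at ≥ 97% identity
  over ≥ 100 columns; a taxon (BIN) is recovered iff any of its specimens
  is. The e-value threshold of a blast search is emulated by the overlap
  floor: at ≥ 97% identity over ≥ 100 nt the e-value condition holds for
  any realistic database size, so overlap is the binding constraint.
* `equal_proportions_test()` is the textbook k-sample chi-square test of
  equal proportions *without* continuity correction — the choice is forced,
  since the published statistics for the packaged success matrix are
  reproduced only without it. One of the three tests is an exact half-tie
  (χ² = 5.115 prints as 5.12 under half-up rounding).
* `library_completeness()` aggregates the per-group audit table. Published
  per-group percentages are themselves rounded, so the aggregate first
  reconstructs the integer count of species-assigned BINs per group
  (`round_half_up(n_bins × pct / 100)`) and only then forms the weighted
  percentage; the naive weighted mean of rounded percentages is off by 0.1
  on one sum row. Both fixture tables ship as plain TSV; the per-individual
  success counts are reconstructed from printed percentages (flagged as
  such in the fixture), since the underlying per-individual table is not
  machine-readable.

## The synthetic world

The generator states one benchmark world and sticks to it:

* 5 mock samples, 22 insect specimens in 14 taxa (4 host taxa — hosts recur
  across samples — and 10 parasitoid taxa, 17 parasitoid specimens).
* One host per sample holding 0.8 of the sample's reads (the observed share
  in the motivating experiment was 82.7%), parasitoids splitting the
  remainder evenly; a bacterial "symbiont" fraction of 0.05 (observed
  aggregate 5.39%; a convenience choice, as no per-sample abundance model
  is published) and a contaminant fraction of 0.02.
* A 658-nt amplicon; 2×300 nt reads (MID included in the forward read), so
  mates never overlap; linear quality decay from Q38 to Q20 with ±3 jitter,
  which reproduces trailing-quality truncation behaviour without modelling
  instrument chemistry.
* Reference libraries built by hierarchical mutation of family ancestors at
  *disjoint* site sets: congeneric species ~8% apart (within the 5–12%
  stratum), genera ≥ 18% apart, families unrelated; conspecific specimen
  barcodes < 1% from their reference. Disjointness makes the strata exact
  rather than probabilistic.
* Substitution errors at 0.001/base; 2% two-parent intra-sample chimeras
  with a uniform breakpoint inside the forward-read window, so the splice
  is observable by a screen that operates on forward uniques. The reverse
  mate of such a read is then pure minor-parent sequence — which is what
  makes the mate-conflict rule effective against screen escapes.

What the generator does **not** emulate: indel sequencing errors,
quality-correlated error rates, PCR-cycle amplification bias,
primer-mismatch dropout (the motivating study lost one host taxon to primer
mismatch; we do not model it), cross-sample contamination, and reference
databases with wrong labels. A green end-to-end test therefore establishes
that the pipeline logic is sound under substitution noise and abundance
skew — not that it is robust to every artefact of a real sequencing run.

## Numerical choices and degenerate inputs

* Identity tie-break (score, then fewest columns, then most matches) is
  shared verbatim by the C++ kernel and the independent pure-R oracle used
  in tests, so oracle equivalence is exact, not approximate.
* Alignments with zero aligned columns report identity 0.
* A pooled proportion of 0 or 1 yields χ² = 0 and p = 1 (no variation).
* Empty lineages serialize as empty strings; internal lineage gaps are
  rejected at parse time with positional diagnostics.
* Phred+64-looking FASTQ input (quality bytes ≥ 64 with a maximum beyond
  'K') is rejected outright rather than silently mis-decoded.
* All generator functions take explicit seeds and restore RNG state
  (`withr::with_seed`); identical seeds give byte-identical output files.

## Known limitations

* The chimera model is openly simplified: two parents, one breakpoint, no
  published weighting formula; detection degrades when the minor segment
  approaches `min_segment`, and such escapes are only neutralized (left
  unassigned via mate conflict), not recovered.
* Whether the original workflow computed identity over gapped or ungapped
  columns is unrecoverable from the publication; our convention (internal
  gaps as mismatches) follows the dominant clustering-tool family, and MOTU
  counts at desk scale are insensitive to it for substitution-only data.
* Whether forward and reverse files were clustered independently and
  reconciled, or one mate clustered with the other riding along, is also
  unstated; we cluster forward reads only, because linking mates by read id
  is the only lossless reconstruction for downstream paired classification.
* Reported sequencing-scale results of the motivating experiment (69 MOTUs
  from ~40k reads against a 150,610-record reference release) are not
  desk-reproducible and are not claimed; the package's acceptance layer
  substitutes seeded synthetic properties with stated thresholds.
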