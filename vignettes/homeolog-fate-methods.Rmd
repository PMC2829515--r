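---
title: "Methods: calling homeolog loss and silencing from CAPS and cDNA-AFLP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling homeolog loss and silencing from CAPS and cDNA-AFLP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoCAPS)
```

## The biological question

When two diploid plant species hybridize and the hybrid doubles its
genome, the resulting allopolyploid carries two complete parental gene
sets. Every gene is present as a pair of *homeologs*, one copy from
each parent. In young natural allopolyploids — such as *Tragopogon
mirus*, formed repeatedly within the last century from *T. porrifolius*
(maternal parent) and *T. dubius* (paternal parent) — these pairs start
changing almost immediately: a homeolog can be physically lost from the
genome, or retained but transcriptionally silenced. Distinguishing the
two requires observations at two tiers: genomic DNA (is the copy still
there?) and cDNA (is it transcribed?). This package implements that
two-tier classification workflow, the assay design that precedes it,
the fragment-level cDNA-AFLP screen that typically seeds such studies,
and a ground-truthed simulator used to validate all of it.

## CAPS assays and the gel model

A CAPS (cleaved amplified polymorphic sequence) assay amplifies a locus
with a single primer pair, digests the amplicon with a restriction
enzyme whose recognition-site content differs between the two parental
alleles, and reads the fragment pattern off an agarose gel. The
in-silico design step mirrors this: both parental alleles are scanned
for (possibly degenerate, IUPAC-coded) recognition sites on both
strands, fragments are the maximal uncut intervals, and the predicted
gel pattern is derived under an explicit gel model.

Coordinates are unambiguous: a cut position is the number of bases 5'
of the scissile bond, so cuts live in `[1, length - 1]` and fragments
always sum to the amplicon length. The scanner requires a concrete
(A/C/G/T) substrate; degenerate bases are allowed only on the enzyme
side. Allowing ambiguity codes in the substrate would create
"maybe-cut" patterns with no gel interpretation, so such input is
rejected with an explicit error. Each recognition window — found on
either strand — contributes a single duplex cut at
`window_start + cut_offset` in top-strand coordinates; palindromic
sites therefore deduplicate naturally, and no overhang bookkeeping is
attempted because only fragment lengths are observable on a gel.
Substrates are linear (PCR amplicons) and digestion is assumed
complete.

The gel model has two tunable parameters (`gel_config()`):

* `min_detectable_bp` (default **50 bp**): fragments below this run off
  the gel and are invisible.
* `comigration_rel_tol` (default **0.05**): two bands whose sizes
  differ by less than 5 % of the larger are indistinguishable. The
  tolerance is relative, not absolute, because agarose resolution
  scales with fragment size. Merging is greedy from the largest
  fragment down, with each cluster represented by its largest member.

Neither parameter is measurable from a publication's gel photographs;
the defaults are conservative values for the 2–4 % agarose gels typical
of CAPS work and are exposed for adjustment. All band comparisons
downstream — diagnostic-band computation, genotype matching, union
patterns — use the same co-migration comparator, so a single tolerance
governs the whole pipeline.

An enzyme is *informative* for a locus when, after filtering and
merging, each parent retains at least one band absent from the other
parent's pattern (its *diagnostic* bands). `design_assays()` evaluates
a whole panel (a bundled panel of twenty common 4–8-bp cutters is the
default) and ranks informative assays first.

## Genotype calls at the genomic tier

`call_genotype()` matches an individual's observed bands against the
assay's diagnostic bands only:

| maternal diagnostics matched | paternal diagnostics matched | call |
|---|---|---|
| ≥ 1 | ≥ 1 | `additive` |
| ≥ 1 | 0 | `loss_paternal` |
| 0 | ≥ 1 | `loss_maternal` |
| 0 | 0 | `unscorable` |

One matched diagnostic band per parent suffices. Requiring the full
band complement would let the dropout of a single shared fragment flip
a call, and shared fragments carry no parent-of-origin information in
the first place. An empty lane is `unscorable` (a failed reaction), and
a lane matching neither parent is also `unscorable` rather than a
"double loss": a tetraploid lacking both homeologs would not have
amplified at all, and no such case is biologically expected.

Two safeguards surround the raw call:

* **Within-parent polymorphism.** If a parent species is itself
  polymorphic at a locus (some parent individuals carry an extra
  amplicon class — as happens for one gene in *T. dubius*, where
  several individuals carry the other parent's amplicon type), loss
  calls in the polyploid become uninterpretable and the locus is
  excluded from loss tallies, globally. The standalone
  `detect_parental_polymorphism()` counts distinct band-pattern classes
  under the co-migration comparator. At the pipeline level, however,
  the screen is *reference-based*: a parent lane flags the locus only
  when it shows a band outside that parent's predicted digest pattern.
  The distinction matters under noise — with strict pattern-class
  counting, a single dropped band in any parent lane would create a
  second "class" and exclude the locus, so gel noise would eventually
  exclude everything; real parental polymorphism instead shows up as
  extra bands, which the reference-based screen still catches.
* **Sequencing confirmation.** A gel-inferred loss can instead be a
  restriction-site polymorphism (the site, not the homeolog, was lost).
  `confirm_loss()` resolves this the way a sequencing follow-up does: a
  true loss recovers only one parental sequence, a lost site recovers
  both. Recovered amplicons are assigned to the parent with the greater
  positional identity over the shared coordinate frame, with a default
  floor of **0.95** — appropriate for recently diverged congeners —
  and ties are left unassigned rather than guessed.

Both parental alleles of a locus are assumed to share one coordinate
frame (pre-aligned or simulator-born, equal length); no alignment
algorithm is implemented, and length-incompatible comparisons are
flagged inconclusive rather than fatal.

## Expression calls at the cDNA tier

The methodological core of the two-tier design is that a missing
transcript band is only evidence of *silencing* when the genomic tier
shows the homeolog is still present:

* genomic `additive` + one parent's cDNA diagnostics absent →
  `silenced_<parent>`;
* genomic `loss_X` + that parent's cDNA diagnostics absent →
  `absent_due_to_genomic_loss` — never silencing;
* genomic `unscorable` or `ambiguous_polymorphism` → `unscorable` at
  the cDNA tier too.

A dataset with no genomic tier therefore cannot produce silencing
calls, which enforces the central caveat of transcript-only screens
(cDNA-AFLP differences may reflect loss, polymorphism, or true
expression change — they cannot be told apart without the genomic
tier).

Silencing is deliberately binary (diagnostic band present/absent),
matching the gel-presence criterion of the underlying assays. A
separate, optional intensity readout (`expression_ratio()`) sums
measured intensities over each parent's matched diagnostic bands and
reports a paternal/maternal ratio with a dominance label. The dominance
threshold defaults to **2.0** — a conservative choice, since no
quantitative threshold is established for gel densitometry — and the
readout is scale-invariant, as only relative intensities are
meaningful. It feeds dominance statements (e.g. rDNA transcription
dominated by one parent's units) but never the silencing call itself.

## cDNA-AFLP fragment scoring

The fragment-level screen that precedes locus selection is scored from
a presence/absence matrix over individuals of the three species. A
fragment present in every individual is *monomorphic*; anything else is
*polymorphic*, subdivided into *novel* (polyploids only),
*maternal-origin* (polyploids + maternal parent only),
*paternal-origin* (symmetric), and *other* (every remaining pattern,
counted but not subdivided so that the classes always partition the
total). Shared-origin subtypes require presence in at least one
polyploid by default; a strictness switch (`polyploid_quantifier =
"all"`) is provided because the quantifier is a genuine free choice in
this scoring scheme. "Present in all individuals" is interpreted
jointly across all three species; a per-species reading exists but is
not implemented.

Display percentages use half-up rounding (`percent()`), the convention
under which published survey tables print values such as 35.0 or 18.97;
banker's rounding would not reproduce them. Raw fractions are retained
in machine output.

## Study-level tallies

`tally_gene_status()` partitions assayable genes into additive /
loss-detected / excluded. `tally_by_parent()` reports gene-level loss
counts per parent over a denominator of **2 × informative genes** (each
non-excluded gene contributes one maternal and one paternal homeolog) —
e.g. a 30-gene survey with one excluded locus yields 58 homeologs.
Excluded loci contribute nothing to any tally. Silencing is tallied at
both the gene level (genes with ≥ 1 silenced individual, over 2 × the
cDNA-assayed informative genes) and the individual level, since both
framings are in common use. Per-population breakdowns count distinct
event loci per population; a locus lost in two populations counts once
in each, and no attempt is made to distinguish independent losses from
a single transmitted loss — the data cannot tell them apart.

No statistical test of parental bias is computed: the surveys this
package models report raw proportions, and adding inference the source
data cannot support would suggest false precision.

## The synthetic-data generator

`simulate_cohort()` generates complete studies with known ground truth.
Default study conditions mirror a 30-gene, seven-population survey of a
young allotetraploid: 40 polyploid individuals, 40 paternal-parent and
20 maternal-parent diploids, 400-bp amplicons, 2 % parental divergence
(uniform per-site substitution, no indels or rate heterogeneity —
alleles stay length-matched and the coordinate frame shared). Defaults
for the event probabilities are per-individual × per-locus: paternal
homeolog loss 0.02, maternal 0.01 (paternal-biased, reflecting the
direction of bias reported for *Tragopogon* allopolyploids), silencing
of a retained homeolog 0.01, within-parent polymorphism 0.03 per locus
(about one locus in a 30-gene survey). Loss draws are independent
across individuals — a founder-transmission correlation is deliberately
not modelled, since observed data cannot distinguish transmitted from
recurrent losses — and the two parents' homeologs are never both lost:
when both draws fire, the later (maternal) draw is suppressed and the
event logged, because a tetraploid with neither homeolog would simply
fail to amplify.

Two design choices deserve emphasis:

* **Planted diagnostic sites.** With purely random 2 % divergence,
  almost no 400-bp locus would carry a parent-diagnostic restriction
  site, yet real CAPS surveys select loci *because* such sites exist.
  `ensure_informative` (default on) therefore plants one intact enzyme
  site in one parent and a single site-destroying substitution in the
  other, alternating direction across loci. This reproduces the
  marker-selection step of the study design rather than biasing the
  sequence model; tests of the substitution model itself disable it.
* **Substreamed randomness.** One root seed feeds separate
  deterministic substreams for alleles, losses, silencing, polymorphism
  and gel noise, so changing the noise setting does not perturb the
  genotype truth, and identical configuration + seed reproduces every
  file byte-for-byte.

The noise model is band dropout (each band independently, probability
`band_dropout_prob`) plus multiplicative size jitter
(`size_jitter_rel`), followed by re-merging under the gel model. No
spurious bands are generated; dropout and jitter are the simplest
mechanisms that exercise the unscorable and false-silencing paths. F1
hybrids force all event probabilities to zero, so a simulated F1 cohort
is the package's built-in additivity control.

What passing simulator-based tests does **not** show about real data:
the generator has no PCR competition or amplification bias, no partial
digestion, no methylation-sensitive enzymes, no concerted evolution of
repeated loci, and its noise is unstructured — so recovery rates on
synthetic data are an upper bound on what identical settings would
achieve on real gels.

Deterministic fixtures (`caps_fixture_from_counts()`,
`aflp_fixture_from_counts()`) complement the simulator: they construct
noise-free datasets whose classification reproduces requested tallies
exactly, which is how the package's end-to-end tests pin the pipeline
to published survey numbers (integer tallies and percentages over
stated denominators) without access to the original gels. Gene-level
per-parent loss counts may legitimately exceed the number of
loss-bearing genes, because one gene can lose either copy in different
individuals; the fixtures encode this via `both_parent_loss_genes`.

## Numerical and degenerate-input choices

* Cut positions at 0 or at full length are discarded (zero-length
  fragments are gel-invisible).
* A band set may become empty after filtering (everything ran off the
  gel); callers treat such lanes as unscorable rather than erroring.
* Loci with no informative enzyme are carried, flagged, and excluded
  from calls and tallies; they emit no simulated observations because
  there is no scorable assay to observe them with. The gene-status
  partition invariant applies to assayable genes.
* Noise-free expression validation at a 30-loci × 40-individuals scale
  and the 3 × 3 loss-probability recovery grid run in under a minute;
  these problem sizes match the default study conditions and keep the
  full suite fast.
* The spec of within-parent silencing when *both* retained homeologs
  are silenced produces an empty cDNA lane, which is called
  `unscorable` — the gel cannot distinguish double silencing from a
  failed reaction.

## Known limitations

* No dosage inference at the genomic tier: presence/absence only.
* No BLAST-style fragment identification, primer design, or gel-image
  processing; inputs begin at sequences and scored band patterns.
* Parental alleles must share a coordinate frame; no aligner is
  bundled.
* The intensity ratio is descriptive; no error model for densitometry
  is attempted.

```{r example}
# a 200-bp locus where a single substitution destroys the paternal
# EcoRI site: the classic diagnostic situation
maternal <- paste0(strrep("A", 79), "GAATTC", strrep("A", 115))
paternal <- paste0(strrep("A", 79), "AAATTC", strrep("A", 115))
assay <- design_assays("TRX1", maternal, paternal)[[1]]
assay

call_genotype(c(200, 120, 80), assay)$call  # both parents' diagnostics
call_genotype(c(120, 80), assay)$call       # paternal diagnostics gone
call_expression("additive", c(120, 80), assay)
```
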