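---
title: "Methods: LINE exonization analysis with linexon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LINE exonization analysis with linexon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linexon)
```

# The problem

Mammalian introns are littered with fragments of LINE retrotransposons.
An antisense L1 fragment is rich in cryptic splice sites and
polyadenylation signals, so every insertion is a potential new exon or
premature 3′ end. Whether that potential is realized depends on two
axes that this package quantifies: the *evolutionary age* of the copy
(young, primate-specific insertions still carry dense runs of
splice-silencer motifs that decay with divergence) and the *repressive
RBP coat* (proteins such as MATR3 and PTBP1 bind these motif runs and
silence the cryptic sites). `linexon` implements the computations for
each axis — inclusion quantification, age classification, motif
multivalency, binding scores and RNA maps, poly(A)-site usage — plus a
seeded generator of synthetic data with planted ground truth.

# Exon inclusion

For an internal exon with `up`/`down` junction-spanning reads supporting
its two inclusion junctions and `skip` reads joining its flanking exons
directly,

$$\mathrm{PSI} = \frac{50\,(up + down)}{skip + 0.5\,(up + down)} \in [0, 100].$$

Each included transcript contributes two inclusion junctions while each
skipped transcript contributes one skipping junction; the factor 50 and
the half-weight on the inclusion support make the estimator the percent
of transcripts including the exon. `(0, 0, 0)` is reported as `NA`
("data not available"), not 0: absence of reads is absence of evidence.

Junction matching (`match_junctions`) tolerates a ±2 nt grace window
around each annotated splice site, requires both junction ends to match,
and only accepts internal exons (both flanking partners present). When
an exon is observed with several flanking pairs, `select_isoform` keeps
the pair with the most junction reads; the tie-break (smaller combined
flanking-intron span, then leftmost) is ours, chosen to be deterministic
and to favour the canonical short-intron isoform — the source procedure
does not specify one.

Tissue aggregation (`tissue_psi`) averages per-sample PSI over the
samples of a tissue. A sample with zero reads in all three junction
classes is ignored rather than treated as PSI 0, mirroring at sample
granularity the tissue-level "data not available" rule; a tissue is `NA`
only when all its samples are uninformative.

`filter_and_classify` keeps an exon when either support reaches 200
reads across all samples: inclusion support `sum(up + down)/2` (the
average of the two inclusion junctions) *or* skip support `sum(skip)`.
The phrase "at least 200 reads (average of up+downstream junctions or
skipping junctions)" admits a pooled reading; we adopted the
either-support reading because it matches the parenthetical's structure
and never discards a well-measured constitutively *skipped* exon. Exons
in configured blacklist regions (by default the immunoglobulin loci,
where repeat-derived exon annotation is unreliable) are dropped
regardless of counts. Average PSI excludes promiscuously transcribed
tissues (testis, vagina, EBV-transformed lines) and maps to classes with
strict bounds: > 85 constitutive, < 15 lowly included, boundary values
(exactly 85 or 15) alternative.

`filter_exonic_bins` implements the cryptic-exon calling contract on
flattened exonic bins: merge adjacent bins with equal inclusion in both
conditions first, then require ≥ 5 nt, ≥ 6 reads (summed over a merged
run) and inclusion strictly above 15% in at least one condition.
Survivors not coordinate-identical to an annotated exon are *cryptic*;
those with a splice site inside a LINE interval are *LINE-derived*.

# Repeat age

`curate_liftover_status` converts a raw liftover outcome into an
ortholog status: `lifted` is only *present* when ≥ 33% of the lifted
interval is LINE-annotated in the target genome (implemented as
`fraction >= 0.33` exactly, the literal reading, with no rounding);
`lifted` below that is *notLINE*, `partially_deleted` is *degenerate*,
`deleted` is *absent*.

`classify_age` applies an ordered decision table over six species
(gorilla, rhesus; mouse, rat; dog, cow — the clade roles are
configurable, so a mouse-centric analysis can swap the primate and
glires roles):

1. *primate_specific* — absent everywhere, or seen in ≥ 1 primate while
   absent-or-notLINE in every non-primate;
2. *euarchontoglires_specific* — absent-or-notLINE in both
   laurasiatherians, present-or-degenerate in mouse or rat;
3. *two_distant* — present in dog and cow;
4. *one_distant* — present in exactly one of dog/cow with the other
   absent-or-notLINE (notLINE counts as non-presence);
5. *degenerate* — degenerate in both laurasiatherians;
6. *unclear* — everything else, excluded from phylogenetic comparisons.

The table is total by construction: an exhaustive test over all
$4^6 = 4096$ status vectors confirms every vector maps to exactly one
label. The precedence for mixed outgroup vectors (degenerate in one
laurasiatherian, absent in the other) is not specified by the source
procedure; such vectors deliberately fall to *unclear* rather than being
guessed into a class. Cross-assembly bridging (discarding elements not
re-locatable in a newer assembly) is an upstream curation step outside
this package's scope.

# Motif multivalency

Motif statistics run on the element's repeat-strand sequence; RNA motifs
(AUCUU, CUCUU) are matched as DNA. `motif_occurrences` counts
overlapping match starts and the fraction of element positions covered
by ≥ 1 match (interval-union semantics, verified against brute-force
position marking); IUPAC codes are expanded in the pattern only, so `N`
in a sequence never matches. `max_window_coverage` is the key
multivalency statistic: the best 100-nt window's covered-position
percentage, capturing the local clustering of silencer motifs that a
whole-element average dilutes. Dots are called at ≥ 10% (two
pentamer/hexamer motifs per window) and ≥ 20%. We made the thresholds
inclusive so the canonical two-motif window (exactly 10%) qualifies,
resolving an internal inconsistency in the source description ("more
than 10% … corresponding to two pentamer motifs", which are 10%
exactly).

`rank_motif_enrichment` ranks motifs by
`median(coverage per 100 nt | young, motif found) − median(… | old,
motif found)` and flags the 2.5% extremes of the empirical statistic
distribution as gain/loss (empirical FDR < 0.05). Medians are taken over
elements in which the motif occurs, *separately per group* — the source
text does not resolve joint-vs-separate conditioning; separate
conditioning keeps the statistic defined whenever the motif is seen in
both groups. The statistic is antisymmetric under group swap (tested).
Decile and tail cuts use `ceiling`, ties broken by element or motif
identity, for determinism.

# CLIP binding

`element_coverage` reports cDNAs per 100 nt and per million library
cDNAs; library-size normalization is by total mapped cDNAs throughout —
no TMM or median-of-ratios scaling, matching the convention of
percentage-of-library track scaling. `relative_binding_scores` restricts
to the top 10% of elements by any-RBP coverage (a proxy for expressed
transcripts), normalizes each element's per-RBP coverages to sum to 1,
and summarizes an RBP's preference for an age group as the group-mean
score over the across-group mean. Elements with zero total coverage
inside the decile have undefined scores and are excluded with a warning.

`classify_peak_dependence` compares peak counts between control and
co-factor-depleted conditions after scaling both to the mean library
size. The fold change is moderated with a pseudocount of 4 per condition
— a deliberate, transparent stand-in for empirical-Bayes shrinkage that
behaves equivalently for the classification at these depths — and peaks
with mean normalized count < 8 are excluded. The class cutoffs
(dependent at LFC ≤ −1, independent at |LFC| < 0.25) are package
defaults exposed as arguments, since the source analysis prints no
numeric cutoffs; classification is monotone in the depleted/control
ratio (tested).

`rna_map` builds metaprofiles: a ±`flank_nt` window around each locus,
oriented 5′→3′ of the host gene, per-position percent occupancy
(fraction of loci with a crosslink, or covered by an interval, at that
offset) averaged in `bin_nt` bins. Normalization to locus count makes
profiles of different locus sets comparable, and the profile of a pooled
locus set is exactly the locus-count-weighted mean of the parts
(tested). `match_control_loci` draws intron-length-matched control loci
by stratified sampling within pool intron-length deciles.
`classify_proximity` applies the 500 nt / 2000 nt edge-distance classes
after removing elements ≤ 100 nt, and `positional_binding_profile`
summarizes splice-site-distance bands (0–100, 100–500, 500–2000,
2000–5000 nt) over introns ≥ 7 kb, ranking tracks by the deep-band to
first-band density ratio.

# Poly(A) sites

`internal_priming_filter` removes a 3′-end read when its ±10 nt genomic
flank contains `AAAAAA` or any 10-nt window with > 70% A — strictly more
than 7 of 10, so a 7-A window without a 6-run survives. The
implementation equals a brute-force scan of all eleven windows on random
flanks (tested on 10,000).

`pair_polya_sites` labels the two highest-count sites of a gene `pA1`
(proximal) and `pA2` (distal) *in transcription order* — not genomic
left-to-right — when both hold ≥ 5% of the gene's reads. For genes with
more than two sites the source outcome (exactly-two-site genes vs
top-two-of-many) is not recoverable; we pair the top two by count and
leave the rest unpaired, which reduces to the documented behaviour for
two-site genes. `proximal_usage_change` reports
`Δ = use(depleted) − use(control)` with `use = 100·pA1/(pA1 + pA2)`,
stratified by `annotate_line_proximity`'s 2-kb LINE window.

# The synthetic generator

`syn_config`/`generate_fixture` build the study conditions every test
runs under. All randomness flows from one root seed through independent
per-component substreams, so adding a generator never shifts another's
draws, and identical configurations give byte-identical bundles.

* **Age mixture** defaults to the relative sizes of the phylogenetic L1
  classes among classified human L1 copies (≈ 0.595 primate-specific,
  0.050 euarchontoglires, 0.147 one-distant, 0.038 two-distant, 0.170
  degenerate). Ortholog tables are built from status templates that the
  classifier provably maps back to the true label, so label recovery is
  exact by design — this validates plumbing, not classifier robustness
  to noisy liftovers.
* **Sequences** derive from one synthetic 6-kb consensus by iid
  substitution at a per-class rate (5% young → 30% degenerate,
  spanning the divergence range of genomic L1 classes); no indels in
  this version, which is sufficient for divergence-ordering and
  motif-decay properties but does not model truncation. Young elements
  get a planted run of eight CTCTT silencer motifs (10 nt apart),
  emulating the multivalent pyrimidine-tract binding sites of young L1s.
* **Junction counts** are drawn per sample as a Poisson total around
  `2 × read_depth` split multinomially in proportions `(p, p, 1 − p)`
  with `p` the planted inclusion fraction, the simplest scheme under
  which the PSI estimator is consistent: plugging the expected counts
  into the formula returns the planted PSI exactly, and planted PSI 100
  forces zero skip reads in every sample. Default depth 50
  reads/exon/sample with 5 tissues × 4 samples; recovery error shrinks
  as depth grows (tested at depth 200 over 1000 exons: ≥ 95% of
  exon-tissue PSIs within ±5 points).
* **Crosslink tracks** scatter Poisson cDNA counts uniformly over each
  element at 0.02 cDNA/nt baseline; repressor-labelled RBPs get a 4-fold
  density on young elements (enhancers the inverse), matching the
  enrichment magnitude the binding-score analysis is expected to
  resolve.
* **Poly(A) reads** place two sites per gene (60/40 proximal bias) and
  label each read an internal-priming artifact with the configured
  probability (default 0.3); artifact flanks carry a planted `AAAAAA`
  and genuine flanks are rejection-sampled to pass the filter, so filter
  sensitivity and false-removal rate are exactly 1 and 0 by
  construction — again a plumbing guarantee, not a claim about real
  A-rich genomic context, where genuine sites near A-rich stretches are
  discarded too.

What the generator does *not* emulate: real L1 sequence composition and
ORF structure, transposition target-site biology, read-level errors,
overdispersed junction counts (the hook exists but the default is
Poisson/multinomial), correlated tissue effects, and liftover noise.
Passing tests therefore demonstrate correctness of the computations
under clean planted structure, not robustness to every artifact of real
data.

# Problem sizes and numerical choices

The shipped tests use fixtures of 60–1000 elements, 12–1000 genes and
up to 1000 samples for the Monte-Carlo PSI check — sizes at which every
planted effect is resolvable with comfortable margins while the whole
suite runs in about a minute. Percentages are 0–100 throughout, matching
the PSI convention; coordinates are 0-based half-open internally with
conversion at the I/O boundary (RepeatMasker 1-based inclusive, BED
0-based); junctions are recorded as (last exonic base of the donor,
first exonic base of the acceptor). Degenerate inputs have defined
behaviour: all-zero junction rows are `NA` not 0, empty age groups warn
and drop, zero-coverage decile elements warn and drop, empty tracks are
valid and rank as `NA`.

# Interface note

The package's surface is its exported functions plus
`scripts/acceptance.R`; analyses in this domain are driven from R
scripts, so no shell subcommand wrapper is shipped.
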