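---
title: "Calling miRNA loci and mapping their transcripts in an AT-rich genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling miRNA loci and mapping their transcripts in an AT-rich genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlocus)
```

# The problem

In *Dictyostelium discoideum* — a social amoeba with a very AT-rich
(~78%) genome — mature ~21-nt miRNAs are produced from stem-loop
precursors embedded in capped RNA polymerase II primary transcripts
(pri-miRNAs). A single nuclear Dicer-like RNase III enzyme is required for
essentially all miRNA maturation: in its knockout, mature miRNAs drop by
orders of magnitude while the unprocessed pri-miRNAs are stabilized and
accumulate. That genetic contrast is the analytical lever this package is
built around. Small RNA libraries from wild type define the mature duplex
products; the knockout's depletion separates genuine miRNA loci from the
vastly more abundant repeat-derived siRNAs (which are made by a different
Dicer and are genotype-invariant); and the knockout's stabilized long
transcripts expose where pri-miRNA transcription starts and ends.

`mirlocus` implements the full analysis: read classification, the
high-confidence calling criteria on folded hairpins, pri-transcript extent
and readthrough mapping, untemplated oligo(A) tail detection, and TSS
motif discovery — all exercised against a seeded synthetic-data generator
with planted ground truth.

# Coordinate conventions

Internally every interval is 0-based half-open, on a named genome segment,
with a strand. Results are reported in the field's signed, zero-free
system anchored on the mature product: position +1 is the first nucleotide
of mir-5p, upstream positions are negative, and 0 does not exist.
`to_relative()` / `from_relative()` convert at the reporting boundary and
are exact inverses on both strands; `span_length()` counts inclusive
positions while skipping the nonexistent 0, so a transcript mapped from
−281 to +388 is

```{r}
span_length(-281, 388)
```

nucleotides long. Keeping the signed system out of the core avoids
off-by-one leakage: there is exactly one conversion point, and a
10⁴-case property test pins the bijection.

Reads on the minus strand are flipped into locus orientation when stacks
are built, so every downstream module reasons in locus-forward
coordinates.

# Hairpin structure and the internal folding model

Candidate hairpin windows (the annotated hairpin interval ± 20-nt flank,
configurable) are folded with a base-pair-maximization recursion using
pair pseudo-energies GC = −2, AU = GU = −1, a minimum loop of 3 nt, and a
deterministic tie-break toward the structure whose opening pair is
5′-most. This is *not* a thermodynamic nearest-neighbor model and its
energies are pseudo-units: comparable across sequences folded by the same
model, but not kcal/mol. Consequently the folding-energy criterion runs at
two thresholds: the canonical −0.2 kcal/mol/nt when structures come from
an external thermodynamic folder (via `read_structure()`, a three-line
sequence / dot-bracket / `energy=` format), and a recalibrated default of
−0.5 pseudo-kcal/mol/nt for the internal model. The recalibration point
was chosen from the model's behavior at design time: random AT-rich
sequence folds to roughly −0.35 to −0.45 pseudo-units per nt under
maximization (AU pairs are cheap and plentiful), whereas GC-rich planted
stems reach −0.55 and beyond, so −0.5 separates structured hairpins from
background with margin on both sides. The threshold is configurable
(`call_thresholds(energy_per_nt = ...)`), and users with real folding
energies should prefer external structures.

The folder is verified against an independent brute-force enumeration of
all legal nested structures on hundreds of random short sequences — score
and structural legality both.

Duplex geometry is measured on the pairing map: the 3′ overhang on each
duplex end is the offset between an arm's 3′ end and the pairing partner
of the opposite arm's 5′ end, with unpaired termini resolved by scanning
inward up to 3 nt (an unresolvable overhang fails the criterion rather
than erroring). The duplex pairing fraction is the share of mir-5p ∪
mir-3p positions paired in the precursor.

# The calling criteria

`classify_locus()` evaluates, per duplex pair:

| criterion | default | meaning |
|---|---|---|
| i read support | ≥ 10 reads/arm | both arms of the duplex observed |
| ii 3′ overhang | exactly 2 nt (strict); 0–4 relaxed | RNase III signature |
| iii 5′ homogeneity | ≥ 50% share the modal 5′ end, each arm | precise processing |
| iv folding energy | < −0.2 kcal/mol/nt (external) / < −0.5 pseudo (internal) | stable hairpin |
| v duplex pairing | ≥ 60% of duplex positions paired | the duplex is in the stem |
| knockout dependence | log2FC ≤ −2, both arms, pseudocount 1 on CPM | microprocessor substrate |

Boundary semantics follow the published wording: homogeneity and pairing
are inclusive ("at least"), the energy inequality is strict ("below"),
and read support is inclusive at 10. "Clearly downregulated" is
quantified as log2FC ≤ −2 — conservative, and robust to the pseudocount
at realistic library sizes. Wild-type replicates and timepoints are
pooled before criteria are applied; developmental regulation (|log2FC| ≥
1 between growth and development on the dominant arm) is reported as a
flag, not a filter.

Arms are assigned by the side of the principal hairpin loop holding ≥ 50%
of the read span. The principal loop is the one under the deepest stem;
shallow side-hairpins that AT-rich flanks fold into are tolerated, while
two equally deep separated loops reject the structure as "not a simple
hairpin". The modal read of an arm is the most frequent (5′ start,
length), ties broken toward the smaller start then the longer read, so
verdicts are pure functions of the stack — permuting read order cannot
change them.

A locus is `high_confidence` iff i, ii (strict), iii, iv, v and knockout
dependence all pass for at least one duplex pair; `candidate` iff
everything passes except read support (the situation of a true locus
occluded by the siRNA background — the published set retained such a
locus with 9 reads on one arm), or when the overhang passes only in
relaxed 0–4 mode; otherwise `reject`. The full per-criterion report is
always attached, so failures are attributable.

## moR-style secondary pairs

Some hairpins produce two duplex pairs sitting immediately adjacent on
the same stem (the miRNA-offset-RNA pattern). `detect_mor_pairs()` masks
the primary duplex's reads (5′ starts within ±2 of each modal), re-calls
arms on the residue, and accepts the secondary pair iff it passes read
support and homogeneity and is adjacent (gap ≤ 3 nt, no overlap) to the
primary on both arms. The base-proximal pair is labeled "-1", the
loop-proximal "-2". Because adjacent pairs are distinct processing
products, the criteria are evaluated per pair on pair-restricted stacks
(reads assigned to the nearest pair's modal starts) — otherwise the
secondary pair's reads would dilute the primary arm's 5′ homogeneity
toward 50% and sink loci that are, in fact, precisely processed.

# Transcript extents, readthrough, and termini

Extents come from coverage depth, not individual read ends: the 5′- and
3′-most positions with depth ≥ `min_depth` (default 1) inside a search
window, reported in mir-5p-relative coordinates. A separate `end_census()`
serves RACE-like per-clone end data (dominant end = most frequent, ties
3′-most), keeping sequencing-depth artifacts and clone-level evidence
apart.

Readthrough detection walks coverage from the hairpin's 3′ edge toward a
downstream feature. A-homopolymers resist both library chemistry and
alignment, so zero-coverage gaps are tolerated iff they are ≤ 50 nt long
*and* ≥ 80% A on the locus strand (both configurable); the locus reads
through iff covered positions inside the downstream feature are reached.
The two knobs operationalize a qualitative observation — they are
deliberately explicit configuration rather than hidden heuristics, and
the call is monotone in `max_gap`.

Untemplated tails follow the maximal-templated-extension convention: the
read is matched against the genome from its anchored 5′ end as far as
possible; the unmatched 3′ suffix is the tail, and a suffix of 1–10 As is
an oligo(A) call. When the suffix is all-A and the templated end itself
runs through As, the true boundary is unknowable; the last templated A is
reported as the templated end and the ambiguity is carried explicitly as
`tail_len_min..tail_len_max` (adding the contiguous templated terminal
As). A tail that the genome can absorb entirely is, by the same
convention, reported as no tail — the range brackets the truth in every
detectable case, which the property suite checks on randomized AT-rich
constructions.

The TSS motif search scans the 140 nt upstream of the 5′-most covered
position (the observable proxy for the capped TSS) for maximal runs of ≥
8 Ts immediately followed by a G — the G being the predicted start. No
minimum run length is established in the literature for this motif; 8 was
chosen as the shortest run that is rare in random 78%-AT sequence within
a 140-nt window (expected < 0.1 spurious hits per window that would
outrank a planted run under the ranking below). Hits are ranked by run
length, then by distance to the anchor, which makes the top hit
deterministic where promoter-mapping experiments are unavailable. The
position frequency matrix aligns per-locus windows at the G (+1) and is
exactly the mean of the one-hot base matrices — verified against a brute
force recomputation.

# The synthetic-data generator

`sim_scenario()` fixes the study conditions; `simulate_dataset()`
produces a genome, features, four small RNA libraries (wt/knockout ×
growth/development), coverage tracks, and tailed intermediate reads, all
byte-deterministic under (scenario, seed).

**Genome.** 50 kb at 78% AT background. Twenty miRNA loci are planted,
each a hairpin with perfectly reverse-complementary GC-rich arms
(20–22 nt, 90% GC), an all-A loop (8–20 nt), a basal stem (4–8 pairs),
and 2-nt 3′ overhang duplex geometry; upstream of each, a T-run
(10–26 nt) immediately followed by the G that is the planted TSS. The
stems are GC-rich so that the pseudo-energy criterion separates them from
AT-rich background; this is a deliberate idealization (see Limitations).
Two model loci carry the published-style geometry: locus 1 has its TSS at
−281 behind a 21-T run, a pri 3′ end at +388 (a 669-nt transcript), and
two 3′-intermediate sites at +243 (unambiguous) and +248 (preceded by
exactly three templated As, so tail lengths there are ambiguous by
construction); locus 2 has its TSS at −116 behind a 26-T run, a wild-type
3′ end at +197, a 31-nt A-run gap, and a downstream gene into which its
knockout transcript reads through. Two loci produce stacked double
duplexes (the moR pattern) and three sit on the minus strand. Because
random GC-rich stems occasionally admit co-optimal folds that scramble
the planted geometry, every planted window is folded at build time and
the stem resampled until the fold reproduces the planted duplex
geometry — the generator's contract is that planted geometry is real
geometry, by construction.

**Decoys.** Ten decoy hairpins violate exactly one criterion each — two
per criterion: too few reads (4/condition, exact counts), scrambled 5′
ends (deterministic 35% modal share), 5-nt overhangs, AT-only stems
(energy), or a 9-pair symmetric A/A internal loop in the duplex
(pairing ≈ 0.55–0.59, with a deeper all-GC basal stem keeping the energy
criterion green). Orthogonality is enforced: decoy read compositions are
deterministic where sampling noise could otherwise trip a second
criterion, and decoys are modeled as non-substrates of the processing
enzyme (genotype-invariant), so they also fail knockout dependence and
never leak into the candidate tier.

**Libraries.** Counts at miRNA and decoy loci are negative binomial
(dispersion 0.1) around 20 reads/condition for true loci, tripled at the
developmental timepoint; arm reads draw lengths peaked at the mature
length and 5′ ends equal to the modal with probability 0.9 (else ±1–3 nt
jitter). The knockout divides miRNA counts by 50 and halves 5′
homogeneity (residual heterogeneous processing by the other Dicer). The
bulk of each library is genotype-invariant: ~30,000 DIRS-1-like siRNA
reads per condition on both strands of five dispersed repeat copies,
~14,000 intergenic background reads, and small structural-ncRNA and mRNA
fractions — so 21-nt class fractions come out at roughly 68–69% DIRS-1
and ~29% intergenic in both genotypes. A TRE3-like complex-repeat class
rises threefold in the knockout (about 0.7% → 2.1% of 21-nt reads), on
the same order as the miRNA reads the knockout loses; with both effects
in place the DIRS-1 *fraction* is genotype-stable by construction, which
is exactly the observed configuration this scenario emulates (DIRS-1
stays near 68% while minor repeat classes rise and miRNAs collapse).
Bulk class totals are Poisson: the negative-binomial overdispersion
belongs to per-locus counts, not to aggregates over thousands of
independent sites, and fraction comparisons between genotypes are then
well calibrated against binomial error.

**Coverage.** Pri spans get depth ~5 in wild type (Poisson, floored at 1
so planted endpoints are always observable) and 8× that in the knockout;
the readthrough locus's knockout span extends into the downstream gene;
planted A-run gaps are forced to zero depth in both genotypes; mRNA
features get constant genotype-invariant background. Library sizes are
fixed at 10⁶ so per-million values are directly comparable.

**What passing does and does not show.** The generator emulates the
statistical structure the analysis relies on — duplex geometry, 5′-end
precision, knockout contrast, coverage plateaus, A-run dropouts,
templated-A ambiguity — but not sequencing error, adapter artifacts,
quality scores, multimapping ambiguity beyond a `hits` field, splicing,
or the long-tailed expression distributions of real libraries. Recovery
on the default scenario demonstrates the pipeline's correctness on data
satisfying its assumptions, not its performance on real libraries.

# Problem sizes and determinism

The default scenario simulates ~190,000 reads across four libraries over
a 50-kb genome with 30 candidate loci; the full pipeline runs in well
under two minutes on one core, and the test suite exercises it end to
end. Sizes were chosen so that per-arm read counts sit comfortably above
the criteria thresholds (minor-arm expectation ≈ 36 pooled reads against
the 10-read criterion) while fraction comparisons have enough
denominator (~60,000 21-nt reads per genotype) for sub-percent binomial
resolution. Every random draw flows from one integer seed through fixed
per-stage offsets, so genomes, libraries, coverage, verdicts and reports
are byte-identical across runs and platforms.

# Known limitations

- The internal folder maximizes weighted pairings; it has no stacking,
  no dangles, no temperature. Its −0.5 pseudo-threshold is calibrated to
  this package's generator conditions and is not portable to
  thermodynamic energies (use external structures for that).
- Planted hairpin stems are GC-rich against an AT-rich background; real
  hairpins in such genomes separate from background by
  thermodynamics, not composition alone, so criterion iv's difficulty is
  understated in simulation.
- The readthrough gap tolerance (≤ 50 nt, ≥ 80% A) is an explicit
  operationalization of a qualitative phenomenon; loci with longer or
  less A-pure unsequenceable regions will need the knobs adjusted.
- Knockout dependence uses a pseudocount log2 fold change on pooled
  libraries, not a shrinkage estimator with replicate-aware error; with
  biological replicates, a dedicated differential-expression model would
  be preferable for borderline loci.
- The 10-read criterion counts arm-overlapping stack reads (the default;
  an exact-mature-sequence count is the stricter alternative), so deeply
  sequenced noisy loci are treated generously.
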