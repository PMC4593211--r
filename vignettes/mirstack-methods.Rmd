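---
title: "mirstack: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirstack: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirstack re-implements, as a tested R pipeline, a complete small-RNA
analysis for stage-structured insect libraries: read preprocessing and
stringent genome mapping, hairpin-precursor discovery from read stacks,
homology triage against a miRBase-style reference, a presence-based decision
tree for novel miRNA calls, TMM/exact-test differential expression with
profile clustering, tandem genomic cluster detection with cross-species
arrangement comparison, and a simplified seed-anchored 3'UTR target scanner.
This vignette records the models behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the design was genuinely open.

## The study design the pipeline assumes

Libraries are small-RNA fractions (17–28 nt) from five developmental stages
— egg, larva, male pupa, female pupa, ovary — with three biological
replicates each and one library (female pupa replicate 2) never sequenced,
so 14 libraries in all. Counts per miRNA are overdispersed across replicates;
a negative-binomial model with common dispersion is used throughout.

## Preprocessing and mapping

Reads shorter than 17 nt are discarded (`min_len = 17`); identical sequences
are collapsed per library and merged across libraries with per-library
counts. Unique sequences are mapped with an exact seed of 18 nt (the 5'
prefix; for 17 nt reads the whole read is the seed and must match exactly —
the upstream convention leaves this case open), at most 2 substitutions
outside the seed, no indels. Reads hitting more than `max_hits = 5` loci are
dropped entirely; otherwise only the best alignment is reported, ties broken
by (fewest mismatches, scaffold name, start, `+` before `-`). The best-hit
threshold is deliberately configurable because the source conventions
disagree between "more than 5 times" and "up to 4 locations"; the default
follows the stated mapping protocol (5).

The index is an exact k-mer table over the forward strand; minus-strand hits
are found by reverse-complement canonicalization of the query seed, so both
strands are searchable. A brute-force scan of every genomic window is kept
in the test suite as the mapping oracle.

## Hairpin discovery

**Excision.** Maximal same-strand overlapping alignment sets ("stacks") with
summed count ≥ `min_stack = 5` each yield two candidate windows: the stack
read as prospective 5' arm (70 nt flank added downstream in transcript
orientation) and as 3' arm (flank upstream). 70 nt is the typical metazoan
precursor scale. Windows outside 40–250 nt are not evaluated: below 40 nt no
hairpin fits, and above 250 nt a window cannot be a canonical precursor
while its cubic-time fold would dominate runtime.

**Folding.** The fold is a Nussinov-style maximum-weight, pseudoknot-free
pairing with weights GC = 3, AU = 2, GU = 1 and a minimum hairpin loop of 3.
It is a stand-in for a thermodynamic MFE model, so stability is reported as
a unit-free `mfe_proxy = -(total pair weight)`. One consequence matters for
design: a max-pairing model cannot "ignore" unpaired flanking sequence the
way free-energy models do — random RNA pairs extensively under Nussinov —
so each excised window is evaluated at several stack-anchored extents
(flanks of 3, 25, 40, 55, 70 nt) and the best shuffle-free score picks the
precursor extent. The fold of sequences ≤ 18 nt is verified in the tests
against exhaustive enumeration of all structures.

**Stability test.** The selected extent (only that one, to avoid
multiple-testing inflation across extents) is compared against
`n_shuffles = 99` dinucleotide-preserving shuffles (Altschul–Erickson
Eulerian-path shuffle): `p = (1 + #{shuffled mfe <= observed}) /
(n_shuffles + 1)`. Sequences under 10 nt return p = 1. The test is skipped —
p set to 1 — when even a significant fold could not lift the candidate above
the reporting threshold; this is purely a runtime optimization and cannot
change which candidates are reported.

**Read-class assignment.** The most abundant read in the window is the
mature; reads overlapping it form the mature block. The main hairpin loop is
located at the innermost pair around the last `(` of the dot-bracket; the
most abundant block fully on the opposite arm is the star; remaining reads
overlapping the loop are loop reads, the rest "other".

**Score.** An additive surrogate (the upstream probabilistic score is not
specified by its published description):

```
score = min(log2((mature+1)/(loop+other+1)), 4)   # capped dominance
      + 2·[star reads observed]
      + 3·[shuffle p <= 0.05] − 3·[shuffle p > 0.05]
      − 12·[mature block not on one arm]
```

The cap means sheer abundance cannot carry a candidate: an abundant
single-block stack without a significant fold tops out at 4 − 3 = 1, below
the reporting threshold of 2. Candidates scoring ≤ −50 are dropped from the
candidate list entirely; `reported` marks score > 2. Decoy loci pass the
shuffle test at its nominal ~5 % false-positive rate, which is the expected
and accepted contamination level of the reported list. Both arms of a
hairpin are typically found as separate "mature" stacks; overlapping
same-strand precursors are therefore merged, keeping the best-scoring
representative.

**Exon overlap.** Pure interval arithmetic on the same scaffold, ignoring
exon strand (the strandedness of this published check is unstated):
`within_exon`, `contains_exon`, `overlaps_exon_boundary`, `intronic` (inside
a gene's exon span without touching an exon), else `intergenic`.

## Homology classes

Mature queries are compared against the reference mature set through shared
exact 16-mers (so only near-identical entries are considered, emulating a
short-word BLAST at word size 16), then scored ungapped over each shared
diagonal. `perfect` means mismatch-free, full-length, equal-length;
`near_perfect` allows one mismatch or up to a 2 nt length difference. A
16-mer word means a single central mutation in a 22-mer can hide an entry
entirely — that is inherited intentionally from the word-size-16 protocol.

Hairpin queries use seed-and-extend ungapped local alignment (match +1,
mismatch −2, X-drop), both orientations, a score floor standing in for a
near-identity E-value cutoff, and the coverage rule discarding matches where
the query is more than 8 bases longer than the aligned stretch. Candidate
labels: `known` = perfect mature match; `iso` = near-perfect mature match or
a surviving hairpin-only match ("iso-miRNA" is operationalized as
near-perfect-but-not-perfect; the class is named but not defined in the
source literature); everything else `novel_candidate`. Every candidate gets
exactly one label.

Reciprocal best hits between two hairpin sets use the same matcher but with
the length-slack filter disabled: that filter belongs to the
reference-database screen, and hairpin conventions (how much genomic flank
an entry carries) legitimately differ between species' sets. Ties break on
alignment score, aligned length, then lexicographic id.

## The novel-miRNA decision tree

Presence is count > 0; an unsequenced library shrinks denominators rather
than counting as absence. Rules are evaluated in order: R1 (present in every
sequenced library) accepts; R2 (absent in exactly one replicate of one
stage) accepts; stage-restricted candidates (present in ≥ 2 stages with ≥ 2
detected replicates each while ≥ 1 whole stage is silent) accept unless the
total count is below `min_total_count = 10` or no star reads were seen
(R3a), or the hairpin is malformed (R3b); everything else rejects as
R4 — including presence patterns the published narrative never encountered,
for which R4 acts as the catch-all "insufficient breadth" rule. A final
guard (R5) rejects any accept-path candidate whose mature count does not
dominate its star count. The `min_total_count` default of 10 sits below the
smallest published accepted total (102) and above single-digit noise.

One honest property of this rule set: a decoy locus expressed consistently
in every library (e.g. a degradation hotspot of an abundant transcript)
passes R1 — presence-based triage cannot reject it. In practice the fold
test removes most such loci at reporting; the few that pass appear among
accepted novels, as they would in the original procedure.

## Expression

Counts per miRNA are obtained by summing collapsed-read counts over best
alignments overlapping each reported mature locus. Normalization and the
pairwise exact test are delegated to edgeR — the implementation the original
analysis itself used: TMM factors (30 %/5 % trims, geometric mean 1) via
`calcNormFactors`, and the two-sided exact negative-binomial test via
`exactTest` with either a common dispersion estimated by `estimateCommonDisp`
(`dispersion = "auto"`) or a fixed value (0 gives the binomial/Poisson
limit). Tests verify these against longhand oracles: a hand-computed
two-sample trimmed-mean factor, exact binomial tails, and the textbook BH
formula. P-values are BH-adjusted within each contrast; significance is
FDR < 0.05; the log2 fold change is computed from normalized stage-mean cpm
with a 0.5 pseudo-count, so it is exactly antisymmetric under swapping the
contrast. All 10 unordered pairs of the five stages are tested by default
(the source text says "11 possible comparisons" in one place and 10 in
another; 10 is combinatorially correct for five groups).

Profile clustering uses log2 ratios of stage-mean cpm (pseudo-count 0.5)
under Euclidean distance and complete linkage. Cross-species comparison
computes Spearman's rho on ortholog-paired cpm per library pair, with a
two-sided t-approximation p-value; cells with fewer than 5 pairs are
flagged rather than computed.

## Genomic clusters

Loci are grouped by (scaffold, strand), sorted, and chained while the
end-to-start gap is ≤ 10 kb (start-to-start measurement is available as an
option); chains of ≥ 2 are clusters. Spans are max(end) − min(start).
Note that in the packaged 31-locus fixture the published "3.5 kb maximum
span" belongs to the largest cluster *by membership* (8 members); a
4-member cluster in the same table spans 4.0 kb, so 3.5 kb is not the
maximum over all clusters.

Arrangement comparison extracts shared families (duplicate labels
preserved), orientation-normalizes when the clusters sit on opposite
strands, and calls `identical`, `reversed`, `rearranged`,
`partial_overlap` or `disjoint`. One design decision: the published
duplicated-family example is `rearranged` even though one species' cluster
carries a family the other lacks, while a single shared family between
otherwise different clusters is `partial_overlap`. These two expectations
cannot both follow from a plain multiset rule, so the order comparison
proceeds whenever the shared family set covers at least one cluster's full
family complement, and `partial_overlap` is returned otherwise.

## Target scanning

Sites are anchored by an exact Watson–Crick complement of miRNA positions
2–7 (6mer; extended to 7mer/8mer classes when positions 8 and 1 also pair).
The 3' remainder aligns against the adjacent UTR segment with +5 per WC
pair, +2 per G:U wobble (wobble forbidden in the seed), −3 per mismatch and
a linear −8 gap penalty (equivalent to a −8 open/−8 extend convention), with
pairs at miRNA positions ≥ 12 at half weight. Raw scores are rescaled so a
perfect 22-mer duplex scores 190, which puts the conventional gates —
pairing score > 155, energy < −7 with per-pair energies −3/−2/−1 — on their
usual scale; the rescaling constant is configuration. Scores are invariant
to UTR context outside the site; overlapping sites keep the best per 25 nt
window. This scanner is deliberately simpler than a full
Smith–Waterman-plus-duplex-energy implementation, whose absolute site
counts are scale-dependent and are not treated as reproducible quantities.

## The synthetic world

The generator's defaults are the stated study conditions: 5 stages × 3
replicates minus the unsequenced female pupa replicate 2; read classes
75 % mature / 8 % star / 2 % loop / 15 % decoy; an extra 4.7 % of reads
below 17 nt; negative-binomial dispersion 0.1; three expression-profile
groups (rising toward pupa; larva-peaked; pupa-depleted/ovary-high) with
4-fold profile contrasts; a 6-copy genomic repeat to exercise the
multiplicity filter; and a cross-species rank correlation target of 0.8
(realized through a Gaussian copula, converting the Spearman target to its
Pearson equivalent).

Where the study conditions do not pin a value, one realistic choice was
made: planted precursors are 22 nt arms with a 15 nt loop and a
near-reverse-complement star arm carrying 2 mismatches (an exact reverse
complement would be a genomic palindrome mapping to both strands); mature
reads carry a ±1 nt 3' wobble; baseline abundances are lognormal (real
miRNA expression spans orders of magnitude without ties); decoys are
concentrated at 30 degradation hotspots with a small uniform scatter,
because uniform genome-wide unique-read coverage at toy genome scale would
chain read stacks across whole scaffolds, which hotspot-concentrated real
background does not; and unrelated read-producing loci are placed in slots
spaced wider than the 10 kb cluster gap, standing in for the ~1 Mb typical
spacing of miRNA loci in a real assembly.

Scale: libraries default to 3,000 reads (not millions) so the read-level
pipeline runs in seconds. Count-level checks that depend on statistical
power at a given cpm floor (differential-expression recovery at
mean cpm ≥ 100) are run at study-scale depth (10^6 reads per library),
since they need only the count matrix. Genome size (6 × 88 kb) is likewise
a toy stand-in for a ~100 Mb assembly.

What a green test establishes: that each operation implements its stated
rule (verified against independent oracles), and that the integrated
pipeline recovers planted signal under the stated noise model. What it does
not establish: fidelity to any particular thermodynamic folding model or
probabilistic discovery score (both deliberately replaced by documented
surrogates), sequencing-platform error profiles (not simulated), isomiR
complexity beyond ±1 nt end wobble, or performance at full genome and
library scale.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive everywhere; sequences are stored as DNA
  (U normalized to T on input) and mature sequences reported as RNA only at
  output boundaries.
- Fold tie-breaks: the traceback prefers leaving a base unpaired, then the
  smallest pairing partner — deterministic structures for equal-score ties.
- The shuffle test's pseudo-count form `(1 + k)/(n + 1)` keeps p in (0, 1].
- All-zero miRNAs get p = 1 and log-fold-change 0; all-zero libraries get
  TMM factor 1 with a warning; zero column sums are an error for cpm.
- Determinism: mapping output is sorted by sequence; excision and cluster
  detection are invariant to input order; pipeline TSV bodies are
  byte-identical across reruns of the same config and seed.

## Known limitations

The fold model ranks structures by pairing weight only; its shuffle test is
the sole stability guard. Homology statistics are score-floor gates, not
E-values. The triage tree inherits the blind spot of presence-based rules
for consistently expressed artifacts. The target scanner's absolute site
counts depend on its rescaling constant. Multi-loop precursors and gapped
alignment in mature matching are out of scope.
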