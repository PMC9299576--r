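---
title: "Modeling and measuring cell-free RNA fragmentation"
author: "cfRNAfrag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring cell-free RNA fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfRNAfrag)
```

## The problem

Cell-free RNA (cfRNA) circulates in plasma, saliva, urine, seminal plasma
and amniotic fluid as a heavily degraded population of fragments, most of
them shorter than 50 nt. Two features of that degradation carry signal.
First, extracellular RNases of the RNase A family cleave preferentially on
the 3\' side of unpaired pyrimidines (C and U), leaving a 3\'-phosphate and
a 5\'-hydroxyl; a fragment population dominated by RNase A work therefore
shows an excess of C/T at fragment 3\' ends and, downstream of each cut, a
bias toward A at 5\' ends. Second, those non-canonical ends are invisible
to standard ligation chemistry: only after T4 polynucleotide kinase (PNK)
rewrites ends to 5\'-phosphate/3\'-hydroxyl can such fragments be tailed,
ligated and sequenced. PNK treatment thus acts as a capture gate that
selectively admits the RNase-degraded compartment.

cfRNAfrag implements the full computational side of a
polyadenylation-ligation cfRNA sequencing workflow — read cleanup, tiered
biotype assignment, small-RNA and mRNA/lncRNA quantification, and fragment
"end-omics" (lengths, terminal bases, 4-mer end motifs) — together with a
generative simulator of the library chemistry, so that every stage can be
validated against exact ground truth without any external data.

## The simulator

The simulator is first-class, tested code; its defaults define the
conditions under which the pipeline is verified.

**Transcriptome.** `simulateTranscriptome()` draws i.i.d. sequences at a
target GC content for each biotype (rRNA, Y RNA, vault RNA, miRNA
hairpins, tRNA, piRNA, mRNA, lncRNA, other ncRNA), with one embedded
mature miRNA of 20-23 nt per hairpin. Length ranges default to values
typical of each class (e.g. tRNA 70-90 nt, piRNA 26-32 nt, mRNA 0.5-3 kb).

**Abundance.** Gene molar abundance is log-normal within each biotype
(`meanlog = 0`, `sdlog = 1.5`, a realistic dynamic range of ~4 orders of
magnitude), and the fragment stream is allocated across biotypes by a
fixed mixture. The default mixture (25% depletion-tier rRNA/Y/vault, 25%
miRNA hairpin, 15% tRNA+piRNA, 30% mRNA+lncRNA, 5% other) represents a
plasma-like library after partial depletion; it is a free parameter, not a
calibrated constant, because biofluid RNase and abundance profiles differ
in ways the underlying study reports only qualitatively. Fragments are
sampled per transcript proportionally to molar abundance times length
(mass), so transcripts-per-million-style estimates are directly comparable
to the recorded truth.

**Fragmentation and end chemistry.** Degradation is modeled as a
two-channel mixture rather than an enzymatic kinetic model — the analysis
only needs its two observable consequences:

* with probability `rnasea_channel_prob` (default 0.8) a fragment comes
  from the **RNase-A channel**: its 3\'-end cut position is drawn with
  relative weight `w_py` (default 4) at positions whose terminal base is
  C/T and weight 1 elsewhere, and it carries 5\'-OH/3\'-P ends;
* otherwise it is **pre-phosphorylated** (5\'-P/3\'-OH) and cut uniformly.

Under this rule the probability that a cut lands 3\' of a pyrimidine has
the closed form `w_py * f_py / (w_py * f_py + f_pu)`, with `f_py`, `f_pu`
the local base fractions — the quantity the test-suite checks by
simulation. The coupling of cut bias and end chemistry in one channel is
deliberate: it is exactly what makes the PNK-on/PNK-off contrast
observable, since PNK-off capture admits only the unbiased
pre-phosphorylated channel. A 5\'-adenine preference is not imposed as a
parameter; a partial preference emerges from cutting 3\' of pyrimidines,
matching the observation without an extra degree of freedom.

Fragment extent is a draw from a two-component length mixture anchored at
the cut: a short geometric component (mode 20 nt, mean 32 nt, fraction
0.9 by default — the degraded bulk) and a long uniform component (50-500
nt). Cut-anchored lengths are truncated at the transcript 5\' end.

**Capture and layout.** If `pnk_treated` is `FALSE`, only 5\'-P/3\'-OH
fragments are captured; depletion-tier fragments are additionally dropped
with probability `depletion_frac` (default 0.9, emulating targeted
depletion of abundant RNAs). Captured fragments become reads laid out as
fragment + poly(A) tail (fixed 20 nt; tailing length is a library
property, not a biological one) + 3\' adapter, truncated to the read
length (default 100 nt). In paired mode, mate 2 starts exactly at the
fragment 3\' end (reverse complement): in polyadenylation-ligation
chemistry the mate-2 primer anneals across the adapter/oligo-dT junction,
so neither tail nor adapter appears inside mate 2. Qualities are constant
Q40 except an optional low-quality tail used to exercise quality
trimming; sequencing error is a uniform substitution rate, 0 by default.

**What the simulator does not model** — and therefore what passing tests
do not show about real data: secondary-structure-dependent cleavage (real
RNase A prefers *unpaired* pyrimidines), positionally biased miRNA
processing (hairpin fragments are cut uniformly, so most fail the
mature-position rule by construction), genome-level features (introns,
promoters), UMIs, ERCC spike-ins, and quality-dependent error profiles.

## The pipeline

**Cleanup** follows the published filter chain: locate the 3\' adapter
(minimum 5-nt match, up to 10% mismatches, longest match preferred with
ties to the rightmost start — common trimmer defaults, since the source
workflow names the steps but not the tolerances), trim bases below Q15
from both ends, then strip a trailing poly(A) run of ≥ 5 nt; reads
shorter than 17 nt or with > 10% N are removed. Two boundary conventions
matter and are tested: 17 nt is kept, 16 removed; exactly 10% N is kept.
One augmentation closes a gap the plain rule order leaves: when a
construct ends inside the poly(A) tail with fewer than 5 adapter bases in
the read, the tail-plus-remnant is recognized and cut as a unit —
otherwise such reads would be unalignable end-to-end.

A known blind spot is inherent to poly(A) chemistry, not to this
implementation: a genuine 3\'-terminal A-run of the fragment merges
indistinguishably into the tail and is stripped with it. Paired-end
merging recovers the full fragment from mate 2 in that case; only
fragments short enough that the loss pushes a mate below 17 nt (a ~0.05%
tail of the default length mixture) escape measurement.

**Pair merging** places reverse-complemented mate 2 against mate 1 at the
longest overlap of ≥ 10 nt with ≤ 10% mismatches; mate-1 bases extending
past the end of mate 2 are read-through into tail/adapter and are
discarded. This overhang-aware rule (as in standard pair mergers) is what
makes merged reads equal their generating fragments exactly at zero error
for all fragments up to `2 * read_length - min_overlap` nt.

**Alignment** reimplements a forward-strand, end-to-end, ≤ 1-mismatch,
all-best-stratum transcriptome aligner: all 0-mismatch placements if any
exist, else all 1-mismatch placements. "Same best mapping quality" is
interpreted as the mismatch stratum — in a `-v`-style alignment mode there
is no other quality. The implementation is a seed-and-verify scheme in
C++ (two disjoint 8-mer seeds; by pigeonhole one seed is exact for any
≤ 1-mismatch placement of a read ≥ 16 nt; shorter reads are scanned
exhaustively) and is property-tested against a brute-force all-offset
scanner written independently in R. Output ordering is deterministic
everywhere so runs are byte-reproducible.

**Tier assignment** applies the references in a fixed order — depletion
(rRNA/Y/vault; hits are removed and counted), miRNA hairpins, tRNA/piRNA,
mRNA/lncRNA, other ncRNA — and a read is claimed by the first tier with a
best-stratum hit. Three rules sit on top:

* *mature-position rule*: a hairpin alignment counts as a mature miRNA
  only if its start is within 3 nt of an annotated mature start and its
  end within 5 nt of the mature end. "Distance at the start/end" is read
  as positional offset from the mature terminus, the standard
  interpretation for hairpin-based quantification; a substitution-distance
  reading is noted as the alternative. Reads failing the rule fall
  through to later tiers by default (`mirnaFallthrough`), which keeps
  read-count conservation exact; the drop behavior is a switch.
* *tRNA over piRNA*: a read hitting both in the same stratum is assigned
  to tRNA only, reflecting the lower confidence of piRNA annotation.
* *weight splitting*: a read with several same-stratum targets inside a
  tier contributes 1/n to each.

Conservation (`input = depleted + assigned + unmapped`) is asserted per
run and recorded in the pipeline manifest.

**Quantification.** Small RNAs are weighted counts normalized to reads
per million mapped (RPM); the denominator is all tier-assigned reads
after depletion removal by default, with a flag to include depleted reads
(the phrase "per million mapped reads" is ambiguous on this point).
mRNA/lncRNA are quantified by a transcript-level EM over equivalence
classes of reads with identical best-stratum hit sets: the E-step splits
a class across its transcripts proportionally to current read fractions,
the M-step re-estimates them, molar abundance is read fraction over
transcript length, and TPM is its normalization to 1e6. Effective length
equals transcript length — cfRNA fragments are far shorter than their
transcripts, and no fragment-length correction is warranted by the data
model. Stopping: max |ΔTPM| < 1e-3 or 200 iterations; the complete-data
log-likelihood is asserted non-decreasing; with only unique reads the EM
equals the closed-form count/length normalization exactly. Detected-gene
summaries use count ≥ 1 in ≥ 2 samples by default.

**Fragmentomics.** Lengths come from two summed strategies: merged (or
single-end) reads contribute their aligned length; unmerged pairs
contribute `(start2 - start1) + aligned_length2` when mate 1 aligns ≥ 90
nt (just under the read length, i.e. the fragment continues past a single
read) and both mates hit the same transcript. Length classes split at
< 50, 50-200, > 200 nt. The 3\' end is defined as the **last aligned
base** (`end - 1`): the cleaved pyrimidine keeps the 3\'-phosphate, so the
cleavage-adjacent residue is inside the fragment. The phrasing "one base
before the alignment locus" admits the first-unaligned-base reading too;
that alternative is exposed as `end3Unaligned`. Each end's 4-mer motif
spans two bases inside and two outside the fragment boundary, read off
the reference; motifs are computed separately for the 5\' and 3\' ends
(whether published figures pool ends is not stated), windows overrunning
the transcript edge are excluded from motif counts (but not base
frequencies), and profiles are percentages over all 256 lexicographic
4-mers. The 3\' pyrimidine/purine ratio `(C+T)/(A+G)` and the 5\' adenine
rate summarize the RNase signature; an all-pyrimidine 3\' population
reports `Inf` with a warning rather than failing.

**Cohort statistics.** PCA centers columns (no scaling by default,
matching the convention of the named base-R implementation) and uses the
SVD; Pearson r carries the usual t-transform p; the rank-sum test is
exact for groups ≤ 20 without ties (validated against full enumeration)
and a normal approximation beyond; the matched t test errors on constant
differences. Significance tiers are reported as `*`, `**`, `***` at .05,
.01, .001. No multiple-testing correction is applied in this module; the
q-values of differential-abundance workflows belong to downstream tools
fed by the exported matrices.

## Verification sizes and determinism

The test-suite verifies the end-to-end contracts at deliberately chosen
sizes: cleavage-bias closed forms at 1e5 fragments; quantification
recovery at 50 genes and 2e5 zero-error reads (rank correlation of truth
vs TPM); paired fragment-length truth at 2e4 fragments; motif-PCA
separation with 5 + 5 samples at two cleavage strengths; rank-sum
calibration over 2000 null replicates. All randomness flows from explicit
seeds; identical config plus seed yields byte-identical FASTQ, tables and
manifest, and the manifest records a config hash so any output is
traceable.

## Known limitations

Transcript-space only (no genome coordinates, no splicing or gapped
alignment); no 5\' adapter handling or UMIs; the sense/antisense
diagnostic is the one place reverse-complement alignment is used; RPM/TPM
are point estimates without uncertainty; and the simulator's i.i.d.
sequences understate the motif structure, repeat content and
multi-mapping pressure of a real transcriptome, so real-data multi-mapping
rates will be higher than in these checks.
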