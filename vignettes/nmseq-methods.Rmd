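---
title: "Models and methods behind nmseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmseq)
```

# Scope

nmseq studies how well ribose 2'-O-methylation (Nm) sites can be mapped,
quantified and assigned to guide snoRNAs from two complementary
sequencing readouts:

* **oxidation-based 3'-end sequencing** (RibOxi-seq-style), where
  iterative periodate oxidation and beta-elimination remove unmethylated
  3' nucleotides so that only Nm-terminated fragments ligate to the
  sequencing linker — Nm sites appear as single-nucleotide 3'-end peaks;
* **alkaline-fragmentation end profiling** (RiboMeth-seq-style), where
  cleavage requires the ribose 2'-OH, so methylated positions show a
  read-end deficit quantified by the *MethScore*.

Because real libraries at tens of millions of reads cannot be reproduced
at desk scale, the package pairs every analysis step with a synthetic
data generator that plants known sites. All guarantees quoted below are
measured against that planted truth, by the test suite and by
`scripts/acceptance.R`.

# The 3'-end simulator

`simulate_riboxi()` draws, per contig, a Poisson number of molecules
around the configured depth and places each molecule's fragmentation
terminus uniformly over transcript positions. Fragmentation is modelled
as uniform; real benzonase digestion has sequence and length biases, but
only the 3'-end statistics matter downstream and those are preserved.
Each planted site is methylated in a given molecule with probability
equal to its *effective stoichiometry* in the simulated condition (its
planted fraction, zeroed when the site's guide snoRNA is not expressed
there).

Two chemical constraints shape the recorded ends:

1. **Cleavage is blocked 3' of a methylated ribose.** A molecule whose
   sampled terminus falls on a nucleotide that is methylated in that
   molecule is rejected — the phosphodiester bond could not have been
   cleaved there. This is the same chemistry that protects positions in
   the alkaline-fragmentation readout.
2. **Trimming stops at the first methylated nucleotide.** Oxidation
   removes unmethylated 3' nucleotides one at a time up to `trim_budget`
   (default 4: the protocol's four oxidation/beta-elimination cycles; the
   final blocking oxidation is modelled as discarding any terminus that
   is still unmethylated). The stopping position is the recorded 3' end.
   Unprotected molecules are discarded except with probability
   `background_end_rate` (default `1e-4`), a flat per-molecule spurious
   ligation with no sequence bias.

Together these rules imply the masking behaviour reported for tandem
(closely spaced) sites: with a fully methylated 3'-proximal ("distal")
partner, trimming from downstream always stops there, and direct
cleavage at the upstream site cannot occur, so the upstream site
receives *exactly zero* records. When the downstream site is partially
methylated the upstream count grows linearly with its unmethylated
fraction — for adjacent sites the expected upstream count is
`rate * trim_budget * (1 - f_dist)`, with `rate` the per-position
molecule rate. Both properties are asserted by the test suite.

Surviving records receive a uniformly random UMI (default 10 nt,
collisions allowed to occur naturally in the 4^10 space), a read length
(uniform 30–150 nt) and a mean base quality (uniform 25–40). Lengths and
qualities deliberately sit above the standard filter thresholds so the
filter does not thin simulated libraries; the filter's strict
inequalities are exercised on crafted records in the unit tests. Raw
FASTQ, sequencing error and alignment ambiguity are out of scope: the
simulator emulates the post-alignment record stream.

# Site calling and the Nm score

After strict quality filtering (`read_length > 20`, `mean_quality > 20`)
and exact-key UMI deduplication — one record per (contig, strand, 3'
end, UMI), first occurrence kept, no mismatch-tolerant network collapse
— deduplicated 3'-end counts are normalized as

```
nm_score = dedup_count * 2e7 / library_size
```

i.e. counts per 20 million deduplicated reads, reported to one decimal.
Under this normalization the conventional thresholds (scores of 500 for
candidate selection and 1000 for confident catalogues) correspond to
plausible absolute counts at the ~30 M-read depth of real libraries.
The scale is an explicit implementation convention of this package; the
literature uses the same score name without stating a formula.

`call_sites()` additionally requires local enrichment: the deduplicated
count must be at least `enrichment_fold` (default 10) times the median
count over the ±`flank` (default 50) nt window around the position,
with absent positions counted as zero and a zero median treated as one.
A bare score threshold would otherwise call plateau positions in very
highly expressed transcripts. Strands are never merged, coordinates are
0-based half-open everywhere, and ties in `top_k()` are broken by
(contig, position) so results are reproducible.

On the default recovery study — one 16 kb contig, five transcripts, 50
planted sites with stoichiometries uniform in [0.5, 1], per-position
molecule rate 75 (so every site expects at least 150 deduplicated
records), background rate 1e-4 — the caller reaches sensitivity and
precision 1.0 against the planted truth.

# MethScore

For the end-profile readout, the end sum at position *n* is
`S(n) = ends3(n) + ends5(n+1)`: both read-end categories created by
cleaving the bond 3' of *n*. The score compares `S(n)` with the
weighted mean end sum of the `flank = 2` positions on each side
(weights default to uniform; the convention in the literature mentions
weighting without stating weights). Two denominator conventions are
shipped because the customary description — dividing by *half* the
weighted flank mean — yields a raw score of −1 at unmethylated
positions:

* `literal` (the default, honouring that description):
  `raw = 1 − S(n) / (0.5 · mean_w(S_flank))`, clamped to [0, 1];
* `mean`: `raw = 1 − S(n) / mean_w(S_flank)`, which equals the
  protection fraction — and hence the methylation stoichiometry — under
  uniform cleavage.

The two raw scores obey `raw_literal = 2 · raw_mean − 1` exactly, so the
choice is a reporting convention, surfaced as a flag rather than decided
silently. Scores are undefined (NA) when every flank end sum is zero or
the window leaves the contig. Replicates are aggregated per position by
mean and sample standard deviation (3 replicates by default).

`simulate_ribometh()` draws both end categories as independent Poisson
counts with mean `depth × (1 − effective fraction)` at planted sites and
`depth` elsewhere. At depth 1000 with 3 replicates, mean-mode scores
recover planted fractions {0, 0.3, 0.7, 1} within ±0.05. The recovery
guarantee applies to isolated sites: a tandem partner inside the ±2
flank suppresses the local denominator and biases the score, which is a
faithful property of flank-normalized scoring, not an artefact of the
simulator.

# Canonical snoRNA guides and the D+5 rule

Box C/D snoRNAs are modelled by their RUGAUGA (box C family) and CUGA
(box D family) motifs: the 5'-most RUGAUGA is box C, the 3'-most CUGA is
box D, internal instances are C'/D' candidates, and the antisense
element (ASE) is the 10–15 nt ending immediately before box D (or D').
Duplexes between an ASE and a target window are scored additively over
the ungapped antiparallel alignment: Watson–Crick +2, G:U wobble +1,
mismatch −2. This deliberately replaces thermodynamic folding-energy
models: the scorer's role here is ranking and canonical filtering, its
values are not kcal/mol, and they are never compared with published
energies.

The targeting rule: the snoRNA nucleotide five positions upstream of the
first base of box D (counting the base immediately 5' of CUGA as one)
selects the paired target base as the methylated position. Worked
indices, for an ASE of length L ending at box-D offset `d` paired with a
plus-strand window starting at `t`: snoRNA offset `d−1` pairs `t`, so
offset `d−5` pairs `t+4`; on the minus strand the prediction mirrors to
`t+L−5`. `scan_targets()` slides each ASE over the ±7 nt region around
an observed site and keeps placements with at least 9 paired positions
(G:U counted), at most 2 mismatches, *and* a D+5 prediction equal to the
observed site exactly. The pairing thresholds are defaults consistent
with the 10–15 nt guide length, exposed in the configuration; published
catalogues filter on unstated score and plausibility cutoffs, so no
numeric equivalence is claimed. With these defaults, shuffled-ASE
decoys produce ~0–1 canonical matches per 100 scans.

`mfe_windows()` supports the noncanonical analysis (U3/U8/U13-style
complementarity): the best additive duplex score of any snoRNA
subsequence of at least 8 nt against the ±7 nt site window, with no
canonical-offset requirement, found by scanning anti-diagonals of the
pairing grid.

# Differential classification across the isogenic design

The four conditions model two wild-type/deletion pairs of neuronal
lines: CT2 and H9, each with an smDEL derivative lacking the paternal
SNORD116 cluster. The CT2-smDEL line additionally silences the
imprinted chr14q32 SNORD113/114 clusters, which the H9 background never
expresses — so SNORD113/114 guides are active in CT2 only, and SNORD116
guides in CT2 and H9.

`build_matrix()` marks a site *present* at score ≥ 500 and *absent* at
score ≤ 50 (10% of the presence threshold; the narrative treatment of
absence is visual, so the numeric rule and its ambiguous buffer are this
package's convention). Positions are compared at single-nucleotide
exactness on the same strand. Importantly, each condition is re-scored
at the *union* of called positions from its own deduplicated coverage:
a position that merely missed the calling threshold in one condition
must not be mistaken for absent. Patterns map to classes —
(P,A,A,A) → SNORD113114 candidate, (P,A,P,A) → SNORD116 candidate,
(P,P,P,P) → shared, (P,P,A,A)/(A,A,P,P) → cell-line specific — and any
row containing an ambiguous cell is left unclassified rather than
guessed. Candidate sites are then scanned for canonical guides
restricted to the matching snoRNA family, so a SNORD116-pattern site can
never be "explained" by an unrelated snoRNA; the best-scoring canonical
match is assigned. Replicate libraries are merged into one record
stream per condition before comparison.

On the default differential study (12 kb contig, 10 constitutive + 4
SNORD116 + 4 SNORD113/114 sites plus one adjacent tandem pair,
stoichiometries uniform in [0.3, 1], per-position rate ~30),
classification of non-ambiguous rows and guide assignment are both
exact. At this library scale a single spurious background record at a
site can exceed the presence threshold, because scores scale inversely
with the tiny library size; at realistic depths the same score
corresponds to hundreds of reads. This is the main caveat when reading
the synthetic guarantees across to real data.

# Metagene annotation and CLASH overlap

Transcript models come from GTF (exon/CDS features) or BED12 (blocks and
thick range); the generator's own models are single-exon with 5'UTR /
CDS / 3'UTR proportions 0.05 / 0.55 / 0.40 by default. Sites are
assigned to the region of an overlapping same-strand transcript; when
several overlap, the longest CDS wins (an explicit isoform policy, since
none is standard). The metagene coordinate is the region index plus the
fractional position within the region, binned 30 bins per region over
[0, 3). Each unique genomic site is counted once. CLASH chimera
fragments intersect sites on half-open intervals, strand-agnostic by
default because chimera strand conventions vary, with a strict-strand
flag.

# Numerical and reproducibility conventions

* Every stochastic function takes an explicit seed; sub-seeds for
  conditions and replicates are derived deterministically and kept well
  below 2^31. Fixed seed in, bit-identical output out.
* All file formats are plain text: FASTA, GTF (1-based on disk), BED /
  bedGraph (0-based half-open), TSV, YAML, JSON. The simulation manifest
  records md5 checksums, and simulation output is staged and renamed so
  a failing run leaves no partial files.
* Problem sizes in the tests and acceptance script — contigs of 2–30 kb,
  library depths of 1e4–8.4e5 molecules, 3 replicates — were chosen as
  the smallest studies at which the binomial/Poisson noise terms are
  comfortably inside the stated tolerances.

# Known limitations

* The simulator does not model sequence-biased fragmentation, ligation
  bias, PCR amplification structure (UMIs are attached post hoc), or
  alignment error; passing tests demonstrate correctness of the
  analysis logic under the stated generative model, not robustness to
  those real-data effects.
* The additive duplex scorer ignores RNA structure and accessibility;
  ranking agreement with thermodynamic tools is expected but not
  guaranteed.
* Presence/absence classification is qualitative by design; it does not
  test differential stoichiometry statistically.
* Scoreable MethScore positions require a full ±flank window inside the
  contig; contig edges are reported as missing rather than padded.
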