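---
title: "Methods: milRNA discovery from small-RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: milRNA discovery from small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milrseek)
```

## The problem

Fungi produce miRNA-like small RNAs (milRNAs): ~20-26 nt RNAs excised by
Dicer-like machinery from hairpin precursors. Unlike plant and animal
miRNAs they lack strong cross-species conservation, so discovery is
structural: candidate precursors are transcript regions that fold into a
stem-loop and accumulate small-RNA reads on both arms of one stem, with
the guide strand (milR) outnumbering the passenger strand (milR*).
`milrseek` implements this inference end to end for a two-state design --
liquid-cultured mycelium (MY) versus wild-type fruiting bodies (FB) --
together with the satellite analyses such studies report: conserved
miRNA annotation, RPKM differential expression, plant-style target
prediction, genomic-context classification, and a k-mer genome-size
estimate.

## Pipeline and models

### Read preprocessing

Reads are 3'-adapter trimmed, quality filtered, length filtered to
18-35 nt, and collapsed to unique sequences with per-library counts
("grouped sRNAs"). Every grouped sRNA carries a library class:
`M` (MY only), `F` (FB only), `B` (both).

Trimming truncates at the *leftmost* position where a prefix of the
adapter (>= 7 nt, <= 1 mismatch) begins; reads whose trimmed insert is
shorter than 18 nt are removed, and reads with no detectable adapter are
kept whole (synthetic inputs may legitimately lack adapters). A
consequence of the leftmost rule -- shared with real adapter trimmers --
is that an insert containing an adapter-like 7-mer is truncated and
effectively lost; the synthetic truth table accounts for this (below).
Quality filtering drops reads with mean Phred < 20 or any `N`. These
parameters are declared defaults in `milr_config()`, not inferences:
typical published pipelines name the goal ("high-quality clean reads")
but not the thresholds.

### Hairpin folding

Contigs are folded with a weighted Nussinov dynamic program maximizing
the pair sum GC = 3, AU = 2, GU = 1 under a minimum hairpin loop of 3 nt,
with a deterministic traceback (pairing preferred over leaving a base
unpaired; smallest partner index on ties), so identical input always
gives an identical dot-bracket. This is deliberately *not* a
thermodynamic model: the downstream candidate criteria depend only on
stem topology (which reads sit on which arm of which stem), which a
maximum-pairing structure supplies, and the weighted-pair objective is
exactly checkable against exhaustive enumeration on short sequences --
the folding test suite does precisely that. A thermodynamic folder can
be substituted via the `backend` argument of `fold_contigs()` behind the
same contract; all shipped tests pass under the built-in folder.

Contigs longer than 2,000 nt are folded in overlapping 700-nt windows
(step 350), since milRNA precursors are local hairpins and the cubic DP
cost must stay bounded. A *stem* is a maximal run of nested pairs merged
across bulges/internal loops of at most 3 nt per side; the 3-nt merge
tolerance is configurable because stem boundaries have no canonical
definition.

### Candidate calling

Grouped sRNAs are remapped onto the folded contigs: every ungapped,
full-length placement with at most `mismatch_max` mismatches is kept.
The default is 3 ("fewer than 4 mismatched nucleotides"); the looser
reading of 4 sometimes quoted for the remapping step is available as a
config override, but the stricter criterion is what the final filter
applies. A contig survives as a precursor candidate only if two
*distinct* sRNA sequences place on it -- a duplex needs two species, so
a single sequence placing at several offsets does not qualify.

Two placements form a duplex when (i) both are stem-located -- at least
half the read's bases are paired, and >= 60% of its paired bases belong
to one stem (the half-paired floor guards against loop-spanning reads);
(ii) they occupy opposite arms of that stem; and (iii) >= 50% of one
read's pairing partners fall inside the other read's interval extended
by 3 nt. In each duplex the read with the strictly larger total
(MY + FB) count is the milR, the other the milR*; equal counts discard
the duplex. Total rather than per-library counts are compared -- the
convention is declared (and configurable) because published criteria do
not specify it. When a read participates in several duplexes (error
variants at noisy settings), its reported role is taken from the duplex
with its highest-count partner: the planted guide still dominates its
star, and a star read that merely outnumbers some low-count variant is
not promoted to guide. milR* reads are reported with their role flagged
rather than dropped, since both arms of a locus are part of the
published output shape.

Reads on one arm whose 5' ends lie within 2 nt form a *locus family*
(isomiR-like 3' heterogeneity); accessions follow
`aci-milR-<locus><letter>-<k>`, with letters assigned along the
precursor (5' family first), variants numbered by descending count, and
suffixes dropped when unambiguous. A precursor's library class is the
union of its reads' classes.

### Conserved miRNA annotation

A grouped sRNA is annotated against a mature miRNA reference when an
ungapped alignment covers >= 18 nt with <= 2 mismatches *and* the sRNA
itself is stem-located on some folded contig; sequences sitting only on
loops or unstructured regions are not reported even at perfect identity.

### Differential expression

Expression is RPKM: `count * 1e9 / (lib_total * length_bp)`. The
two-library test models a gene's reads as a binomial split between
libraries with null proportion `total_MY / (total_MY + total_FB)` -- the
model class of count-based two-library tests -- using the exact
two-sided binomial p-value below 30 total reads and the normal
approximation above. FDR control is Benjamini-Hochberg (implemented
directly; the test suite cross-checks it against `stats::p.adjust`).
Differential expression requires FDR < 0.05 and an RPKM fold change
(FB/MY) >= 2 or <= 0.5. Genes with zero reads in one library and at
least 5 in the other are classed `MY_specific`/`FB_specific` *before*
the ratio rule, which avoids pseudocounts and division by zero; 5 is a
declared floor so that a single stray read does not create a
"specific" gene. The five classes partition all genes.

### Target prediction

Complementarity is scored with the plant-style expectation penalty: the
site is aligned to the reverse complement of the milRNA (at most 2 gaps)
and each milRNA position contributes 0 (match), 0.5 (G:U wobble), 1
(mismatch) or 2 (gap), doubled at positions 2-13 from the milRNA 5' end.
Hits require expectation <= 4.0. Only the best site per milRNA-unigene
pair is reported. Inhibition is `Translation` when any imperfection
falls at positions 9-11, else `Cleavage`. The weights and the central
rule are the standard psRNATarget/miRU convention, adopted explicitly
because a bare threshold of 4.0 is meaningless without its scoring
scheme; all weights live in `milr_config()`. One convention had to be
fixed for gaps: an unaligned *site* base is attributed to the milRNA
position of the adjacent aligned base on its 3' side (clamped at the 5'
end); the enumeration oracle in the tests implements the same
convention independently. The final cross-filter keeps a hit only when
the milRNA's library and the target's expression direction are opposed
(an M-class milRNA must hit a gene up in FB, and vice versa; B-class
accepts either), dropping targets without a differential-expression
call.

### Genomic context

Precursor regions (the minimal contig interval covering a precursor's
candidate reads) are located on scaffolds by exact match of the
sequence and its reverse complement -- precursors derive from the same
strain's transcripts, so mismatch-tolerant placement is out of scope.
Context precedence is exon before intron: opposite-strand exon overlap
is `exon_antisense` ("antisense frame" is read as opposite-strand
overlap, since reading-frame analysis is undefined for non-coding
placements), same-strand overlap `exon_sense`, then `intron`, else
`intergenic`; overlap means one shared base on 0-based half-open
intervals.

### Genome-size estimation

The k-mer spectrum estimator counts all k-mers (default k = 17), drops
multiplicities 1-2 (the error shoulder), smooths the multiplicity
histogram with a 5-wide running mean, and returns
`total_kmers / peak_depth`. The smoothing stabilizes the peak at desk
scale, where the raw mode of a near-Poisson spectrum wobbles by a few
units; without it the estimate can drift by ~5% on a 10-kb toy genome.

## The synthetic study

`synthetic_truth()` + `simulate_study()` generate a complete toy study
with a known answer: planted hairpin loci embedded in transcript
contigs, a two-scaffold genome placing each precursor in a stated
context (intergenic, intron, or antisense to an exon; all three always
present), two FASTQ libraries, a unigene panel with planted fold
changes and embedded target sites, a mature-miRNA reference carrying
two planted milRs under reference-style names (all sequences synthetic),
and a `truth.tsv`.

Defaults state the emulated world: milR lengths 20-26 nt peaking at
23 nt; 50% 5'-uracil bias; library classes drawn in roughly 13:46:4
M:F:B proportion with all classes forced present; milR* designed as the
near-reverse-complement of the milR with 0-2 non-pairing substitutions;
per-locus counts log-normal around ~60 with milR* at 5-40% of milR;
19-nt fixed 3' adapter, recorded in `truth.tsv` rather than hard-coded
downstream; per-base substitution error 0.01; 20% uniform random
background reads. Background is drawn uniformly rather than from the
genome so that truth evaluation stays unambiguous. Identical seeds give
byte-identical files.

What the generator does *not* emulate: colorspace reads, position-
dependent quality decay, ligation bias, expression-dependent 3'
heterogeneity, genome-derived degradation fragments, or read-level
RNA-seq simulation (unigene counts are drawn directly as Poisson
counts). A green recovery test therefore establishes that the inference
is correct on cleanly planted structure plus iid substitution noise --
not that it is robust to every artefact of a real sequencing run.

The truth table's `recoverable` flag marks loci the pipeline can be
expected to find: the designed duplex must survive folding of the full
contig (random flanks occasionally distort a hairpin), total milR count
must strictly exceed milR*, and the planted reads must survive adapter
trimming faithfully (an adapter-like 7-mer inside a planted insert
truncates its reads -- a property of the trimming rule, not a bug).
Recovery criteria are asserted against recoverable loci: 100% with
exact roles and classes at zero noise, and >= 90% on average across
seeds at the stated noise.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at file boundaries (GFF3 is 1-based inclusive on disk).
* RNA is the internal alphabet for sRNA/contig work (T mapped to U on
  input); genome scaffolds stay DNA.
* Grouped sRNAs sort by total count descending with lexicographic
  tie-break; all orderings in the pipeline are total, so outputs are
  reproducible byte for byte.
* Equal-count duplexes are discarded (strict inequality), zero-count
  genes get p = 1, empty inputs yield empty outputs rather than errors
  wherever an empty result is meaningful.
* The exact binomial p-value sums outcome probabilities not exceeding
  the observed one with a 1e-7 relative slack, matching
  `binom.test()`'s handling of floating-point ties.

## Limitations

The built-in folder ranks structures by weighted pair count, not free
energy; structures can differ from thermodynamic folders in
low-complexity regions (the pluggable backend exists for exactly that).
Candidate discovery is desk-scale: the mapper is an exact O(n*m) scan,
appropriate for thousands of grouped sRNAs against contig panels, not
for tens of millions of raw reads. Published headline counts from real
studies (clean-read totals, the exact number of candidates) depend on
proprietary preprocessing of archived libraries and are treated as
inputs or reference data, never as assertions the pipeline could
reproduce from scratch.
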