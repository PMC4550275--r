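---
title: "Screening transcriptomes for lcPUFA biosynthesis genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening transcriptomes for lcPUFA biosynthesis genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpufa)
```

## The problem

Marine molluscs can elongate and desaturate dietary C18 fatty acids into
omega-3 long-chain polyunsaturated fatty acids (lcPUFAs) such as EPA and DHA.
The enzymes responsible belong to two membrane-protein families: fatty acyl
desaturases (Fad), which introduce double bonds, and elongases of very
long-chain fatty acids (Elovl), which extend the carbon chain. Surveys of
these families in non-model species start from assembled transcriptome
contigs and must answer three questions per contig: does it encode a
full-length protein of the right family; is that protein structurally
plausible as a functional enzyme (as opposed to a pseudogenised or partial
copy); and where does it fall in the family phylogeny relative to
functionally characterised references (for example delta-5 desaturases, or
Elovl4/Elovl5 elongases)?

`lcpufa` implements that screen end to end as composable, tested functions:
contig merging and six-frame ORF extraction, degenerate-motif and
hydropathy-based structural filters, a conserved-residue checklist
transferred by global alignment, distance and likelihood phylogenetics with
bootstrap support, clone-versus-assembly validation arithmetic, and a
synthetic transcriptome generator that provides ground truth for every stage.

## The structural screen

A candidate contig passes through, in order:

1. **Length pre-filter.** Contigs shorter than 200 nt are dropped before ORF
   search (`min_contig_nt`, configurable).
2. **ORF extraction** (`find_orfs()`). All ATG-initiated reading frames on
   both strands; nested ORFs sharing a stop keep only the longest, matching
   standard ORF-finder behaviour. An ORF is *full length* for a family when
   its protein length falls in the family window — Fad 380–480 aa, Elovl
   230–340 aa, enclosing the 428–445 and 261–324 aa ranges observed for
   curated family members — and it terminates at a stop codon inside the
   contig.
3. **Fad structure** (`check_fad_structure()`). The haeme-binding motif HPGG
   within the N-terminal 80 residues (the motif sits inside the cytochrome
   b5-like domain, so its position proxies for the domain), the three
   histidine boxes HXXXH, HXXHH and QXXHH, their order along the sequence,
   and 3–4 transmembrane segments. Because every HXXHH window is also an
   HXXXH window, the first-box filter demands an HXXXH occurrence *distinct*
   from any HXXHH window; the ordering filter is evaluated over the boxes
   that are present. Together these choices make the filters separable: on a
   scaffold protein, deleting one motif flips exactly one filter, which the
   test suite asserts as a lesion–evidence bijection.
4. **Elovl structure** (`check_elovl_structure()`). The diagnostic HXXHH box,
   5–7 transmembrane segments, and a 17-residue conserved checklist
   (`125K, 128E, 131DT, 137L, 151HH, 178N, 182H, 185MY, 188YY, 208T, 250LF,
   254F` on the Elovl5 reference coordinate system; a token such as `131DT`
   denotes *consecutive* positions — the only reading under which the list
   totals 17). Checklist positions are transferred onto the candidate by
   global alignment; matches and conservative substitutions (S/T, L/V/I/A,
   F/Y, K/R, D/E, N/Q — generalising observed T→S, L→V and L→A exchanges at
   these sites) are accepted, and at most one non-conservative mismatch is
   tolerated, since curated family members occasionally carry a single
   substitution at a conserved site.
5. **Call assembly** (`classify_candidate()`). Full-length and all filters
   passed → `functional`; full-length with at least one failed structural
   filter → `putative_pseudogene`; no full-length ORF but a diagnostic motif
   (HPGG for Fad, HXXHH for Elovl) in some ORF → `partial`; otherwise
   `rejected`. If both family checks fully pass — which does not occur on
   realistic input — the family with more passing filters wins and an exact
   tie is rejected as ambiguous. Family assignment needs no similarity
   pre-screen because every contig is screened exhaustively; a BLAST-style
   pre-filter would only be a speed optimisation and is deliberately absent.

### Transmembrane counting without an HMM

Membrane topology predictors are external services; only the *count* of
membrane-crossing segments enters the screen (3–4 for Fad, 5–7 for Elovl).
The package therefore counts segments from a Kyte–Doolittle sliding-window
hydropathy profile (`tm_segments()`): window 19 (one membrane-crossing
helix), threshold 1.6, minimum segment length 19, merge gap 5. These defaults
follow common hydropathy-plot practice; raising the threshold on
well-separated stretches only removes segments, and on generator scaffolds
the detected count equals the planted count exactly. The scanner makes no
claim about topology (in/out orientation) or signal peptides. One caveat is
documented rather than hidden: with merging enabled, threshold monotonicity
is a property of well-separated hydrophobic stretches, not a theorem for
arbitrary profiles, so the suite asserts it on generator-style scaffolds.

## Alignment

Pairwise global alignment is affine-gap Needleman–Wunsch (Gotoh) with a
deterministic traceback (diagonal > up > left), BLOSUM62 for proteins and
+5/−4 for nucleotides, gap open 10 and extend 1 (a gap of length L costs
`gap_open + L * gap_extend`). The free-end-gap variant used for
clone-versus-assembly comparison treats gaps before the first or after the
last residue of either sequence as free; it stands in for the free-end-gap
"93% similarity" preset of interactive alignment tools, whose exact
parameters are not published — the preset here is documented, not asserted
as equivalent. The dynamic-programming core is compiled (Rcpp) and is checked
against exhaustive enumeration of all alignments on short sequences.

The multiple aligner (`progressive_msa()`) replaces meta-aligners with an
in-house progressive scheme: pairwise identity distances, a neighbor-joining
guide tree with deterministic tie-breaking, profile–profile merging in guide
order, and one leave-one-out refinement round kept only when it does not
lower the sum-of-pairs score. Published alignment-conservation counts from
curated family compilations depend on external database accessions and
manual editing, so the package treats conservation counting directionally:
`conserved_columns()` never increases when a divergent row is added, and
dropping the most divergent row (the outgroup analogue) never lowers the
count. Those invariants are tested; the printed counts themselves are not
reproduction targets.

## Phylogenetics

Distances implement the two named nucleotide models in closed form:

* Kimura 2-parameter: `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with P and Q
  the observed transition and transversion proportions;
* Tamura 3-parameter: `d = -h ln(1 - P/h - Q) - (1-h)/2 ln(1 - 2Q)` with
  `h = 2 theta (1 - theta)` and theta the G+C content (estimated from the
  pair by default). At theta = 0.5 it reduces exactly to K2P.

Saturated pairs yield `NA` rather than an error; neighbor joining drops the
most-NA label with a warning (conservative, since the source procedure is
silent on saturation). Tree search replaces a full ML implementation with a
desk-scale equivalent: NJ starting tree, Felsenstein pruning log-likelihood
under a K2P- or T92-style reversible rate matrix with an invariant-sites
class plus `ncat = 4` discrete-gamma categories (mean-normalised; shape and
invariant proportion are free configuration, as the source analyses do not
print them), and hill-climbing over nearest-neighbour interchanges with
branch lengths re-fit per topology by non-negative least squares against the
model distance matrix. The likelihood engine is validated three ways:
brute-force summation over internal-state assignments on small trees,
rooting invariance (the pulley principle), and agreement with an independent
phylogenetics library to 1e-8. Protein trees are supported through NJ on
alignment-derived distances only; an amino-acid likelihood model is out of
scope, keeping the likelihood engine nucleotide-only and enumerable.

Bootstrap support resamples alignment columns with replacement, rebuilds
with the supplied builder, and reports the percentage of replicates
containing each bipartition of the point tree; the reporting convention
suppresses values under 75%. Clade assignment roots at an explicit outgroup
leaf when given (else midpoint) and returns the label of the smallest
candidate-containing clade with at least one labelled reference, provided
the labels agree, the clade does not span the outgroup, and the subtending
support meets the threshold; edges without a numeric support annotation are
not used to withhold assignment.

## Clone validation arithmetic

`compare_orfs()` aligns a Sanger-style clone to the assembled coding sequence
with free end gaps, counts mismatch columns within the ORF span, classifies
each mismatch by translating both codons in the assembled frame, and reports
percent identity over the ORF length, rounded half-up to one decimal to match
printed-value conventions. The denominator is the ORF alignment span, not the
clone length, so UTR overhang never dilutes identity. Two worked examples
anchor the arithmetic: five synonymous substitutions across a 1293-nt ORF
give 99.6%, and one across a 293-codon (879-nt) ORF gives 99.9%. Two
documented wrinkles: a 432-aa protein strictly needs 1296 coding nt plus a
stop, so the 1293-nt/432-aa pairing reported for the merged desaturase
transcript is internally inconsistent — the package uses the printed 1293-nt
figure (431 codons) for the validation arithmetic and does not attempt to
reconcile the pair; and including the stop codon in the 879-nt example (882
nt) changes nothing at one-decimal precision. A third reported value (99.5%
with three synonymous substitutions over a 266-aa ORF) is not reproducible
from the printed lengths under this arithmetic, which gives 99.6%; it is
recorded as a discrepancy rather than targeted.

## The synthetic-data generator

No raw sequencing data ships with the package; the generator
(`make_transcriptome()`) is the statistical stand-in, and it is first-class,
tested code. Each planted gene is a scaffold protein with the family's
architecture at fixed coordinates — for Fad: HPGG at 25, HXXXH at 120, HXXHH
at 155, QXXHH at 360 (drawn from the observed consensus variants HDF/YGH,
HY/FQ/LHH, QI/VEHH), 3–4 hydrophobic 21-mers from position 190; for Elovl:
the HVF/YHH box at 148 (so its terminal HH coincides with checklist
positions 151–152), the 17 checklist residues at their reference
coordinates, and 5–6 hydrophobic 21-mers. Hydrophobic stretches draw from
{L,I,V,F,A} and linkers from {E,K,R,D,N,S,G}: the pools guarantee
Kyte–Doolittle separation beyond the detection threshold, and the linker
pool excludes H, P and Q so motifs occur only where planted. Family members
are generated as homologs: each gene diverges from a canonical per-family
backdrop at 15% of positions, giving roughly 85–90% identity — realistic for
congeneric paralogs and enough signal for the alignment and checklist
transfer stages. Coding sequences are back-translated with uniform synonymous
codon choice (the simplest defensible model; a codon-usage hook is left as a
parameter), flanked by UTRs whose 5' side ends in an in-frame stop so the
planted ORF coordinates are exact, and placed on a random strand.

Lesions produce the other truth classes: deleting HPGG or scrambling a
diagnostic box yields full-length putative pseudogenes that fail exactly one
filter; truncating the contig inside the ORF yields partials; a frameshift's
expected status is derived at generation time from the realised ORF geometry
(window membership, stop presence, retained motif evidence) using only
low-level primitives, never the screen itself. Decoy contigs are i.i.d.
uniform nucleotides with lengths drawn from the planted records, so length
alone cannot separate classes. Clone pairs plant exactly `n` substitutions
drawn from third-position synonymous degeneracy (or forced nonsynonymous),
and `simulate_alignment()` evolves gap-free alignments down a tree under the
K2P/T92 transition probabilities with the invariant/gamma rate mixture.

What passing tests on this generator do and do not show: they demonstrate
that the screen's logic is sound — 100% recovery of planted genes with
correct family and status, zero functional calls on decoys, exact
planted-SNP ledger recovery — under data whose motifs, hydropathy contrast
and homology structure are idealised. Real transcriptomes add assembly
chimeras, allelic variation, sequencing error, and family members whose
hydropathy or motif spacing deviates from the scaffold; the thresholds are
configurable precisely because those realities require tuning that synthetic
data cannot supply.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: brute-force
alignment enumeration up to 8 residues, likelihood enumeration up to 5 taxa,
two-taxon distance recovery at 10,000 sites (the K2P estimator's standard
error at d = 0.2 is about 0.005, so a 3-s.e. band is decisive), 6-taxon
simulations at 2,000 sites with 200 bootstrap replicates, and recovery runs
of 10 planted genes plus decoys per seed across at least five seeds. The
pipeline default for bootstrap replicates is 1,000, the convention for
published family surveys. Floating-point ties in the alignment traceback are
broken deterministically (diagonal > up > left); guide-tree and NJ joins
break ties by label order; every stochastic function takes an explicit seed
and the pipeline records its configuration hash, so identical configuration
reproduces identical reports byte for byte.

## Known limitations

* The Elovl reference protein shipped with the package is a synthetic
  scaffold carrying the checklist residues at their reference positions, not
  the database Elovl5 protein; screening real data should substitute a real
  annotated reference via `default_refs()`.
* The hydropathy scanner is not an HMM; proteins with marginal or
  re-entrant helices can be miscounted, which is why the windows (3–4, 5–7)
  rather than exact counts enter the filters.
* The likelihood engine is nucleotide-only; protein trees use NJ on
  alignment-score distances.
* Merging accepts only exact overlaps (default 15 nt), by design: fuzzy
  merging risks chimeric transcripts.
* Published per-species gene counts and tree figures depend on external
  accessions and manual curation and are outside what the synthetic
  conditions can or should reproduce.
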