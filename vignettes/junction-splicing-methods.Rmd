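---
title: "Junction-read splicing analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-read splicing analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionASE)
library(data.table)
```

## Why junction reads

5' single-cell RNA-seq has strongly biased read coverage along genes, so
any quantification that depends on read depth across an exon body (and
hence on length normalization) is unreliable.  Exon-exon junction reads
side-step this: the inclusion and the exclusion isoform of an alternative
splicing event (ASE) are each supported by reads crossing specific splice
junctions, the two junction classes sit at comparable distances from the
5' end, and the resulting counts are clean binomial pairs.  `junctionASE`
therefore detects and quantifies ASEs exclusively from reads containing a
reference skip, with one exception: intron retention, where the inclusion
(retaining) isoform has no junction and is instead supported by non-gapped
reads that span an exon-intron boundary contiguously.

Molecules, not reads, are the unit of evidence in single-cell mode: all
reads sharing a cell barcode and UMI are merged, and a molecule supports a
junction at most once.  Bulk mode skips this step.  Reference skips
shorter than 20 nt are treated as deletions, and only primary alignments
are counted; both choices are conventions of splice-aware aligners rather
than results of this method.

## Event detection and classification

Junctions passing a minimum-support filter (default 10 molecules; 5 for
low-coverage per-cell-type work) are grouped by shared splice positions.
A junction J acts as an exclusion junction; junctions nested strictly
inside J's intron sharing its start or end are inclusion candidates, and
when more than two share a position only the top two by count are kept
(ties: smaller intron, then leftmost).  Shared start *and* end with an
exonic gap gives a cassette exon (CE); one-sided sharing is classified
against annotated transcript structures:

* both alternative boundaries at non-overlapping annotated **first** exons
  → AFE (alternative promoter); at last exons → ALE.  The proximal
  junction — the nested, shorter intron — is the inclusion isoform.
* both at annotated donors (acceptors) of overlapping exons → A5SS (A3SS),
  named on the gene strand.
* no transcript linkage → UN; linkage to two genes → UN with a flag.

The overlap requirement on A5SS/A3SS exons is what separates genuine
alternative donors/acceptors from the junction signature of mutually
exclusive exons, whose alternative exons are disjoint.  MXE and IR are not
reliably detectable from junction patterns alone, so both are taken from
annotation: an IR event is an intron of one transcript that is fully
exonic in another transcript of the same gene; an MXE is a pair of
internal exons that share flanking exons and never co-occur.  Junction
candidates whose junctions are fully explained by an annotated MXE are
suppressed in favour of the annotation-defined event.  Novel events in
immunoglobulin, T-cell-receptor and HLA loci are discarded (DNA
recombination and mapping artifacts), known events are kept.

An event is `known` only when every junction it uses is an annotated
intron.  The primary annotation wins over an assembled one whenever both
explain an event.

## PSI and its exact interval

For inclusion count I and exclusion count E, PSI = I/(I+E).  For CE the
inclusion junction with the larger *pooled* count is used for every cell —
a per-cell choice would make PSI incomparable across cells.  For IR the
per-cell inclusion count is the maximum of the two boundary-span counts.
Aggregation sums counts and PSI is always recomputed from sums; per-cell
PSIs are never averaged.  The 95% interval is the exact Clopper-Pearson
interval (the interval of `binom.test`), computed from beta quantiles; it
is conservative by construction, which the coverage test verifies.

## Empirical-Bayes inferred PSI

For embedding, counts are aggregated per sample x cell type and filtered
(defaults: at least 1e6 junction reads per sample, at least 5000 per
sample-cell-type, event detected in at least 80% of units).  Each event's
PSI across units is modelled as Beta(a, b) with beta-binomially
distributed counts; (a, b) is fitted by direct maximization of the
beta-binomial likelihood from a method-of-moments start, with shapes
bounded to (1e-3, 1e6) — degenerate events pinned at 0 or 1 clamp at the
bound and are flagged.  The posterior for a unit is Beta(a+I, b+E) and its
median (`qbeta(0.5, ...)`) is the inferred PSI; zero-coverage units
receive the prior median, so the matrix has no missing values.  The
permutation null redraws I' ~ Binomial(I+E, p ~ Beta(a, b)) per unit,
destroying splicing-ratio information while preserving every coverage
total exactly; priors are not refitted on permuted data.  Reading the
permutation as a beta-binomial redraw (rather than a rounded beta draw)
keeps counts integral and totals fixed by construction.

## Differential splicing

Events pass a coverage filter (pooled I >= 10, pooled E >= 10, each
group's junction total >= 10) and a four-condition noise filter on the
groups' Clopper-Pearson bounds requiring that neither isoform is splicing
noise in both groups.  The test compares nested binomial GLMs with logit
link on per-sample (I, E) rows — `(I, E) ~ sample + group` against
`(I, E) ~ sample` (or `~ group` vs intercept-only without the covariate) —
by likelihood-ratio test with df = 1 for a two-level group, BH-corrected.
An event is *specific* when FDR < 0.01 and |dPSI| > 0.2, with dPSI from
pooled counts per group.  Complete separation (a group entirely at PSI 0
or 1) is handled by adding 0.5 to every cell of that event and flagging
the result rather than failing silently.  Samples with zero coverage for
an event are dropped from that event's regression.

Enrichment of specific-ASE genes against nonspecific-ASE background genes
uses one-tailed Fisher tests per gene set after down-sampling the
background within expression deciles to match the test genes' expression
distribution, BH at FDR < 0.05.

## T-cell indices

The splicing distance between two subtypes rescales each shared event's
two PSIs linearly onto [0.01, 0.99] (the affine map keeping the logit
finite at boundary PSIs), logit-transforms them, and takes the Euclidean
norm of the difference; events need at least 5 reads in both subtypes.
The similarity score places a sample between two subtype anchor PSIs per
event: 0 at or beyond the A anchor, 1 at or beyond the B anchor, linear
between, oriented per event toward the B anchor (so relabelling the axis
maps S to 1-S).  The sample score is the mean over axis events with at
least 5 reads; samples where more than one third of axis events fall
below that floor are excluded.  Anchor PSIs are pooled across samples,
treating them as subtype properties.

## Antigen chain

Candidate events are gated per cell type (I >= 5, E >= 5, both CI bounds
inside (0.05, 0.95)).  An isoform side is *atypical* when its proportion
is at least 10x the normal-tissue mean and its CI lower bound at least 4x
the proportion in every individual normal tissue; the cancer-versus-stroma
step relaxes this to 5x the stromal mean and 2x every patient's stromal
proportion (allowing for doublet contamination), plus strict
undetectability — zero supporting reads — in the tissue-of-origin
reference.  Eligible types are CE, A5SS, A3SS and IR within coding
regions.  NMD is predicted on the isoform that differs from the
representative transcript (the linking transcript with the longest CDS —
the most conservative premature-stop context) by the 50-nt rule: decay is
predicted when translation stops more than 50 nt upstream of the final
exon-exon junction of that isoform.  NMD-positive candidates are excluded.
Surviving isoforms are translated; 8-11-mers present in the atypical
protein but absent from the normal isoform's protein and from the
reference proteome are scored with an *external* MHC predictor's %rank
table (the predictor is a pluggable interface, never re-implemented);
the strongest rank over up to six patient alleles decides strong binding
at %rank < 0.5.  The tumor antigen burden of a sample is the sum over
strong binders of atypical proportion x gene CPM in cancer cells
(CPM = 1e6 x gene count / library total).  When both sides of an event
pass the filters, both become candidates with distinct event-side keys.

## The synthetic study design

All tests run on a self-contained fixture
(`generate_genome_and_annotation`, `simulate_reads`,
`generate_references`): a ~100 kb single-chromosome genome whose 2 kb
windows hold genes realising every event type — an in-frame CE, a
frameshifting CE engineered as a canonical 50-nt-rule NMD target (a stop
codon planted in the shifted frame, harmless in the annotated frame), a
frameshifting CE whose premature stop falls in the last exon, a CE in the
3' UTR, A5SS, A3SS, AFE, ALE (on the minus strand), an annotation-defined
MXE and IR, an unannotated junction pair (UN), a single-isoform filler
gene carrying background reads, and constitutive two-exon genes.  Coding
sequences are written as stop-free codons and verified by translation.

The default design is 4 samples x 2 cell types (T cell, cancer) x 25
cells, 10 molecules per event per cell, with planted PSIs per cell type;
four events differ between the cell types by at least 0.3 (the
cancer-specific set), and two isoform sides (the A5SS exclusion and the
IR retention) are planted as cancer-only antigen candidates.  In `exact`
mode molecule counts are deterministic (`round(m * psi)`), isolating
correctness from sampling; `sampled` mode draws binomially for
calibration tests.  Each molecule emits 1-3 duplicate reads sharing its
barcode and UMI, so deduplication is always exercised; background read
starts decay geometrically with a configurable 5' bias.  Normal-tissue
references express only the normal isoform apart from a configurable
contamination fraction, the proteome holds all annotated proteins, and
the MHC rank table marks three designated peptides per candidate as
strong binders — standing in for an external predictor's output.

What the fixture does *not* emulate: sequencing errors, barcode
collisions, multi-mapping, expression heterogeneity between cells,
overlapping genes and soft-clipped alignments.  Passing tests therefore
demonstrate algorithmic correctness under clean alignments, not
robustness to upstream alignment artifacts.

## Numerical choices and problem sizes

* Posterior medians and Clopper-Pearson bounds come from `qbeta`; the test
  suite checks them against bisection of the beta CDF to 1e-9/1e-10.
* Beta-binomial optimization works on log-shape scale with L-BFGS-B.
* Event ids are deterministic strings of (type, chromosome, exclusion
  intron, sorted inclusion coordinates), stable across runs and samples.
* Deterministic tie-breaks throughout: top-two junction selection and the
  CE counting junction prefer higher count, then smaller intron, then
  leftmost coordinate.
* Simulation sizes in the tests and the acceptance script (200 cells, 200
  events for GLM calibration, 50 units for prior recovery, 1e4 draws for
  coverage) were chosen as the smallest sizes at which the statistical
  properties under test are stable.

## Known limitations

Multi-exon-skipping cassettes are emitted as the maximal event plus any
nested events that independently pass the filters, deduplicated by id.
AFE events whose two first exons straddle the shared exon at exactly equal
distance cannot be oriented and are flagged rather than decided.  The GLM
stage models no extra-binomial dispersion by design; the beta-binomial
machinery is reserved for the embedding prior.  Annotation-free IR and
MXE detection is out of scope, as is everything upstream of a
coordinate-sorted, tagged BAM (alignment, barcode correction) and the MHC
binding predictor itself.
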