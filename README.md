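# junctionASE

Junction-read based detection, classification and quantification of
alternative splicing events (ASEs) in cell-barcoded, UMI-tagged RNA-seq
alignments — built for 10x Genomics 5' single-cell data, with a bulk mode
that skips UMI deduplication — plus the downstream statistics that turn
those counts into biology: Bayesian inferred-PSI embedding, binomial-GLM
differential splicing, T-cell splicing distance/similarity indices, and a
tumor-antigen prioritization chain ending in the splice-derived tumor
antigen burden (ATB).

## Who this is for

Anyone who wants to study alternative splicing in 5' single-cell RNA-seq,
where read coverage decays along the gene body and exon-body quantification
is unreliable.  The package works exclusively from exon-exon junction reads
(plus exon-intron boundary-spanning reads for intron retention), which sit
at comparable distances from the 5' end for both isoforms of an event and
yield clean binomial count pairs.

## The model in brief

For an event with inclusion count *I* and exclusion count *E* (deduplicated
molecules per cell),

* **PSI** = *I* / (*I* + *E*), with the exact two-sided 95%
  Clopper–Pearson interval;
* seven event types are called — CE, AFE, ALE, A5SS, A3SS, MXE, IR — plus
  UN for junction pairs not linkable to any transcript; MXE and IR are
  annotation-defined, the rest are junction-defined;
* per-event priors PSI ~ Beta(a, b) are fitted across sample × cell-type
  aggregates by beta-binomial maximum likelihood; the posterior median of
  Beta(a+I, b+E) is the inferred PSI used for PCA/tSNE, and a permutation
  null redraws I' ~ Binomial(I+E, p ~ Beta(a, b)) to destroy splicing
  information while preserving coverage;
* differential splicing compares nested binomial GLMs
  (*I*, *E*) ~ sample + group vs (*I*, *E*) ~ sample by likelihood-ratio
  test, BH-corrected; *specific* means FDR < 0.01 and |ΔPSI| > 0.2;
* atypical isoforms are called against normal references (≥10× the
  normal-tissue mean proportion, CI lower bound ≥4× every individual
  tissue; 5×/2× against stroma), filtered by the 50-nt NMD rule,
  translated into proteome-unique 8–11-mers, scored with an external MHC
  %rank table (strong binder: %rank < 0.5), and summed into
  ATB = Σ proportion × gene CPM.

## Worked example

Everything below runs on the package's own synthetic fixture — a ~100 kb
toy genome with one planted event of every type and a ground-truth
manifest — so it works offline in seconds.

```r
library(junctionASE)
library(data.table)

fx   <- generate_genome_and_annotation(seed = 1)   # genome + GTF + manifest
sim  <- simulate_reads(fx, seed = 1)               # tagged, sorted BAM
jx   <- extract_junctions(sim$bam)                 # UMI-deduplicated junctions
idx  <- build_boundary_index(fx$models)
ev   <- detect_events(jx, idx, min_reads = 10, genome = fx$genome)
ev[, .N, by = as_type]
#>    as_type     N
#> 1:      CE     4
#> 2:     AFE     1
#> 3:     ALE     1
#> 4:    A5SS     1
#> 5:    A3SS     1
#> 6:     MXE     1
#> 7:      IR     1
#> 8:      UN     1
```

Eleven events: four cassette exons (in-frame, NMD frameshift, non-NMD
frameshift, 3' UTR), one of each other type, and one unannotated (UN)
junction pair.  Counting and PSI:

```r
cnt <- count_events(ev, jx)     # per-cell (I, E); spans needed for IR
compute_psi(7L, 3L)
#>        I     E   psi    ci_low   ci_high
#> 1:     7     3   0.7 0.3475471 0.9332605
```

PSI 0.7 with an exact interval (0.35, 0.93): ten molecules cannot pin an
isoform ratio tightly, which is exactly why the downstream tests work on
counts, never on point estimates.  A differential comparison of the two
planted cell types flags precisely the events planted with ΔPSI > 0.2:

```r
units <- sim$truth[, .(I = sum(I), E = sum(E)),
                   by = .(event_id, sample_id, group = cell_type)]
res <- diff_splicing(units, min_total = 10)
res[specific == TRUE, .(event_id, delta_psi = round(delta_psi, 2), fdr)]
#>                           event_id delta_psi           fdr
#> 1:   A5SS:chrT:6201-6400:6260-6400      -0.5 2.274142e-130
#> 2:    AFE:chrT:2201-3000:2801-3000       0.4  4.085810e-73
#> 3: CE:chrT:201-500:201-300|391-500       0.6 1.211382e-168
#> 4:          IR:chrT:12201-12240:.        0.4  6.054822e-90
```

The sign of ΔPSI is first group level minus second (here cancer minus
T cell): the CE at +0.6 is the planted cassette whose inclusion is 0.8 in
cancer cells and 0.2 in T cells; exactly the four events planted with
|ΔPSI| > 0.2 are flagged, at vanishing FDR because the fixture counts are
noise-free.

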