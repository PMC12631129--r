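test_that("atypical calling evaluates both stated inequalities", {
  # cancer proportion 0.4 (CI low ~0.34 at n=250) vs normals at ~0.02
  cancer <- data.table(event_id = "e1", I = 100L, E = 150L)
  normals <- CJ(tissue = sprintf("t%d", 1:4), event_id = "e1")
  normals[, `:=`(I = 4L, E = 196L)]                    # inclusion prop 0.02
  hit <- call_atypical_vs_normal(cancer, normals)
  expect_equal(hit[side == "inclusion", event_id], "e1")
  # one normal tissue at 0.1 breaks the 4x lower-bound rule
  normals2 <- copy(normals)
  normals2[tissue == "t1", `:=`(I = 20L, E = 180L)]
  hit2 <- call_atypical_vs_normal(cancer, normals2)
  expect_equal(nrow(hit2[side == "inclusion"]), 0L)
  # degenerate folds with silent normals accept every gated event
  normals0 <- copy(normals)[, `:=`(I = 0L, E = 200L)]
  hit3 <- call_atypical_vs_normal(cancer, normals0, fold_mean = 1,
                                  fold_max = 1)
  expect_equal(hit3[side == "inclusion", event_id], "e1")
})

test_that("the detectability gate enforces counts and CI noise bounds", {
  normals <- CJ(tissue = "t1", event_id = c("lowI", "noisy", "ok"))
  normals[, `:=`(I = 0L, E = 200L)]
  cancer <- data.table(event_id = c("lowI", "noisy", "ok"),
                       I = c(4L, 6L, 80L), E = c(300L, 6L, 160L))
  hit <- call_atypical_vs_normal(cancer, normals)
  # lowI fails I >= 5; noisy at n = 12 has a wide CI crossing 0.95? its CI
  # is (0.21, 0.79) so it passes the gate; ok passes everything
  expect_true("ok" %in% hit$event_id)
  expect_false("lowI" %in% hit$event_id)
  # relaxing folds never shrinks the atypical set (monotonicity)
  strict <- call_atypical_vs_normal(cancer, normals, fold_mean = 10, fold_max = 4)
  lax <- call_atypical_vs_normal(cancer, normals, fold_mean = 2, fold_max = 1)
  expect_true(all(paste(strict$event_id, strict$side) %in%
                  paste(lax$event_id, lax$side)))
})

test_that("stromal comparison and origin-reference undetectability gate candidates", {
  cand <- data.table(event_id = "e1", side = "inclusion", proportion = 0.5,
                     ci_low = 0.4, mean_normal = 0, max_normal = 0)
  cancer <- data.table(event_id = "e1", I = 125L, E = 125L)  # CI low ~0.44
  stroma <- data.table(patient = c("p1", "p2"), event_id = "e1",
                       I = c(5L, 10L), E = c(95L, 90L))
  keep <- call_tumor_specific_vs_stroma(cand, cancer, stroma)
  expect_equal(nrow(keep), 1L)
  # a stromal proportion of 0.3 in one patient violates the 2x CI rule
  stroma2 <- copy(stroma)[patient == "p2", `:=`(I = 30L, E = 70L)]
  expect_equal(nrow(call_tumor_specific_vs_stroma(cand, cancer, stroma2)), 0L)
  # any atypical-side reads in the origin reference disqualify
  origin_clean <- data.table(tissue = "o1", event_id = "e1", I = 0L, E = 200L)
  origin_dirty <- data.table(tissue = "o1", event_id = "e1", I = 3L, E = 197L)
  expect_equal(nrow(call_tumor_specific_vs_stroma(cand, cancer, stroma,
                                                  origin_clean)), 1L)
  expect_equal(nrow(call_tumor_specific_vs_stroma(cand, cancer, stroma,
                                                  origin_dirty)), 0L)
})

test_that("atypical peptides are unique k-mers absent from the proteome", {
  fx <- get_fixture(); ch <- get_chain(); refs <- get_refs()
  for (k in unique(refs$designated$event_id)) {
    ev <- ch$events[event_id == k]
    side <- refs$designated[event_id == k, atypical_side][1]
    peps <- translate_atypical(ev, side, ch$idx, fx$genome, refs$proteome)
    expect_gt(length(peps), 0L)
    expect_true(all(nchar(peps) %in% 8:11))
    # none is a substring of any reference protein (exhaustive re-check)
    for (p in peps)
      expect_false(any(vapply(as.character(refs$proteome), grepl,
                              TRUE, pattern = p, fixed = TRUE)))
    expect_true(all(refs$designated[event_id == k, peptide] %in% peps))
  }
  # NMD-positive and wrong-type events are refused
  nmd_ev <- ch$events[nmd == TRUE][1L]
  expect_error(translate_atypical(nmd_ev, "exclusion", ch$idx, fx$genome,
                                  refs$proteome), "NMD")
  afe <- ch$events[as_type == "AFE"][1L]
  expect_error(translate_atypical(afe, "inclusion", ch$idx, fx$genome,
                                  refs$proteome), "not eligible")
})

test_that("peptide k-mer sets equal brute-force enumeration over both proteins", {
  fx <- get_fixture(); ch <- get_chain(); refs <- get_refs()
  k <- refs$designated$event_id[1]
  ev <- ch$events[event_id == k]
  side <- refs$designated[event_id == k, atypical_side][1]
  peps <- translate_atypical(ev, side, ch$idx, fx$genome, refs$proteome)
  # rebuild both proteins through the package, then enumerate naively
  models <- fx$models
  rep_tx <- models$transcripts[gene_id == ev$gene_id &
                               frame_ok == TRUE][order(-cds_len)][1L]
  rep_exons <- junctionASE:::.rep_chain(models, rep_tx$transcript_id)
  cds <- models$cds[transcript_id == rep_tx$transcript_id]
  chains <- junctionASE:::.event_isoform_chains(ev, rep_exons)
  tr <- function(s) junctionASE:::.translate_event_chain(
    chains[[s]], min(cds$start), "+", fx$genome, ev$chrom)$aa
  atyp <- tr(side); norm <- tr(setdiff(c("inclusion", "exclusion"), side))
  bf <- setdiff(bf_kmers(atyp), bf_kmers(norm))
  bf <- bf[!vapply(bf, function(p) any(vapply(as.character(refs$proteome),
    grepl, TRUE, pattern = p, fixed = TRUE)), TRUE)]
  expect_setequal(peps, sort(bf))
})

test_that("MHC rank attachment picks the strongest binder", {
  rt <- data.table(peptide = c("PEPTIDEONE", "PEPTIDEONE", "PEPTIDETWO"),
                   allele = c("A1", "A2", "A1"),
                   percent_rank = c(1.2, 0.3, 5))
  r <- attach_mhc_ranks(c("PEPTIDEONE", "PEPTIDETWO"), rt, c("A1", "A2"))
  expect_equal(r$best_percent_rank, 0.3)
  expect_true(r$strong)
  r2 <- attach_mhc_ranks("PEPTIDETWO", rt, c("A1", "A2"))
  expect_false(r2$strong)
  # restricting alleles changes the minimum
  r3 <- attach_mhc_ranks("PEPTIDEONE", rt, "A1")
  expect_equal(r3$best_percent_rank, 1.2)
  expect_false(r3$strong)
  expect_warning(attach_mhc_ranks("ABSENT", rt, "A1"), "non-binders")
  expect_error(attach_mhc_ranks("PEPTIDEONE", rt, character(0)), "allele")
})

test_that("ATB is the sum of proportion x CPM over strong binders and is linear", {
  cand <- data.table(event_id = c("e1", "e2", "e3"),
                     gene_id = c("g1", "g2", "g3"),
                     side = "inclusion",
                     proportion = c(0.2, 0.5, 0.9),
                     strong = c(TRUE, TRUE, FALSE))
  cpm <- data.table(gene_id = c("g1", "g2", "g3"), cpm = c(50, 10, 100))
  r <- compute_atb(cand, cpm)
  expect_equal(r$atb, 0.2 * 50 + 0.5 * 10)
  expect_equal(sum(r$contributions$abundance), r$atb)
  # linear in CPM
  cpm2 <- copy(cpm)[, cpm := cpm * 3]
  expect_equal(compute_atb(cand, cpm2)$atb, 3 * r$atb)
  # no strong binders: zero burden
  none <- copy(cand)[, strong := FALSE]
  expect_equal(compute_atb(none, cpm)$atb, 0)
  # missing expression contributes zero with a warning
  expect_warning(r3 <- compute_atb(cand, cpm[gene_id != "g2"]), "missing")
  expect_equal(r3$atb, 0.2 * 50)
})

test_that("the antigen chain recovers exactly the designated fixture candidates", {
  fx <- get_fixture(); sim <- get_sim(); ch <- get_chain(); refs <- get_refs()
  cells <- sim$cells
  cnt <- merge(ch$counts, cells, by.x = "cell", by.y = "cell_barcode")
  cancer <- cnt[cell_type == "cancer", .(I = sum(I), E = sum(E)), by = event_id]
  stroma <- cnt[cell_type == "T_cell",
                .(I = sum(I), E = sum(E)), by = .(patient = sample_id, event_id)]
  at <- call_atypical_vs_normal(cancer, refs$normal_counts)
  ts <- call_tumor_specific_vs_stroma(at, cancer, stroma, refs$origin_counts)
  expect_setequal(paste(ts$event_id, ts$side),
                  unique(paste(refs$designated$event_id,
                               refs$designated$atypical_side)))
  # contamination past the 4x bound removes the affected events
  refs_dirty <- generate_references(fx, contamination = 0.2, seed = 1)
  at2 <- call_atypical_vs_normal(cancer, refs_dirty$normal_counts)
  expect_equal(nrow(at2), 0L)
  # ATB equals the analytic value from the manifest proportions
  ev_gene <- ch$events[, .(event_id, gene_id)]
  strong <- merge(ts, ev_gene, by = "event_id")
  strong[, strong := TRUE]
  # gene CPM in one sample's cancer cells from the truth molecule counts
  s1 <- sim$truth[sample_id == "S1" & cell_type == "cancer",
                  .(n = sum(I + E)), by = event_id]
  s1 <- merge(s1, ev_gene, by = "event_id")
  gc <- s1[!is.na(gene_id), .(count = sum(n)), by = gene_id]
  cpm <- compute_cpm(gc)
  atb <- compute_atb(strong, cpm)
  tot <- sum(gc$count)
  manifest_expect <- sum(vapply(seq_len(nrow(strong)), function(i) {
    ev <- fx$manifest$events[[strong$event_id[i]]]
    p <- if (ev$atypical_side == "inclusion") ev$psi[["cancer"]]
      else 1 - ev$psi[["cancer"]]
    gene_n <- s1[gene_id == ev$gene_id, sum(n)]
    p * 1e6 * gene_n / tot
  }, 0))
  expect_equal(atb$atb, manifest_expect, tolerance = 1e-12)
  # and the observed proportions equal the planted cancer-side proportions
  for (i in seq_len(nrow(strong))) {
    ev <- fx$manifest$events[[strong$event_id[i]]]
    p_true <- if (ev$atypical_side == "inclusion") ev$psi[["cancer"]]
      else 1 - ev$psi[["cancer"]]
    expect_equal(strong$proportion[i], p_true, tolerance = 1e-12)
  }
})
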