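test_that("textbook cassette and single-side candidates are paired correctly", {
  # junctions (100-500) with (100-300) and (400-500): one CE candidate
  tot <- data.table(chrom = "chr1",
                    start = c(100L, 100L, 400L),
                    end = c(500L, 300L, 500L),
                    total = c(50L, 30L, 30L))
  cand <- detect_junction_events(tot)
  ce <- cand[shared == "both"]
  expect_equal(nrow(ce), 1L)
  expect_equal(ce$i1_end, 300L)
  expect_equal(ce$i2_start, 400L)
  # with only the shared-start junction: one single-side candidate
  cand2 <- detect_junction_events(tot[1:2])
  expect_equal(cand2$shared, "start")
  expect_equal(cand2$i1_end, 300L)
  # an ungrouped junction alone yields nothing
  expect_equal(nrow(detect_junction_events(tot[1])), 0L)
})

test_that("only the top two junctions per shared splice position are kept", {
  tot <- data.table(chrom = "chr1",
                    start = rep(100L, 5L),
                    end = c(900L, 300L, 400L, 500L, 600L),
                    total = c(99L, 50L, 40L, 30L, 20L))
  cand <- detect_junction_events(tot)
  kept <- cand[excl_end == 900L, sort(unique(i1_end))]
  expect_equal(kept, c(300L, 400L))     # counts 50 and 40 survive
  # equal counts: smaller intron, then leftmost wins
  tot2 <- data.table(chrom = "chr1", start = rep(100L, 4L),
                     end = c(900L, 300L, 400L, 500L),
                     total = c(99L, 30L, 30L, 30L))
  cand2 <- detect_junction_events(tot2)
  expect_equal(cand2[excl_end == 900L, sort(unique(i1_end))], c(300L, 400L))
})

test_that("fixture events are recovered with exact type labels and no extras", {
  fx <- get_fixture(); ch <- get_chain()
  ev <- ch$events
  mf <- fx$manifest$event_table
  expect_setequal(ev$event_id, mf$event_id)     # recall = 1, precision = 1
  m <- merge(ev, mf[, .(event_id, type_exp = as_type, nov_exp = novelty,
                        gene_exp = gene_id)], by = "event_id")
  expect_equal(m$as_type, m$type_exp)
  expect_equal(m$novelty, m$nov_exp)
  expect_equal(m$gene_id, m$gene_exp)
  # AFE/ALE: the proximal junction is the inclusion junction
  afe <- ev[as_type %in% c("AFE", "ALE")]
  expect_true(all(afe$proximal_is_inclusion))
  expect_true(all(afe$i1_end - afe$i1_start < afe$excl_end - afe$excl_start))
})

test_that("classification is invariant to junction input order", {
  fx <- get_fixture(); ch <- get_chain()
  jx <- ch$jx
  set.seed(9)
  jx_shuf <- jx[sample(.N)]
  ev2 <- detect_events(jx_shuf, ch$idx, min_reads = 10, genome = fx$genome)
  setkey(ev2, NULL)
  expect_identical(as.data.frame(ch$events), as.data.frame(ev2))
})

test_that("candidates without transcript linkage are unclassified", {
  fx <- get_fixture(); ch <- get_chain()
  un <- ch$events[as_type == "UN"]
  expect_equal(nrow(un), 1L)
  expect_true(is.na(un$gene_id))
  expect_equal(un$strand, "*")
  expect_equal(un$novelty, "novel")
})

test_that("annotated IR and MXE detection matches the planted manifest", {
  fx <- get_fixture()
  ir <- detect_annotated_ir(fx$models)
  mf_ir <- fx$manifest$event_table[as_type == "IR"]
  expect_setequal(ir$event_id, mf_ir$event_id)
  mxe <- detect_annotated_mxe(fx$models)
  mf_mxe <- fx$manifest$event_table[as_type == "MXE"]
  expect_setequal(mxe$event_id, mf_mxe$event_id)
  # a gene whose middle exons co-occur is not an MXE
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "G"; transcript_id "Ta"; gene_name "G";',
    'chr1\tx\texon\t201\t300\t.\t+\t.\tgene_id "G"; transcript_id "Ta"; gene_name "G";',
    'chr1\tx\texon\t401\t500\t.\t+\t.\tgene_id "G"; transcript_id "Ta"; gene_name "G";',
    'chr1\tx\texon\t601\t700\t.\t+\t.\tgene_id "G"; transcript_id "Ta"; gene_name "G";',
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "G"; transcript_id "Tb"; gene_name "G";',
    'chr1\tx\texon\t601\t700\t.\t+\t.\tgene_id "G"; transcript_id "Tb"; gene_name "G";'),
    gtf)
  m <- load_annotation(gtf); unlink(gtf)
  expect_equal(nrow(detect_annotated_mxe(m)), 0L)
})

test_that("novel events in blacklisted immune loci are dropped, known kept", {
  ev <- data.table(
    event_id = c("e1", "e2", "e3"),
    as_type = c("UN", "CE", "CE"), chrom = "chr9",
    novelty = c("novel", "known", "novel"),
    excl_start = c(100L, 150L, 5000L), excl_end = c(400L, 400L, 5400L))
  bl <- data.table(chrom = "chr9", start = 1L, end = 1000L)
  kept <- apply_region_blacklist(ev, bl)
  expect_setequal(kept$event_id, c("e2", "e3"))
  # empty blacklist is the identity
  expect_identical(apply_region_blacklist(ev, bl[0]), ev)
  # blacklist built from IG/TR/HLA gene-name patterns
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr9\tx\texon\t1\t900\t.\t+\t.\tgene_id "GI"; transcript_id "TI"; gene_name "IGHV1-1";',
    'chr9\tx\texon\t2000\t2900\t.\t+\t.\tgene_id "GO"; transcript_id "TO"; gene_name "OTHER";'),
    gtf)
  m <- load_annotation(gtf); unlink(gtf)
  bl2 <- build_blacklist(m)
  expect_equal(nrow(bl2), 1L)
  expect_equal(bl2$end, 900L)
})

test_that("coding effects follow frame arithmetic on the planted genes", {
  fx <- get_fixture(); ch <- get_chain()
  m <- merge(ch$events[, .(event_id, coding_effect)],
             fx$manifest$event_table[, .(event_id, expect = coding_effect)],
             by = "event_id")
  expect_equal(m$coding_effect, m$expect)
  # the in-frame CE removes a multiple-of-3 exon, the disruptive ones do not
  ce_if <- fx$manifest$event_table[tag == "CE_inframe"]
  ev <- ch$events[event_id == ce_if$event_id]
  expect_equal((ev$i2_start - ev$i1_end - 1L) %% 3L, 0L)
  ce_fs <- ch$events[event_id == fx$manifest$event_table[tag == "CE_fsNMD",
                                                         event_id]]
  expect_gt((ce_fs$i2_start - ce_fs$i1_end - 1L) %% 3L, 0L)
})

test_that("the 50-nt rule decides NMD on hand-constructed transcripts", {
  nf <- make_nmd_fixture()
  ev <- classify_coding_effect(nf$events, nf$index)
  ev <- predict_nmd(ev, nf$index, nf$genome)
  expect_equal(ev$nmd, nf$events$expect_nmd)
  # fixture events: engineered NMD truth is reproduced
  fx <- get_fixture(); ch <- get_chain()
  m <- merge(ch$events[, .(event_id, nmd)],
             fx$manifest$event_table[, .(event_id, expect = nmd)],
             by = "event_id")
  expect_identical(m$nmd, m$expect)
})
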