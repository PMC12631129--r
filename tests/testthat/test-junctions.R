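test_that("reads sharing a cell barcode and UMI are merged into one molecule", {
  recs <- list(
    list(qname = "r1", pos = 100L, cigar = "30M100N30M", cb = "C1", umi = "U1"),
    list(qname = "r2", pos = 100L, cigar = "30M100N30M", cb = "C1", umi = "U1"),
    list(qname = "r3", pos = 100L, cigar = "30M100N30M", cb = "C1", umi = "U1"),
    list(qname = "r4", pos = 100L, cigar = "30M100N30M", cb = "C1", umi = "U2"),
    list(qname = "r5", pos = 500L, cigar = "60M", cb = "C1", umi = "U3"))
  bam <- make_bam(recs)
  jx <- extract_junctions(bam)
  expect_equal(nrow(jx), 1L)            # ungapped read contributes nothing
  expect_equal(jx$count, 2L)            # 3 duplicates -> 1 molecule, + U2
  expect_equal(jx$start, 130L)
  expect_equal(jx$end, 229L)
  # bulk mode counts every read
  jb <- extract_junctions(bam, mode = "bulk")
  expect_equal(jb$count, 4L)
})

test_that("duplicating every record leaves single-cell counts unchanged and doubles bulk", {
  sim <- get_sim()
  jx1 <- extract_junctions(sim$bam)
  jb1 <- extract_junctions(sim$bam, mode = "bulk")
  # rewrite the BAM with every record twice
  p <- Rsamtools::ScanBamParam(what = Rsamtools::scanBamWhat(),
                               tag = c("CB", "UB"))
  sam0 <- tempfile(fileext = ".sam")
  Rsamtools::asSam(sim$bam, sub("\\.sam$", "", sam0), overwrite = TRUE)
  lines <- readLines(sam0)
  hdr <- grepl("^@", lines)
  dup <- c(lines[hdr], rep(lines[!hdr], each = 2L))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(dup, sam2)
  bam2 <- Rsamtools::asBam(sam2, tempfile(), overwrite = TRUE,
                           indexDestination = TRUE)
  jx2 <- extract_junctions(bam2)
  expect_identical(jx1, jx2, ignore_attr = TRUE)
  jb2 <- extract_junctions(bam2, mode = "bulk")
  expect_equal(jb2$count, 2L * jb1$count)
})

test_that("per-cell junction counts equal the planted-molecule manifest", {
  fx <- get_fixture(); sim <- get_sim(); ch <- get_chain()
  jx <- ch$jx
  # every junction event's exclusion junction support per cell = truth E
  tr <- sim$truth
  for (ev in fx$manifest$events) {
    if (ev$as_type == "IR") next
    got <- jx[chrom == ev$chrom & start == ev$excl[1] & end == ev$excl[2],
              .(cell, count)]
    want <- tr[event_id == ev$key & E > 0, .(cell, E)]
    m <- merge(got, want, by = "cell", all = TRUE)
    expect_true(all(!is.na(m$count) & !is.na(m$E) & m$count == m$E),
                info = ev$key)
  }
})

test_that("sub-minimum reference skips are deletions, not junctions", {
  recs <- list(
    list(qname = "r1", pos = 100L, cigar = "30M10N30M", cb = "C1", umi = "U1"),
    list(qname = "r2", pos = 100L, cigar = "30M20N30M", cb = "C1", umi = "U2"))
  bam <- make_bam(recs)
  jx <- extract_junctions(bam, min_intron = 20L)
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$end - jx$start + 1L, 20L)
})

test_that("a read with two skips supports two junctions", {
  bam <- make_bam(list(
    list(qname = "r1", pos = 100L, cigar = "30M100N40M200N30M",
         cb = "C1", umi = "U1")))
  jx <- extract_junctions(bam)
  expect_equal(nrow(jx), 2L)
  expect_equal(jx$count, c(1L, 1L))
})

test_that("boundary spans require contiguous coverage across the site", {
  site <- data.table(chrom = "chr1", pos = 129L)
  recs <- list(
    # gap starts exactly at the boundary: junction read, not a span
    list(qname = "r1", pos = 100L, cigar = "30M100N30M", cb = "C1", umi = "U1"),
    # contiguous read across the boundary
    list(qname = "r2", pos = 110L, cigar = "60M", cb = "C1", umi = "U2"),
    # read fully beyond the boundary
    list(qname = "r3", pos = 140L, cigar = "40M", cb = "C1", umi = "U3"))
  bam <- make_bam(recs)
  sp <- count_boundary_spans(bam, site)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$count, 1L)
  # fixture: per-cell span-derived IR counts equal the manifest
  fx <- get_fixture(); ch <- get_chain(); sim <- get_sim()
  ir <- ch$events[as_type == "IR"]
  sp2 <- as.data.table(ch$spans)[chrom == ir$chrom &
                                 pos %in% c(ir$ir_site1, ir$ir_site2)]
  got <- sp2[, .(n = max(count)), by = cell]
  want <- sim$truth[event_id == ir$event_id & I > 0, .(cell, I)]
  m <- merge(got, want, by = "cell", all = TRUE)
  expect_true(all(!is.na(m$n) & !is.na(m$I) & m$n == m$I))
})

test_that("minimum-support filtering equals the brute-force filter", {
  set.seed(3)
  tab <- data.table(chrom = "chr1",
                    start = sample(1:50, 120, TRUE) * 10L,
                    end = integer(120), cell = sample(LETTERS[1:5], 120, TRUE),
                    count = sample(1:6, 120, TRUE))
  tab[, end := start + 500L]
  for (mr in c(1L, 5L, 10L)) {
    got <- filter_min_support(tab, mr)
    tot <- tab[, .(t = sum(count)), by = .(chrom, start, end)]
    keep <- tot[t >= mr]
    bf <- tab[paste(start, end) %in% paste(keep$start, keep$end)]
    expect_setequal(paste(got$start, got$cell, got$count),
                    paste(bf$start, bf$cell, bf$count))
  }
  expect_equal(nrow(filter_min_support(tab, 1L)), nrow(tab))  # identity
  one <- jt(list("chr1", 100, 300, "C1", 9))
  expect_equal(nrow(filter_min_support(one, 10L)), 0L)
})

test_that("junction tables demand indexed input", {
  bam <- make_bam(list(
    list(qname = "r1", pos = 100L, cigar = "30M100N30M", cb = "C1", umi = "U1")))
  file.remove(paste0(bam, ".bai"))
  expect_error(extract_junctions(bam), "indexed")
})
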