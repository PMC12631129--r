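library(data.table)

# one shared fixture per test run; building it is a few seconds, so cache
.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fx_cache$fx))
    .fx_cache$fx <- generate_genome_and_annotation(seed = 1)
  .fx_cache$fx
}

get_sim <- function() {
  if (is.null(.fx_cache$sim))
    .fx_cache$sim <- simulate_reads(get_fixture(), seed = 1)
  .fx_cache$sim
}

get_refs <- function() {
  if (is.null(.fx_cache$refs))
    .fx_cache$refs <- generate_references(get_fixture(), seed = 1)
  .fx_cache$refs
}

# junction extraction -> detection -> counting on the shared fixture
get_chain <- function() {
  if (is.null(.fx_cache$chain)) {
    fx <- get_fixture(); sim <- get_sim()
    jx <- extract_junctions(sim$bam)
    idx <- build_boundary_index(fx$models)
    ir0 <- detect_annotated_ir(fx$models)
    sites <- unique(rbind(ir0[, .(chrom, pos = ir_site1)],
                          ir0[, .(chrom, pos = ir_site2)]))
    spans <- count_boundary_spans(sim$bam, sites)
    events <- detect_events(jx, idx, min_reads = 10, genome = fx$genome)
    counts <- count_events(events, jx, spans)
    .fx_cache$chain <- list(jx = jx, idx = idx, spans = spans,
                            events = events, counts = counts)
  }
  .fx_cache$chain
}

# per-(sample, cell type) aggregates of the truth counts
get_units <- function() {
  tr <- get_sim()$truth
  u <- tr[, .(I = sum(I), E = sum(E)), by = .(event_id, sample_id, cell_type)]
  u[, unit := paste(sample_id, cell_type, sep = "|")]
  u
}

# a small hand-made junction table (chrom, start, end, cell, count)
jt <- function(...) {
  rows <- list(...)
  rbindlist(lapply(rows, function(r)
    data.table(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), cell = r[[4]],
               count = as.integer(r[[5]]))))
}

# write a SAM in code and convert to an indexed BAM; records are lists
# (qname, pos, cigar, cb, umi); seq defaults to repeated A of aligned length
make_bam <- function(records, chrom = "chr1", chrom_len = 100000L,
                     dir = tempfile("bam_")) {
  dir.create(dir, showWarnings = FALSE)
  qlen <- function(cig) sum(as.integer(
    regmatches(cig, gregexpr("[0-9]+(?=[MIS=X])", cig, perl = TRUE))[[1]]))
  body <- vapply(records, function(r) {
    tags <- if (!is.null(r$cb))
      sprintf("\tCB:Z:%s\tUB:Z:%s", r$cb, r$umi) else ""
    n <- qlen(r$cigar)
    sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s%s",
            r$qname, chrom, r$pos, r$cigar, strrep("A", n),
            strrep("I", n), tags)
  }, "")
  ord <- order(vapply(records, function(r) r$pos, 0))
  sam <- file.path(dir, "t.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)), sam)
  cat(paste0(body[ord], "\n"), file = sam, append = TRUE, sep = "")
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}
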