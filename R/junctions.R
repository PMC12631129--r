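# Junction and boundary-span extraction from barcoded alignments.
#
# Reference-skip (N) operations shorter than `min_intron` bases are treated
# as deletions: they neither define junctions nor interrupt the aligned
# span used for boundary-spanning reads.

.check_bam <- function(bam_path) {
  if (!file.exists(bam_path)) stop("alignment file not found: ", bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]
  so <- hdr$text[["@HD"]]
  if (is.null(so) || !any(grepl("^SO:coordinate$", so)))
    stop("alignment file must be coordinate-sorted (SO:coordinate): ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("alignment file must be indexed (.bai missing): ", bam_path)
  invisible(TRUE)
}

# primary alignments only, with positions, cigars and CB/UB tags
.scan_reads <- function(bam_path, cb_tag, umi_tag) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar"),
    tag  = c(cb_tag, umi_tag),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1L]]
  data.table(chrom = as.character(res$rname),
             pos   = res$pos,
             cigar = res$cigar,
             cell  = as.character(res$tag[[cb_tag]]),
             umi   = as.character(res$tag[[umi_tag]]))
}

#' Extract UMI-deduplicated splice junctions per cell from a BAM file
#'
#' Every reference-skip segment of a primary alignment contributes the
#' skipped intron interval (1-based first and last intronic base).  In
#' `single_cell` mode, reads sharing (cell barcode, UMI) are merged into a
#' single molecule before counting: a molecule supports a junction if any
#' of its reads spans it, and supports it at most once.  In `bulk` mode
#' every read counts and UMI unification is skipped.
#'
#' @param bam_path Coordinate-sorted, indexed BAM file.
#' @param cb_tag,umi_tag Cell-barcode and UMI tag names (Cell Ranger
#'   convention `CB`/`UB` by default).
#' @param mode `"single_cell"` or `"bulk"`.
#' @param min_intron Minimum reference-skip length counted as a junction;
#'   shorter skips are treated as deletions (default 20).
#' @return data.table with columns chrom, start, end (intron interval),
#'   cell (`"bulk"` in bulk mode) and count (deduplicated molecules).
#'   Reads missing either tag in `single_cell` mode are skipped; their
#'   number is reported via the `n_tagless` attribute (with a warning).
#' @export
extract_junctions <- function(bam_path, cb_tag = "CB", umi_tag = "UB",
                              mode = c("single_cell", "bulk"),
                              min_intron = 20L) {
  mode <- match.arg(mode)
  .check_bam(bam_path)
  reads <- .scan_reads(bam_path, cb_tag, umi_tag)
  n_tagless <- 0L
  if (mode == "single_cell") {
    tagless <- is.na(reads$cell) | is.na(reads$umi)
    n_tagless <- sum(tagless)
    if (n_tagless > 0L) {
      warning(n_tagless, " reads missing ", cb_tag, "/", umi_tag,
              " tags were skipped")
      reads <- reads[!tagless]
    }
  }
  jx <- .read_junctions(reads, min_intron)
  if (nrow(jx) == 0L) {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), cell = character(), count = integer())
  } else if (mode == "single_cell") {
    mol <- unique(jx[, .(chrom, start, end, cell, umi)])
    out <- mol[, .(count = .N), by = .(chrom, start, end, cell)]
  } else {
    out <- jx[, .(count = .N), by = .(chrom, start, end)]
    out[, cell := "bulk"]
    setcolorder(out, c("chrom", "start", "end", "cell", "count"))
  }
  setorder(out, chrom, start, end, cell)
  setattr(out, "n_tagless", n_tagless)
  setattr(out, "mode", mode)
  out[]
}

# one row per (read, junction): reference-skips of length >= min_intron
.read_junctions <- function(reads, min_intron) {
  if (nrow(reads) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      cell = character(), umi = character()))
  skips <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = "N")
  n_per_read <- S4Vectors::elementNROWS(skips)
  flat <- unlist(skips, use.names = FALSE)
  idx <- rep(seq_len(nrow(reads)), n_per_read)
  dt <- data.table(chrom = reads$chrom[idx],
                   start = IRanges::start(flat),
                   end   = IRanges::end(flat),
                   cell  = reads$cell[idx],
                   umi   = reads$umi[idx])
  dt[end - start + 1L >= min_intron]
}

# contiguous aligned blocks per read, with sub-min_intron skips bridged
.read_blocks <- function(reads, min_intron) {
  aligned <- GenomicAlignments::extractAlignmentRangesOnReference(
    reads$cigar, pos = reads$pos)
  merged <- IRanges::reduce(aligned, min.gapwidth = min_intron)
  n_per_read <- S4Vectors::elementNROWS(merged)
  flat <- unlist(merged, use.names = FALSE)
  idx <- rep(seq_len(nrow(reads)), n_per_read)
  data.table(chrom = reads$chrom[idx],
             bstart = IRanges::start(flat),
             bend   = IRanges::end(flat),
             cell   = reads$cell[idx],
             umi    = reads$umi[idx])
}

#' Count molecules spanning exon-intron boundary sites
#'
#' A molecule counts at a site if one of its reads covers positions `site`
#' and `site + 1` contiguously, i.e. without a reference skip across the
#' boundary.  Junction reads whose skip starts exactly at the boundary are
#' therefore not counted.  UMI merging follows [extract_junctions()].
#'
#' @param bam_path Coordinate-sorted, indexed BAM file.
#' @param sites data.frame/data.table with columns chrom, pos: boundary
#'   positions of candidate retained introns.
#' @inheritParams extract_junctions
#' @return data.table with columns chrom, pos, cell, count.
#' @export
count_boundary_spans <- function(bam_path, sites, cb_tag = "CB",
                                 umi_tag = "UB",
                                 mode = c("single_cell", "bulk"),
                                 min_intron = 20L) {
  mode <- match.arg(mode)
  .check_bam(bam_path)
  sites <- as.data.table(sites)[, .(chrom, pos)]
  reads <- .scan_reads(bam_path, cb_tag, umi_tag)
  if (mode == "single_cell") reads <- reads[!is.na(cell) & !is.na(umi)]
  empty <- data.table(chrom = character(), pos = integer(),
                      cell = character(), count = integer())
  if (nrow(reads) == 0L || nrow(sites) == 0L) return(empty)
  blocks <- .read_blocks(reads, min_intron)
  sites2 <- copy(sites)[, `:=`(start = pos, end = pos + 1L)]
  setkey(blocks, chrom, bstart, bend)
  hits <- foverlaps(sites2, blocks,
                    by.x = c("chrom", "start", "end"),
                    by.y = c("chrom", "bstart", "bend"),
                    type = "within", nomatch = NULL)
  if (nrow(hits) == 0L) return(empty)
  if (mode == "single_cell") {
    mol <- unique(hits[, .(chrom, pos, cell, umi)])
    out <- mol[, .(count = .N), by = .(chrom, pos, cell)]
  } else {
    out <- hits[, .(count = .N), by = .(chrom, pos)]
    out[, cell := "bulk"]
    setcolorder(out, c("chrom", "pos", "cell", "count"))
  }
  setorder(out, chrom, pos, cell)
  out[]
}

#' Keep junctions supported by a minimum total number of molecules
#'
#' @param junctions Output of [extract_junctions()].
#' @param min_reads Minimum total support summed over cells (>= 1).
#' @return The retained junction rows.
#' @export
filter_min_support <- function(junctions, min_reads) {
  stopifnot(min_reads >= 1L)
  junctions <- as.data.table(junctions)
  tot <- junctions[, .(total = sum(count)), by = .(chrom, start, end)]
  keep <- tot[total >= min_reads, .(chrom, start, end)]
  junctions[keep, on = c("chrom", "start", "end")]
}

#' Total junction support pooled over cells
#'
#' @param junctions Output of [extract_junctions()].
#' @return data.table chrom, start, end, total.
#' @export
junction_totals <- function(junctions) {
  as.data.table(junctions)[, .(total = sum(count)), by = .(chrom, start, end)]
}
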