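#' @import data.table
#' @importFrom methods is
NULL

#' Load transcript models from a GTF annotation
#'
#' Parses an Ensembl-dialect GTF into a set of transcript models: one model
#' per `transcript_id`, with exons ordered 5' to 3' along the transcript
#' strand and optional CDS intervals.  Coordinates are kept 1-based
#' inclusive exactly as in the GTF; nothing is shifted.
#'
#' @param gtf_path Path to a GTF file with `exon` (and optionally `CDS`)
#'   features carrying `transcript_id` and `gene_id` attributes.
#' @param source_label Either `"primary_annotation"` (e.g. Ensembl) or
#'   `"assembled_annotation"` (e.g. a StringTie assembly).  Classification
#'   prefers primary models when both explain an event.
#' @return An object of class `tx_models`: a list with data.tables
#'   `transcripts` (transcript_id, gene_id, gene_name, chrom, strand,
#'   source, cds_len, frame_ok), `exons` and `cds` (transcript_id, chrom,
#'   start, end, strand, rank; rank counts 5' to 3').
#' @export
load_annotation <- function(gtf_path,
                            source_label = c("primary_annotation",
                                             "assembled_annotation")) {
  source_label <- match.arg(source_label)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  dt <- data.table(
    type          = as.character(gr$type),
    chrom         = as.character(GenomicRanges::seqnames(gr)),
    start         = GenomicRanges::start(gr),
    end           = GenomicRanges::end(gr),
    strand        = as.character(GenomicRanges::strand(gr)),
    transcript_id = if (is.null(gr$transcript_id)) NA_character_ else as.character(gr$transcript_id),
    gene_id       = if (is.null(gr$gene_id)) NA_character_ else as.character(gr$gene_id),
    gene_name     = if (is.null(gr$gene_name)) NA_character_ else as.character(gr$gene_name)
  )
  exons <- dt[type == "exon" & !is.na(transcript_id)]
  if (nrow(exons) == 0L) stop("no exon features with transcript_id found in ", gtf_path)
  cds <- dt[type == "CDS" & !is.na(transcript_id)]

  order_tx <- function(tab) {
    # 5'->3' in transcription order: ascending on +, descending on -
    tab <- tab[order(transcript_id, start)]
    tab[, rank := seq_len(.N), by = transcript_id]
    neg <- tab$strand == "-"
    if (any(neg)) {
      tab[strand == "-", rank := rev(rank), by = transcript_id]
    }
    tab[order(transcript_id, rank),
        .(transcript_id, chrom, start, end, strand, rank)]
  }
  exons <- order_tx(exons)
  cds   <- if (nrow(cds)) order_tx(cds) else
    data.table(transcript_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               rank = integer())

  tx <- unique(dt[type == "exon" & !is.na(transcript_id),
                  .(transcript_id, gene_id, gene_name, chrom, strand)])
  if (anyDuplicated(tx$transcript_id))
    stop("transcript_id maps to more than one gene/chrom/strand")
  cds_len <- cds[, .(cds_len = sum(end - start + 1L)), by = transcript_id]
  tx <- merge(tx, cds_len, by = "transcript_id", all.x = TRUE)
  tx[is.na(cds_len), cds_len := 0L]
  tx[, frame_ok := cds_len > 0L & cds_len %% 3L == 0L]
  tx[, source := source_label]

  models <- list(transcripts = tx[order(transcript_id)],
                 exons = exons, cds = cds)
  class(models) <- "tx_models"
  models
}

#' Combine primary and assembled transcript models
#'
#' @param primary,assembled `tx_models` objects (assembled may be `NULL`).
#' @return A `tx_models` with both sources; duplicate transcript ids in the
#'   assembled set are dropped in favour of the primary ones.
#' @export
merge_annotations <- function(primary, assembled = NULL) {
  stopifnot(is(primary, "tx_models"))
  if (is.null(assembled)) return(primary)
  stopifnot(is(assembled, "tx_models"))
  keep <- !(assembled$transcripts$transcript_id %in%
            primary$transcripts$transcript_id)
  kept_ids <- assembled$transcripts$transcript_id[keep]
  out <- list(
    transcripts = rbind(primary$transcripts,
                        assembled$transcripts[transcript_id %in% kept_ids]),
    exons = rbind(primary$exons, assembled$exons[transcript_id %in% kept_ids]),
    cds   = rbind(primary$cds,   assembled$cds[transcript_id %in% kept_ids])
  )
  class(out) <- "tx_models"
  out
}

#' Serialize transcript models back to GTF-style exon records
#'
#' Used to verify that coordinates round-trip unchanged through parsing.
#'
#' @param models A `tx_models` object.
#' @return data.table of exon records (chrom, start, end, strand,
#'   transcript_id, gene_id) sorted by transcript and genomic start.
#' @export
serialize_exons <- function(models) {
  out <- merge(models$exons,
               models$transcripts[, .(transcript_id, gene_id)],
               by = "transcript_id")
  out[order(transcript_id, start),
      .(chrom, start, end, strand, transcript_id, gene_id)]
}

# introns of every transcript, genomic coordinates of first/last intronic base
.tx_introns <- function(models) {
  ex <- models$exons[order(transcript_id, start)]
  ex[, n := .N, by = transcript_id]
  multi <- ex[n > 1L]
  if (nrow(multi) == 0L)
    return(data.table(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character()))
  introns <- multi[, .(chrom = chrom[1L], strand = strand[1L],
                       start = head(end, -1L) + 1L,
                       end   = tail(start, -1L) - 1L),
                   by = transcript_id]
  introns[, .(transcript_id, chrom, start, end, strand)]
}

#' Build a splice-boundary index from transcript models
#'
#' Indexes every annotated intron together with its donor site (last exonic
#' base before the intron, on the transcript strand) and acceptor site
#' (first exonic base after it), plus the intron-adjacent boundaries of
#' annotated first and last exons.  Event classification aligns observed
#' junction positions against this index.
#'
#' @param models A `tx_models` object (non-empty).
#' @return An object of class `boundary_index` with data.tables `introns`
#'   (chrom, start, end, strand, transcript_id, gene_id), `donors` and
#'   `acceptors` (chrom, strand, pos), `first_exon_sites` and
#'   `last_exon_sites` (chrom, strand, pos, gene_id): the splice-side
#'   boundary positions of first/last exons.
#' @export
build_boundary_index <- function(models) {
  stopifnot(is(models, "tx_models"), nrow(models$transcripts) > 0L)
  introns <- .tx_introns(models)
  introns <- merge(introns, models$transcripts[, .(transcript_id, gene_id, source)],
                   by = "transcript_id")

  # donor = exonic base 5' of the intron; acceptor = exonic base 3' of it
  donors <- unique(introns[, .(chrom, strand, gene_id,
                               pos = fifelse(strand == "+", start - 1L, end + 1L))])
  acceptors <- unique(introns[, .(chrom, strand, gene_id,
                                  pos = fifelse(strand == "+", end + 1L, start - 1L))])

  ex <- models$exons
  firsts <- ex[rank == 1L]
  firsts <- firsts[transcript_id %in% introns$transcript_id]  # multi-exon only
  first_sites <- merge(
    firsts[, .(transcript_id, chrom, strand,
               pos = fifelse(strand == "+", end, start),
               exon_start = start, exon_end = end)],
    models$transcripts[, .(transcript_id, gene_id)], by = "transcript_id")
  lasts <- ex[, .SD[rank == max(rank)], by = transcript_id]
  lasts <- lasts[transcript_id %in% introns$transcript_id]
  last_sites <- merge(
    lasts[, .(transcript_id, chrom, strand,
              pos = fifelse(strand == "+", start, end),
              exon_start = start, exon_end = end)],
    models$transcripts[, .(transcript_id, gene_id)], by = "transcript_id")

  idx <- list(introns = introns,
              donors = donors[order(chrom, pos)],
              acceptors = acceptors[order(chrom, pos)],
              first_exon_sites = unique(first_sites[, .(chrom, strand, pos,
                                                        gene_id, exon_start, exon_end)]),
              last_exon_sites  = unique(last_sites[, .(chrom, strand, pos,
                                                       gene_id, exon_start, exon_end)]),
              models = models)
  class(idx) <- "boundary_index"
  idx
}

#' Load a genome FASTA into memory
#'
#' @param fasta_path Path to a (small) genome FASTA.
#' @return A named `DNAStringSet`, names truncated at the first whitespace.
#' @export
load_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# spliced sequence of a set of intervals (transcription order), strand-aware
.spliced_seq <- function(chrom, starts, ends, strand, genome) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  o <- order(starts)
  pieces <- Biostrings::DNAStringSet(lapply(seq_along(o), function(i) {
    Biostrings::subseq(genome[[chrom]], starts[o[i]], ends[o[i]])
  }))
  s <- Reduce(Biostrings::xscat, pieces)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Extract the spliced coding sequence of a transcript
#'
#' @param models A `tx_models` object.
#' @param transcript_id Transcript whose CDS to extract.
#' @param genome A `DNAStringSet` from [load_genome()].
#' @return A `DNAString` of the CDS in transcript orientation (reverse
#'   complemented for minus-strand models).
#' @export
extract_coding_sequence <- function(models, transcript_id, genome) {
  tid <- transcript_id
  cds <- models$cds[transcript_id == tid]
  if (nrow(cds) == 0L) stop("transcript has no CDS: ", tid)
  info <- models$transcripts[transcript_id == tid]
  if (!info$frame_ok)
    stop("frame-incomplete CDS (length not a positive multiple of 3): ", tid)
  .spliced_seq(cds$chrom[1L], cds$start, cds$end, info$strand, genome)
}
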