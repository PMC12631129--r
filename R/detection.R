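# Grouping of filtered junctions into alternative splicing events,
# classification into the seven types (+ UN), and annotation of coding
# effect and predicted nonsense-mediated decay.

#' Deterministic event identifier
#'
#' @param chrom Chromosome.
#' @param excl Exclusion-junction intron interval `c(start, end)`.
#' @param incl_list List of inclusion-junction intervals (possibly empty).
#' @param as_type Event type label.
#' @return A stable string key, identical for identical coordinates/type.
#' @export
make_event_id <- function(chrom, excl, incl_list, as_type) {
  incl <- if (length(incl_list) == 0L) "." else
    paste(sort(vapply(incl_list, function(iv) paste0(iv[1], "-", iv[2]), "")),
          collapse = "|")
  paste0(as_type, ":", chrom, ":", excl[1], "-", excl[2], ":", incl)
}

#' Pair junctions into candidate splicing events
#'
#' Treats every junction as a potential exclusion junction and finds
#' inclusion junctions nested strictly inside its intron that share its
#' start or its end.  When more than two junctions share one splice
#' position, only the top two by read count are kept per position (ties
#' broken by smaller intron, then leftmost coordinate).  A shared-start and
#' a shared-end junction that leave at least one exonic base between them
#' form a cassette (two-sided) candidate; junctions pairing on one side
#' only form single-sided candidates.
#'
#' @param totals data.table chrom, start, end, total (from
#'   [junction_totals()], after [filter_min_support()]).
#' @return data.table of candidates: chrom, excl_start, excl_end, shared
#'   (`"both"`, `"start"` or `"end"`), i1_start, i1_end, i2_start, i2_end
#'   (i2 only for two-sided candidates).
#' @export
detect_junction_events <- function(totals) {
  totals <- as.data.table(totals)[, .(chrom, start, end, total)]
  empty <- data.table(chrom = character(), excl_start = integer(),
                      excl_end = integer(), shared = character(),
                      i1_start = integer(), i1_end = integer(),
                      i2_start = integer(), i2_end = integer())
  if (nrow(totals) == 0L) return(empty)
  J <- copy(totals)[, width := end - start + 1L]

  # partners nested strictly inside the exclusion intron, sharing one side
  left <- merge(J[, .(chrom, start, excl_end = end)],
                J[, .(chrom, start, p_end = end, p_total = total,
                      p_width = width)],
                by = c("chrom", "start"), allow.cartesian = TRUE)
  left <- left[p_end < excl_end]
  setnames(left, "start", "excl_start")
  if (nrow(left)) {
    setorder(left, chrom, excl_start, excl_end, -p_total, p_width, p_end)
    left <- left[, head(.SD, 2L), by = .(chrom, excl_start, excl_end)]
  }
  right <- merge(J[, .(chrom, end, excl_start = start)],
                 J[, .(chrom, end, p_start = start, p_total = total,
                       p_width = width)],
                 by = c("chrom", "end"), allow.cartesian = TRUE)
  right <- right[p_start > excl_start]
  setnames(right, "end", "excl_end")
  if (nrow(right)) {
    setorder(right, chrom, excl_start, excl_end, -p_total, p_width, p_start)
    right <- right[, head(.SD, 2L), by = .(chrom, excl_start, excl_end)]
  }

  out <- list()
  ce <- if (nrow(left) && nrow(right))
    merge(left, right, by = c("chrom", "excl_start", "excl_end"),
          allow.cartesian = TRUE)[p_end + 2L <= p_start]
  else NULL
  if (!is.null(ce) && nrow(ce)) {
    out$ce <- ce[, .(chrom, excl_start, excl_end, shared = "both",
                     i1_start = excl_start, i1_end = p_end,
                     i2_start = p_start, i2_end = excl_end)]
  }
  ce_keys <- if (!is.null(ce) && nrow(ce))
    unique(ce[, .(chrom, excl_start, excl_end)]) else
    data.table(chrom = character(), excl_start = integer(), excl_end = integer())
  if (nrow(left)) {
    sl <- left[!ce_keys, on = c("chrom", "excl_start", "excl_end")]
    if (nrow(sl))
      out$sl <- sl[, .(chrom, excl_start, excl_end, shared = "start",
                       i1_start = excl_start, i1_end = p_end,
                       i2_start = NA_integer_, i2_end = NA_integer_)]
  }
  if (nrow(right)) {
    sr <- right[!ce_keys, on = c("chrom", "excl_start", "excl_end")]
    if (nrow(sr))
      out$sr <- sr[, .(chrom, excl_start, excl_end, shared = "end",
                       i1_start = p_start, i1_end = excl_end,
                       i2_start = NA_integer_, i2_end = NA_integer_)]
  }
  if (length(out) == 0L) return(empty)
  res <- rbindlist(out)
  setorder(res, chrom, excl_start, excl_end, shared, i1_start, i1_end)
  unique(res)
}

# gene linkage of a set of junction intervals: annotated-intron matches
# first (primary annotation preferred), then splice-site matches
.link_gene <- function(chrom_, jxs, index) {
  introns <- index$introns
  hits <- rbindlist(lapply(jxs, function(iv)
    introns[chrom == chrom_ & start == iv[1] & end == iv[2],
            .(gene_id, strand, source)]))
  if (nrow(hits) == 0L) {
    flanks <- unique(unlist(lapply(jxs, function(iv) c(iv[1] - 1L, iv[2] + 1L))))
    site_genes <- rbind(
      index$donors[chrom == chrom_ & pos %in% flanks, .(gene_id, strand)],
      index$acceptors[chrom == chrom_ & pos %in% flanks, .(gene_id, strand)])
    hits <- unique(site_genes)[, source := "site"]
  }
  if (nrow(hits) == 0L) return(NULL)
  hits <- unique(hits[, .(gene_id, strand, source)])
  prim <- hits[source == "primary_annotation"]
  if (nrow(prim)) hits <- prim
  genes <- unique(hits$gene_id)
  list(genes = genes, strand = hits$strand[1L])
}

.is_known <- function(chrom_, jxs, index) {
  all(vapply(jxs, function(iv)
    nrow(index$introns[chrom == chrom_ & start == iv[1] & end == iv[2]]) > 0L,
    TRUE))
}

#' Classify candidate events against annotated transcript structures
#'
#' Two-sided candidates become cassette exons (CE).  Single-sided
#' candidates are classified by aligning their alternative splice positions
#' to the boundary index: boundaries of two non-overlapping annotated first
#' exons give AFE (the proximal junction, i.e. the nested/shorter intron,
#' is the inclusion isoform), of last exons ALE; two annotated donor
#' (acceptor) boundaries of overlapping exons give A5SS (A3SS), named on
#' the gene strand.  Candidates that cannot be linked to any transcript are
#' UN; candidates linking two genes are UN with a `multi_gene` flag.
#' An event is `known` only when all its junctions are annotated introns.
#'
#' @param candidates Output of [detect_junction_events()].
#' @param index A [build_boundary_index()] result.
#' @return data.table of events: event_id, as_type, chrom, strand, gene_id,
#'   excl/incl coordinates, novelty, proximal_is_inclusion, flag.
#' @export
classify_event <- function(candidates, index) {
  candidates <- as.data.table(candidates)
  models <- index$models
  rows <- vector("list", nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    cd <- candidates[r]
    excl <- c(cd$excl_start, cd$excl_end)
    incl <- if (cd$shared == "both")
      list(c(cd$i1_start, cd$i1_end), c(cd$i2_start, cd$i2_end))
    else list(c(cd$i1_start, cd$i1_end))
    jxs <- c(list(excl), incl)
    link <- .link_gene(cd$chrom, jxs, index)
    known <- .is_known(cd$chrom, jxs, index)
    as_type <- "UN"; strand <- "*"; gene <- NA_character_
    flag <- NA_character_; proximal <- NA

    if (is.null(link)) {
      as_type <- "UN"
    } else if (length(link$genes) > 1L) {
      as_type <- "UN"; flag <- "multi_gene"
    } else {
      gene <- link$genes; strand <- link$strand
      if (cd$shared == "both") {
        as_type <- "CE"
      } else {
        alt <- if (cd$shared == "start")
          c(cd$i1_end + 1L, cd$excl_end + 1L)   # varying right flanks
        else
          c(cd$i1_start - 1L, cd$excl_start - 1L)  # varying left flanks
        fe <- index$first_exon_sites[gene_id == gene & chrom == cd$chrom]
        le <- index$last_exon_sites[gene_id == gene & chrom == cd$chrom]
        ex_at <- function(p) {
          # exons whose intron-facing boundary sits at p
          e <- models$exons[chrom == cd$chrom & (start == p + 1L | end == p - 1L |
                                                 start == p | end == p)]
          e[end == p | start == p]
        }
        disjoint_pair <- function(sites, alt) {
          e1 <- sites[pos == alt[1]]; e2 <- sites[pos == alt[2]]
          nrow(e1) > 0L && nrow(e2) > 0L &&
            any(outer(seq_len(nrow(e1)), seq_len(nrow(e2)),
                      Vectorize(function(i, j)
                        e1$exon_end[i] < e2$exon_start[j] ||
                        e2$exon_end[j] < e1$exon_start[i])))
        }
        overlap_pair <- function(alt) {
          e1 <- ex_at(alt[1]); e2 <- ex_at(alt[2])
          nrow(e1) > 0L && nrow(e2) > 0L &&
            any(outer(seq_len(nrow(e1)), seq_len(nrow(e2)),
                      Vectorize(function(i, j)
                        e1$start[i] <= e2$end[j] && e2$start[j] <= e1$end[i])))
        }
        donor_side <- (cd$shared == "end") == (strand == "+")
        if (disjoint_pair(fe, alt)) {
          as_type <- "AFE"; proximal <- TRUE
        } else if (disjoint_pair(le, alt)) {
          as_type <- "ALE"; proximal <- TRUE
        } else if (donor_side &&
                   all(alt %in% index$donors[gene_id == gene]$pos) &&
                   overlap_pair(alt)) {
          as_type <- "A5SS"
        } else if (!donor_side &&
                   all(alt %in% index$acceptors[gene_id == gene]$pos) &&
                   overlap_pair(alt)) {
          as_type <- "A3SS"
        } else {
          as_type <- "UN"; flag <- "linked_unclassified"
        }
      }
    }
    rows[[r]] <- data.table(
      event_id = make_event_id(cd$chrom, excl, incl, as_type),
      as_type = as_type, chrom = cd$chrom, strand = strand, gene_id = gene,
      excl_start = excl[1], excl_end = excl[2],
      i1_start = incl[[1]][1], i1_end = incl[[1]][2],
      i2_start = if (length(incl) > 1L) incl[[2]][1] else NA_integer_,
      i2_end   = if (length(incl) > 1L) incl[[2]][2] else NA_integer_,
      ir_site1 = NA_integer_, ir_site2 = NA_integer_,
      mxe_incl_start = NA_integer_, mxe_incl_end = NA_integer_,
      mxe_excl_start = NA_integer_, mxe_excl_end = NA_integer_,
      novelty = if (known) "known" else "novel",
      proximal_is_inclusion = proximal, flag = flag)
  }
  unique(rbindlist(rows))
}

#' Detect annotation-defined intron retention events
#'
#' An intron of one transcript that is entirely exonic (including both
#' boundaries) in another transcript of the same gene defines an IR event:
#' the intron's junction is the exclusion evidence and the two exon-intron
#' boundary positions are the inclusion evidence.
#'
#' @param models A `tx_models`.
#' @param totals Optional observed junction totals; when given, only IR
#'   events whose exclusion junction was observed are reported.
#' @return data.table of IR events in the [classify_event()] layout.
#' @export
detect_annotated_ir <- function(models, totals = NULL) {
  introns <- .tx_introns(models)
  introns <- merge(introns, models$transcripts[, .(transcript_id, gene_id)],
                   by = "transcript_id")
  ex <- merge(models$exons, models$transcripts[, .(transcript_id, gene_id)],
              by = "transcript_id")
  rows <- list()
  for (r in seq_len(nrow(introns))) {
    iv <- introns[r]
    host <- ex[gene_id == iv$gene_id & transcript_id != iv$transcript_id &
               chrom == iv$chrom & start <= iv$start - 1L & end >= iv$end + 1L]
    if (nrow(host) == 0L) next
    if (!is.null(totals) &&
        nrow(as.data.table(totals)[chrom == iv$chrom & start == iv$start &
                                   end == iv$end]) == 0L) next
    excl <- c(iv$start, iv$end)
    rows[[length(rows) + 1L]] <- data.table(
      event_id = make_event_id(iv$chrom, excl, list(), "IR"),
      as_type = "IR", chrom = iv$chrom, strand = iv$strand,
      gene_id = iv$gene_id,
      excl_start = excl[1], excl_end = excl[2],
      i1_start = NA_integer_, i1_end = NA_integer_,
      i2_start = NA_integer_, i2_end = NA_integer_,
      ir_site1 = iv$start - 1L, ir_site2 = iv$end,
      mxe_incl_start = NA_integer_, mxe_incl_end = NA_integer_,
      mxe_excl_start = NA_integer_, mxe_excl_end = NA_integer_,
      novelty = "known", proximal_is_inclusion = NA, flag = NA_character_)
  }
  if (length(rows) == 0L) return(.empty_events())
  unique(rbindlist(rows))
}

.empty_events <- function() {
  data.table(event_id = character(), as_type = character(),
             chrom = character(), strand = character(), gene_id = character(),
             excl_start = integer(), excl_end = integer(),
             i1_start = integer(), i1_end = integer(),
             i2_start = integer(), i2_end = integer(),
             ir_site1 = integer(), ir_site2 = integer(),
             mxe_incl_start = integer(), mxe_incl_end = integer(),
             mxe_excl_start = integer(), mxe_excl_end = integer(),
             novelty = character(), proximal_is_inclusion = logical(),
             flag = character())
}

#' Detect annotation-defined mutually exclusive exon events
#'
#' Two internal exons of one gene, each used by some transcript, never
#' co-occurring in any transcript, sharing their flanking exons, define an
#' MXE event.  The 5'-most alternative exon (on the gene strand) is the
#' inclusion isoform; counting junctions run from the 5' flanking exon
#' into each alternative exon.
#'
#' @inheritParams detect_annotated_ir
#' @return data.table of MXE events in the [classify_event()] layout; the
#'   exclusion junction leads to the exclusion exon, `i1_*` to the
#'   inclusion exon, and `mxe_*` columns carry the two exon intervals.
#' @export
detect_annotated_mxe <- function(models, totals = NULL) {
  tx <- models$transcripts
  ex <- models$exons
  rows <- list()
  for (g in unique(tx$gene_id)) {
    tids <- tx[gene_id == g, transcript_id]
    if (length(tids) < 2L) next
    chains <- lapply(tids, function(t) ex[transcript_id == t][order(start)])
    names(chains) <- tids
    for (i in seq_along(tids)) for (j in seq_along(tids)) {
      if (i == j) next
      c1 <- chains[[i]]; c2 <- chains[[j]]
      if (nrow(c1) < 3L || nrow(c2) < 3L || nrow(c1) != nrow(c2)) next
      key1 <- paste(c1$start, c1$end); key2 <- paste(c2$start, c2$end)
      diff1 <- which(!(key1 %in% key2)); diff2 <- which(!(key2 %in% key1))
      if (length(diff1) != 1L || length(diff2) != 1L) next
      k <- diff1
      if (k == 1L || k == nrow(c1) || diff2 == 1L || diff2 == nrow(c2)) next
      if (diff2 != k) next
      X <- c(c1$start[k], c1$end[k]); Y <- c(c2$start[k], c2$end[k])
      if (X[2] >= Y[1] && Y[2] >= X[1]) next        # must be disjoint
      # shared flanks already implied by identical other exons; never co-occur:
      cooccur <- any(vapply(chains, function(cc) {
        kk <- paste(cc$start, cc$end)
        all(c(paste(X[1], X[2]), paste(Y[1], Y[2])) %in% kk)
      }, TRUE))
      if (cooccur) next
      strand <- c1$strand[1L]
      # orient: inclusion = 5'-most exon on the gene strand
      first_is_5p <- if (strand == "-") X[2] > Y[2] else X[1] < Y[1]
      inc <- if (first_is_5p) X else Y
      exc <- if (first_is_5p) Y else X
      flank_l <- c(c1$start[k - 1L], c1$end[k - 1L])
      flank_r <- c(c1$start[k + 1L], c1$end[k + 1L])
      jx_to <- function(exon) {
        if (strand == "-") c(exon[2] + 1L, flank_r[1] - 1L)
        else c(flank_l[2] + 1L, exon[1] - 1L)
      }
      # on minus strand the 5' flank is the genomically right one
      jx_to <- function(exon) {
        if (strand == "-") c(exon[2] + 1L, flank_r[1] - 1L)
        else c(flank_l[2] + 1L, exon[1] - 1L)
      }
      jinc <- jx_to(inc); jexc <- jx_to(exc)
      if (!is.null(totals)) {
        tt <- as.data.table(totals)
        if (nrow(tt[chrom == c1$chrom[1] & start == jexc[1] & end == jexc[2]]) == 0L)
          next
      }
      rows[[length(rows) + 1L]] <- data.table(
        event_id = make_event_id(c1$chrom[1], jexc, list(jinc), "MXE"),
        as_type = "MXE", chrom = c1$chrom[1], strand = strand, gene_id = g,
        excl_start = jexc[1], excl_end = jexc[2],
        i1_start = jinc[1], i1_end = jinc[2],
        i2_start = NA_integer_, i2_end = NA_integer_,
        ir_site1 = NA_integer_, ir_site2 = NA_integer_,
        mxe_incl_start = inc[1], mxe_incl_end = inc[2],
        mxe_excl_start = exc[1], mxe_excl_end = exc[2],
        novelty = "known", proximal_is_inclusion = NA, flag = NA_character_)
    }
  }
  if (length(rows) == 0L) return(.empty_events())
  unique(rbindlist(rows))
}

# all junctions diagnostic for an MXE event (both flank-in and out jumps)
.mxe_junction_set <- function(mxe_row, models) {
  ex <- models$exons[transcript_id %in%
                     models$transcripts[gene_id == mxe_row$gene_id, transcript_id]]
  exon_ivs <- list(c(mxe_row$mxe_incl_start, mxe_row$mxe_incl_end),
                   c(mxe_row$mxe_excl_start, mxe_row$mxe_excl_end))
  jxs <- character(0)
  for (e in exon_ivs) {
    host <- ex[start == e[1] & end == e[2]][1L]
    cc <- ex[transcript_id == host$transcript_id][order(start)]
    k <- which(cc$start == e[1] & cc$end == e[2])
    jxs <- c(jxs,
             paste0(cc$end[k - 1L] + 1L, "-", e[1] - 1L),
             paste0(e[2] + 1L, "-", cc$start[k + 1L] - 1L))
  }
  unique(jxs)
}

#' Resolve blacklist intervals from gene-name patterns
#'
#' Immunoglobulin (IG), T-cell receptor (TR) and HLA gene loci are prone to
#' DNA recombination and mapping artifacts; novel events inside them are
#' discarded.
#'
#' @param models A `tx_models`.
#' @param patterns Regular expressions on gene names.
#' @return data.table chrom, start, end (gene spans of matching genes).
#' @export
build_blacklist <- function(models,
                            patterns = c("^IG[HKL]", "^TR[ABGD]", "^HLA-")) {
  tx <- models$transcripts
  hit <- tx[grepl(paste(patterns, collapse = "|"), gene_name), transcript_id]
  if (length(hit) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  models$exons[transcript_id %in% hit,
               .(start = min(start), end = max(end)), by = chrom]
}

#' Drop novel events overlapping blacklisted regions
#'
#' Known (fully annotated) events are retained even inside blacklisted
#' regions; only novel events are removed.
#'
#' @param events Event table.
#' @param blacklist data.table chrom, start, end (e.g. [build_blacklist()]).
#' @return The filtered event table.
#' @export
apply_region_blacklist <- function(events, blacklist) {
  events <- as.data.table(events)
  blacklist <- as.data.table(blacklist)
  if (nrow(blacklist) == 0L || nrow(events) == 0L) return(events)
  drop <- rep(FALSE, nrow(events))
  for (b in seq_len(nrow(blacklist))) {
    drop <- drop | (events$novelty == "novel" &
                    events$chrom == blacklist$chrom[b] &
                    events$excl_start <= blacklist$end[b] &
                    events$excl_end >= blacklist$start[b])
  }
  events[!drop]
}

# --- coding effect and NMD ---------------------------------------------------

# representative transcript: linking transcript with the longest CDS
.representative_tx <- function(models, gene) {
  cand <- models$transcripts[gene_id == gene & frame_ok == TRUE]
  if (nrow(cand) == 0L) return(NULL)
  cand[order(-cds_len, transcript_id)][1L]
}

# genomic regions that differ between the two isoforms of an event
.event_diff_regions <- function(ev, index) {
  switch(ev$as_type,
    CE = list(c(ev$i1_end + 1L, ev$i2_start - 1L)),
    A5SS = ,
    A3SS = if (ev$i1_start == ev$excl_start)
      list(c(ev$i1_end + 1L, ev$excl_end))
    else
      list(c(ev$excl_start, ev$i1_start - 1L)),
    IR = list(c(ev$excl_start, ev$excl_end)),
    MXE = list(c(ev$mxe_incl_start, ev$mxe_incl_end),
               c(ev$mxe_excl_start, ev$mxe_excl_end)),
    AFE = ,
    ALE = {
      sites <- if (ev$as_type == "AFE") index$first_exon_sites else
        index$last_exon_sites
      alt <- if (ev$i1_start == ev$excl_start)
        c(ev$i1_end + 1L, ev$excl_end + 1L)
      else c(ev$i1_start - 1L, ev$excl_start - 1L)
      s <- sites[gene_id == ev$gene_id & pos %in% alt]
      lapply(seq_len(nrow(s)), function(i) c(s$exon_start[i], s$exon_end[i]))
    },
    list())
}

.overlap_len <- function(a, b) max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)

#' Classify the coding effect of events
#'
#' An event whose changed region lies entirely outside the representative
#' transcript's CDS span is `noncoding`; one that removes the start codon
#' or changes the coding length by a non-multiple of 3 is
#' `coding-disruptive`; a multiple-of-3 change away from the start codon is
#' `in-frame`.  Events in genes without a frame-complete CDS transcript are
#' `unknown`.
#'
#' @param events Event table from [detect_events()] components.
#' @param index A `boundary_index` (carries the models).
#' @return The event table with a `coding_effect` column.
#' @export
classify_coding_effect <- function(events, index) {
  models <- index$models
  events <- as.data.table(events)
  eff <- character(nrow(events))
  for (r in seq_len(nrow(events))) {
    ev <- events[r]
    if (is.na(ev$gene_id) || ev$as_type == "UN") { eff[r] <- "unknown"; next }
    rep_tx <- .representative_tx(models, ev$gene_id)
    if (is.null(rep_tx)) { eff[r] <- "unknown"; next }
    cds <- models$cds[transcript_id == rep_tx$transcript_id]
    span <- c(min(cds$start), max(cds$end))
    regions <- .event_diff_regions(ev, index)
    in_span <- vapply(regions, function(rg) .overlap_len(rg, span) > 0L, TRUE)
    if (!any(in_span)) { eff[r] <- "noncoding"; next }
    if (ev$as_type %in% c("AFE", "ALE")) { eff[r] <- "coding-disruptive"; next }
    start_codon <- if (rep_tx$strand == "-")
      c(span[2] - 2L, span[2]) else c(span[1], span[1] + 2L)
    touches_start <- any(vapply(regions, function(rg)
      .overlap_len(rg, start_codon) > 0L, TRUE))
    if (ev$as_type == "IR") {
      delta <- ev$excl_end - ev$excl_start + 1L
    } else if (ev$as_type == "MXE") {
      # each alternative exon is coding in its own host transcript
      gene_cds <- models$cds[transcript_id %in%
        models$transcripts[gene_id == ev$gene_id & frame_ok == TRUE,
                           transcript_id]]
      lens <- vapply(regions, function(rg) {
        ov <- vapply(seq_len(nrow(gene_cds)), function(i)
          .overlap_len(rg, c(gene_cds$start[i], gene_cds$end[i])), 0L)
        if (length(ov)) max(ov) else 0L
      }, 0L)
      eff[r] <- if (abs(lens[1] - lens[2]) %% 3L == 0L) "in-frame"
        else "coding-disruptive"
      next
    } else {
      delta <- sum(vapply(regions, function(rg) sum(vapply(seq_len(nrow(cds)),
        function(i) .overlap_len(rg, c(cds$start[i], cds$end[i])), 0L)), 0L))
    }
    eff[r] <- if (touches_start) "coding-disruptive"
      else if (delta == 0L) "noncoding"
      else if (delta %% 3L == 0L) "in-frame"
      else "coding-disruptive"
  }
  events[, coding_effect := eff]
  events[]
}

# exon chains (lists of genomic intervals, ascending) for the inclusion
# and exclusion isoforms of an event, patched onto a representative chain
.event_isoform_chains <- function(ev, rep_exons) {
  span <- c(ev$excl_start, ev$excl_end)
  incl_introns <- switch(ev$as_type,
    CE = list(c(ev$i1_start, ev$i1_end), c(ev$i2_start, ev$i2_end)),
    IR = list(),
    list(c(ev$i1_start, ev$i1_end)))
  rep_pos <- unlist(lapply(rep_exons, function(iv) seq.int(iv[1], iv[2])))
  outside <- rep_pos[rep_pos < span[1] | rep_pos > span[2]]
  span_pos <- seq.int(span[1], span[2])
  chain_of <- function(introns) {
    dropped <- unlist(lapply(introns, function(iv) seq.int(iv[1], iv[2])))
    .positions_to_intervals(sort(c(outside, setdiff(span_pos, dropped))))
  }
  list(inclusion = chain_of(incl_introns),
       exclusion = chain_of(list(span)))
}

# translate a genomic exon chain from a start-codon anchor; strand-aware
.translate_event_chain <- function(chain, anchor, strand, genome, chrom) {
  pos <- unlist(lapply(chain, function(iv) seq.int(iv[1], iv[2])))
  tlens <- vapply(chain, function(iv) iv[2] - iv[1] + 1L, 0L)
  if (strand == "-") { pos <- rev(pos); tlens <- rev(tlens) }
  ai <- match(anchor, pos)
  if (is.na(ai)) return(NULL)
  total_len <- length(pos)
  cpos <- pos[ai:total_len]
  cpos <- cpos[seq_len(3L * (length(cpos) %/% 3L))]
  if (length(cpos) < 3L) return(NULL)
  bases <- strsplit(as.character(genome[[chrom]]), "")[[1L]][cpos]
  if (strand == "-") bases <- unname(.COMP[bases])
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(bases, collapse = "")),
    if.fuzzy.codon = "solve"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  has_stop <- stop_at > 0L
  stop_end_tpos <- if (has_stop) (ai - 1L) + 3L * stop_at else NA_integer_
  list(aa = if (has_stop) substr(aa, 1L, stop_at - 1L) else aa,
       has_stop = has_stop, stop_end_tpos = stop_end_tpos,
       last_junction_tpos = total_len - tlens[length(tlens)],
       n_exons = length(tlens))
}

# which isoform side of the event differs from the representative chain
.altered_side <- function(chains, rep_exons) {
  key <- function(ch) paste(vapply(ch, function(iv) paste(iv, collapse = "-"), ""),
                            collapse = ";")
  rep_key <- key(rep_exons[order(vapply(rep_exons, `[`, 0, 1))])
  if (key(chains$inclusion) == rep_key) "exclusion"
  else if (key(chains$exclusion) == rep_key) "inclusion"
  else NA_character_
}

.rep_chain <- function(models, tid) {
  ex <- models$exons[transcript_id == tid][order(start)]
  lapply(seq_len(nrow(ex)), function(i) c(ex$start[i], ex$end[i]))
}

#' Predict nonsense-mediated decay by the 50-nt rule
#'
#' For CDS-altering CE, A5SS, A3SS and IR events, the isoform differing
#' from the representative transcript (longest CDS in the gene) is rebuilt
#' and translated from the annotated start codon.  The event is predicted
#' to trigger NMD when translation terminates more than 50 nt upstream of
#' the final exon-exon junction of that isoform; a stop in the last exon
#' (or no premature stop at all) is NMD-negative.  Other event types, and
#' events without a coding change, return `NA` (not applicable).
#'
#' @param events Event table with `coding_effect` filled in.
#' @param index A `boundary_index`.
#' @param genome A `DNAStringSet` from [load_genome()].
#' @return The event table with an `nmd` logical column.
#' @export
predict_nmd <- function(events, index, genome) {
  models <- index$models
  events <- as.data.table(events)
  nmd <- rep(NA, nrow(events))
  for (r in seq_len(nrow(events))) {
    ev <- events[r]
    if (!ev$as_type %in% c("CE", "A5SS", "A3SS", "IR")) next
    if (!identical(ev$coding_effect, "coding-disruptive") &&
        !identical(ev$coding_effect, "in-frame")) next
    rep_tx <- .representative_tx(models, ev$gene_id)
    if (is.null(rep_tx)) next
    rep_exons <- .rep_chain(models, rep_tx$transcript_id)
    cds <- models$cds[transcript_id == rep_tx$transcript_id]
    anchor <- if (rep_tx$strand == "-") max(cds$end) else min(cds$start)
    chains <- .event_isoform_chains(ev, rep_exons)
    side <- .altered_side(chains, rep_exons)
    if (is.na(side)) next
    tr <- .translate_event_chain(chains[[side]], anchor, rep_tx$strand,
                                 genome, ev$chrom)
    if (is.null(tr)) next
    nmd[r] <- tr$has_stop &&
      (tr$last_junction_tpos - tr$stop_end_tpos) > 50L
  }
  events[, nmd := nmd]
  events[]
}

#' Detect, classify and annotate splicing events from junction data
#'
#' Orchestrates the junction-based detection chain: support filtering,
#' candidate pairing, classification, suppression of junction patterns
#' already explained by annotation-defined MXE events, annotation-defined
#' IR and MXE detection, optional blacklist filtering, and (when a genome
#' is supplied) coding-effect and NMD annotation.
#'
#' @param junctions Per-cell junction table from [extract_junctions()].
#' @param index A `boundary_index`.
#' @param min_reads Minimum total junction support (default 10).
#' @param blacklist Optional blacklist intervals ([build_blacklist()]).
#' @param genome Optional `DNAStringSet` for coding/NMD annotation.
#' @return data.table of annotated events.
#' @export
detect_events <- function(junctions, index, min_reads = 10L,
                          blacklist = NULL, genome = NULL) {
  models <- index$models
  totals <- junction_totals(filter_min_support(junctions, min_reads))
  cands <- detect_junction_events(totals)
  events <- classify_event(cands, index)
  mxe <- detect_annotated_mxe(models, totals)
  ir <- detect_annotated_ir(models, totals)

  if (nrow(mxe) && nrow(events)) {
    mxe_jx <- unique(unlist(lapply(seq_len(nrow(mxe)), function(i)
      .mxe_junction_set(mxe[i], models))))
    jkey <- function(s, e) paste0(s, "-", e)
    covered <- events[, jkey(excl_start, excl_end) %in% mxe_jx &
                        jkey(i1_start, i1_end) %in% mxe_jx]
    covered[is.na(covered)] <- FALSE
    events <- events[!(covered & as_type != "CE")]
  }
  events <- rbind(events, mxe, ir)
  if (!is.null(blacklist)) events <- apply_region_blacklist(events, blacklist)
  events <- classify_coding_effect(events, index)
  if (!is.null(genome)) events <- predict_nmd(events, index, genome)
  setorder(events, chrom, excl_start, excl_end, as_type)
  unique(events)
}
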