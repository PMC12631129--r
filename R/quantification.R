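# Inclusion/exclusion counting per event per cell, aggregation, and PSI
# with exact Clopper-Pearson confidence intervals.

#' Count inclusion and exclusion molecules per event per cell
#'
#' Exclusion counts come from the exclusion junction.  Inclusion counts:
#' for CE, from the single inclusion junction with the larger pooled count
#' (the same junction for every cell, so PSI stays comparable across
#' cells; ties broken by smaller intron, then leftmost); for A5SS, A3SS,
#' AFE, ALE, MXE and UN from the single inclusion junction (for AFE/ALE
#' the proximal junction); for IR, per cell, the maximum of the two
#' exon-intron boundary span counts.  Rows with zero total are omitted.
#'
#' @param events Event table from [detect_events()].
#' @param junctions Per-cell junction table ([extract_junctions()]).
#' @param spans Per-cell boundary-span table ([count_boundary_spans()]),
#'   required when IR events are present.
#' @return data.table event_id, cell, I, E.
#' @export
count_events <- function(events, junctions, spans = NULL) {
  events <- as.data.table(events)
  junctions <- as.data.table(junctions)
  totals <- junction_totals(junctions)
  out <- vector("list", nrow(events))
  jx_cells <- function(s, e, ch) {
    junctions[chrom == ch & start == s & end == e, .(cell, n = count)]
  }
  for (r in seq_len(nrow(events))) {
    ev <- events[r]
    Ecounts <- jx_cells(ev$excl_start, ev$excl_end, ev$chrom)
    if (ev$as_type == "IR") {
      if (is.null(spans)) stop("IR events need boundary span counts")
      sp <- as.data.table(spans)[chrom == ev$chrom &
                                 pos %in% c(ev$ir_site1, ev$ir_site2)]
      Icounts <- if (nrow(sp) == 0L)
        data.table(cell = character(), n = integer())
      else sp[, .(n = max(count)), by = cell]
    } else if (ev$as_type == "CE") {
      t1 <- totals[chrom == ev$chrom & start == ev$i1_start & end == ev$i1_end]
      t2 <- totals[chrom == ev$chrom & start == ev$i2_start & end == ev$i2_end]
      n1 <- if (nrow(t1)) t1$total else 0L
      n2 <- if (nrow(t2)) t2$total else 0L
      w1 <- ev$i1_end - ev$i1_start; w2 <- ev$i2_end - ev$i2_start
      use1 <- (n1 > n2) || (n1 == n2 && (w1 < w2 ||
                (w1 == w2 && ev$i1_start <= ev$i2_start)))
      Icounts <- if (use1) jx_cells(ev$i1_start, ev$i1_end, ev$chrom)
        else jx_cells(ev$i2_start, ev$i2_end, ev$chrom)
    } else {
      Icounts <- jx_cells(ev$i1_start, ev$i1_end, ev$chrom)
    }
    m <- merge(setnames(copy(Icounts), "n", "I"),
               setnames(copy(Ecounts), "n", "E"),
               by = "cell", all = TRUE)
    m[is.na(I), I := 0L][is.na(E), E := 0L]
    m <- m[I + E >= 1L]
    if (nrow(m)) out[[r]] <- cbind(event_id = ev$event_id, m)
  }
  res <- rbindlist(out[!vapply(out, is.null, TRUE)])
  if (nrow(res) == 0L)
    return(data.table(event_id = character(), cell = character(),
                      I = integer(), E = integer()))
  setorder(res, event_id, cell)
  res[]
}

#' Aggregate per-cell counts to group resolution
#'
#' @param table data.table event_id, cell, I, E.
#' @param grouping data.frame/table with columns cell, group (cells not
#'   covered are dropped with a warning).
#' @return data.table event_id, group, I, E with I and E summed per group.
#' @export
aggregate_counts <- function(table, grouping) {
  table <- as.data.table(table)
  grouping <- as.data.table(grouping)[, .(cell, group)]
  missing <- setdiff(unique(table$cell), grouping$cell)
  if (length(missing))
    warning(length(missing), " counted cells missing from grouping; dropped")
  m <- merge(table, grouping, by = "cell")
  m[, .(I = sum(I), E = sum(E)), by = .(event_id, group)][order(event_id, group)]
}

#' PSI with an exact binomial confidence interval
#'
#' PSI = I / (I + E).  The interval is the exact two-sided Clopper-Pearson
#' interval for I successes in I + E trials (the interval reported by
#' `binom.test`), computed from beta quantiles.
#'
#' @param I,E Non-negative integer vectors (recycled); I + E must be >= 1.
#' @param conf_level Confidence level (default 0.95).
#' @return data.table I, E, psi, ci_low, ci_high.
#' @export
compute_psi <- function(I, E, conf_level = 0.95) {
  n <- I + E
  if (any(n < 1L)) stop("PSI undefined: I + E must be >= 1")
  alpha <- 1 - conf_level
  low <- ifelse(I == 0, 0, stats::qbeta(alpha / 2, I, E + 1))
  high <- ifelse(E == 0, 1, stats::qbeta(1 - alpha / 2, I + 1, E))
  data.table(I = I, E = E, psi = I / n, ci_low = low, ci_high = high)
}
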