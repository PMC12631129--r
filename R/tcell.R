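# T-cell splicing indices: the between-subtype splicing distance on
# logit-transformed rescaled PSIs, and the per-sample splicing similarity
# score along a subtype axis.

.logit <- function(p) log(p / (1 - p))

#' Splicing distance between cell subtypes
#'
#' For events covered in both subtypes of a pair, the PSI values are
#' linearly rescaled so that the per-event minimum and maximum across the
#' compared subtypes map to 0.01 and 0.99, logit-transformed, and the
#' distance is the Euclidean norm of the difference.  The rescaling keeps
#' the logit finite for boundary PSIs.
#'
#' @param psi_profiles data.table subtype, event_id, psi, n_reads.
#' @param min_reads Events require at least this many reads in both
#'   subtypes of a pair (default 5).
#' @return data.table subtype_a, subtype_b, distance, n_shared_events
#'   (symmetric pairs reported once, a < b).
#' @export
splicing_distance <- function(psi_profiles, min_reads = 5L) {
  pp <- as.data.table(psi_profiles)
  subtypes <- sort(unique(pp$subtype))
  if (length(subtypes) < 2L) stop("need at least 2 subtypes")
  out <- list()
  for (i in seq_along(subtypes)) for (j in seq_along(subtypes)) {
    if (i >= j) next
    a <- pp[subtype == subtypes[i] & n_reads >= min_reads]
    b <- pp[subtype == subtypes[j] & n_reads >= min_reads]
    m <- merge(a[, .(event_id, psi_a = psi)], b[, .(event_id, psi_b = psi)],
               by = "event_id")
    if (nrow(m) == 0L) stop("no shared events between ", subtypes[i], " and ",
                            subtypes[j])
    lo <- pmin(m$psi_a, m$psi_b); hi <- pmax(m$psi_a, m$psi_b)
    rescale <- function(p) ifelse(hi > lo,
                                  0.01 + (p - lo) / (hi - lo) * 0.98, 0.5)
    d <- .logit(rescale(m$psi_a)) - .logit(rescale(m$psi_b))
    out[[length(out) + 1L]] <- data.table(
      subtype_a = subtypes[i], subtype_b = subtypes[j],
      distance = sqrt(sum(d^2)), n_shared_events = nrow(m))
  }
  rbindlist(out)
}

#' Per-sample splicing similarity score along a subtype axis
#'
#' For each axis event l with anchor PSIs for subtypes A and B (A the
#' lower anchor; orientation is per event), the per-sample score is 0 at
#' or below the A anchor, 1 at or above the B anchor, and linear in
#' between.  The sample score is the mean over axis events with at least
#' `min_reads` reads in the sample; samples in which more than
#' `max_missing_fraction` of axis events fall below `min_reads` are
#' marked excluded.
#'
#' @param axis data.table event_id, psi_a, psi_b (anchors; rows with equal
#'   anchors are skipped with a warning).
#' @param sample_psi data.table sample_id, event_id, psi, n_reads.
#' @param min_reads Read floor per event per sample (default 5).
#' @param max_missing_fraction Exclusion threshold (default 1/3).
#' @return data.table sample_id, score, n_events_used, excluded.
#' @export
similarity_score <- function(axis, sample_psi, min_reads = 5L,
                             max_missing_fraction = 1 / 3) {
  axis <- as.data.table(axis)
  eq <- axis$psi_a == axis$psi_b
  if (any(eq)) {
    warning(sum(eq), " axis events with equal anchors skipped")
    axis <- axis[!eq]
  }
  if (nrow(axis) == 0L) stop("no usable axis events")
  sp <- as.data.table(sample_psi)
  n_axis <- nrow(axis)
  out <- list()
  for (s in unique(sp$sample_id)) {
    rows <- merge(axis, sp[sample_id == s], by = "event_id")
    low <- n_axis - nrow(rows[n_reads >= min_reads])
    used <- rows[n_reads >= min_reads]
    score <- if (nrow(used)) {
      lo <- pmin(used$psi_a, used$psi_b)
      hi <- pmax(used$psi_a, used$psi_b)
      sl <- pmin(pmax((used$psi - lo) / (hi - lo), 0), 1)
      # orientation: score measured toward the B anchor of each event
      sl <- ifelse(used$psi_a <= used$psi_b, sl, 1 - sl)
      mean(sl)
    } else NA_real_
    out[[length(out) + 1L]] <- data.table(
      sample_id = s, score = score, n_events_used = nrow(used),
      excluded = low / n_axis > max_missing_fraction)
  }
  rbindlist(out)
}
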