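# Empirical-Bayes beta-binomial machinery for inferred-PSI embedding:
# per-event prior fitting across sample x cell-type aggregates, posterior
# median PSI, and the splicing-information-destroying permutation null.

#' Filter events and units for embedding
#'
#' Units (sample x cell-type aggregates) must reach a minimum junction-read
#' total per sample and per sample-cell-type; events must be detected in a
#' minimum fraction of retained units.
#'
#' @param counts data.table event_id, sample_id, cell_type, I, E.
#' @param min_sample_reads Minimum junction reads per sample (default 1e6).
#' @param min_celltype_reads Minimum per sample x cell type (default 5000).
#' @param min_detection_fraction Minimum fraction of retained units in
#'   which an event has I + E >= 1 (default 0.8).
#' @return List with `counts` (filtered rows), `units` and `events` kept.
#' @export
filter_for_embedding <- function(counts, min_sample_reads = 1e6,
                                 min_celltype_reads = 5000,
                                 min_detection_fraction = 0.8) {
  counts <- as.data.table(counts)
  counts[, unit := paste(sample_id, cell_type, sep = "|")]
  sample_tot <- counts[, .(tot = sum(I + E)), by = sample_id]
  ok_samples <- sample_tot[tot >= min_sample_reads, sample_id]
  unit_tot <- counts[sample_id %in% ok_samples,
                     .(tot = sum(I + E)), by = .(sample_id, cell_type, unit)]
  ok_units <- unit_tot[tot >= min_celltype_reads, unit]
  kept <- counts[unit %in% ok_units]
  if (nrow(kept) == 0L) stop("no units pass the embedding coverage filters")
  n_units <- length(unique(kept$unit))
  det <- kept[I + E >= 1L, .(frac = uniqueN(unit) / n_units), by = event_id]
  ok_events <- det[frac >= min_detection_fraction, event_id]
  if (length(ok_events) == 0L) stop("no events pass the detection-fraction filter")
  list(counts = kept[event_id %in% ok_events],
       units = sort(unique(kept$unit)), events = sort(ok_events))
}

# beta-binomial log-likelihood of (I, I+E) pairs
.bb_loglik <- function(a, b, I, n) {
  sum(lchoose(n, I) + lbeta(a + I, b + n - I) - lbeta(a, b))
}

#' Fit a beta-binomial prior for one event across units
#'
#' Maximizes the beta-binomial likelihood of the observed (I, I + E) pairs
#' over the shape parameters, starting from a method-of-moments estimate,
#' with shapes bounded to (1e-3, 1e6).  Degenerate data (all PSI pinned at
#' 0 or 1) yield a prior clamped at the bound, flagged.
#'
#' @param I,E Integer vectors over units (>= 3 units with I + E >= 1).
#' @return List with `a`, `b`, `clamped` (logical), `loglik`.
#' @export
fit_beta_prior <- function(I, E) {
  keep <- (I + E) >= 1L
  I <- I[keep]; E <- E[keep]
  if (length(I) < 3L) stop("need at least 3 units with coverage to fit a prior")
  n <- I + E
  p <- I / n
  lower <- 1e-3; upper <- 1e6
  m <- mean(p); v <- stats::var(p)
  if (is.na(v) || v <= 0 || m <= 0 || m >= 1) {
    a0 <- b0 <- 1
  } else {
    k <- max(m * (1 - m) / v - 1, 0.1)
    a0 <- max(min(m * k, upper), lower)
    b0 <- max(min((1 - m) * k, upper), lower)
  }
  nll <- function(par) -.bb_loglik(exp(par[1]), exp(par[2]), I, n)
  fit <- stats::optim(log(c(a0, b0)), nll, method = "L-BFGS-B",
                      lower = log(lower), upper = log(upper))
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  clamped <- a <= lower * 1.0001 || a >= upper * 0.9999 ||
             b <= lower * 1.0001 || b >= upper * 0.9999
  list(a = a, b = b, clamped = clamped, loglik = -fit$value)
}

#' Fit beta-binomial priors for all events
#'
#' @param counts data.table event_id, unit (or sample_id/cell_type), I, E.
#' @return data.table event_id, a, b, clamped.
#' @export
fit_beta_priors <- function(counts) {
  counts <- as.data.table(counts)
  counts[, .(res = list(fit_beta_prior(I, E))), by = event_id][
    , .(event_id, a = vapply(res, `[[`, 0, "a"),
        b = vapply(res, `[[`, 0, "b"),
        clamped = vapply(res, `[[`, TRUE, "clamped"))]
}

#' Posterior-median inferred PSI
#'
#' The posterior of the PSI under a Beta(a, b) prior and observed (I, E)
#' is Beta(a + I, b + E); its median is the inferred PSI.  With I = E = 0
#' the prior median is returned (imputation).
#'
#' @param a,b Prior shapes (vectors recycled).
#' @param I,E Observed counts.
#' @return Numeric vector of posterior medians in (0, 1).
#' @export
posterior_psi <- function(a, b, I = 0, E = 0) {
  stats::qbeta(0.5, a + I, b + E)
}

#' Permute counts under the fitted prior, preserving totals
#'
#' For each row, draws p ~ Beta(a, b) and I' ~ Binomial(I + E, p), so that
#' splicing-ratio information is destroyed while every total I + E (and
#' hence the coverage structure) is preserved exactly.
#'
#' @param counts data.table with event_id, I, E (plus any unit columns).
#' @param priors data.table event_id, a, b from [fit_beta_priors()].
#' @param seed Integer seed.
#' @return Copy of `counts` with permuted I and E.
#' @export
permute_counts <- function(counts, priors, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- copy(as.data.table(counts))
  m <- merge(counts, as.data.table(priors)[, .(event_id, a, b)],
             by = "event_id", sort = FALSE)
  n <- m$I + m$E
  p <- stats::rbeta(nrow(m), m$a, m$b)
  Inew <- stats::rbinom(nrow(m), n, p)
  Inew[n == 0L] <- 0L
  m[, `:=`(I = Inew, E = n - Inew, a = NULL, b = NULL)]
  m[]
}

#' Build the inferred-PSI matrix for embedding
#'
#' @param counts data.table event_id, unit, I, E (one row per event x
#'   unit; missing pairs are imputed with the prior median).
#' @param priors data.table event_id, a, b.
#' @return Numeric matrix, rows = units, columns = events, values =
#'   posterior-median PSI in [0, 1]; no missing values.
#' @export
build_psi_matrix <- function(counts, priors) {
  counts <- as.data.table(counts)
  priors <- as.data.table(priors)
  units <- sort(unique(counts$unit))
  events <- sort(unique(counts$event_id))
  grid <- CJ(unit = units, event_id = events)
  m <- merge(grid, counts[, .(event_id, unit, I, E)],
             by = c("unit", "event_id"), all.x = TRUE)
  m[is.na(I), I := 0L][is.na(E), E := 0L]
  m <- merge(m, priors[, .(event_id, a, b)], by = "event_id")
  m[, psi := posterior_psi(a, b, I, E)]
  mat <- matrix(NA_real_, length(units), length(events),
                dimnames = list(units, events))
  mat[cbind(match(m$unit, units), match(m$event_id, events))] <- m$psi
  stopifnot(!anyNA(mat))
  mat
}
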