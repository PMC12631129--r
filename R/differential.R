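# Cell-type / group-specific splicing: coverage and noise filters,
# binomial-GLM likelihood-ratio tests, BH correction, and
# expression-matched Fisher enrichment tests.

#' Coverage filter for differential testing
#'
#' Events are retained when the pooled inclusion and the pooled exclusion
#' read counts are each at least `min_total`, and each group's junction
#' read total is at least `min_total`.
#'
#' @param counts data.table event_id, group, I, E (two groups).
#' @param min_total Minimum count (default 10).
#' @return Character vector of retained event ids.
#' @export
coverage_filter <- function(counts, min_total = 10L) {
  counts <- as.data.table(counts)
  s <- counts[, .(I = sum(I), E = sum(E)), by = event_id]
  g <- counts[, .(tot = sum(I + E)), by = .(event_id, group)]
  gmin <- g[, .(gmin = min(tot), ngroups = .N), by = event_id]
  ok <- merge(s, gmin, by = "event_id")
  ok[I >= min_total & E >= min_total & gmin >= min_total & ngroups >= 2L,
     sort(event_id)]
}

#' Splicing-noise filter on group confidence intervals
#'
#' With H and L the upper and lower bounds of each group's 95% PSI
#' confidence interval, an event passes only if all four conditions hold:
#' (L_A > 0.05 or L_B > 0.05), (H_A < 0.95 or H_B < 0.95),
#' (L_A > 0.05 or H_A < 0.95), and (L_B > 0.05 or H_B < 0.95) -- i.e.
#' neither alternative isoform is mere splicing noise in both groups.
#'
#' @param l_a,h_a,l_b,h_b Bounds of the two groups' intervals (vectors).
#' @param lo,hi Noise thresholds (defaults 0.05 and 0.95).
#' @return Logical vector.
#' @export
noise_filter <- function(l_a, h_a, l_b, h_b, lo = 0.05, hi = 0.95) {
  (l_a > lo | l_b > lo) &
  (h_a < hi | h_b < hi) &
  (l_a > lo | h_a < hi) &
  (l_b > lo | h_b < hi)
}

#' Binomial-GLM likelihood-ratio test for one event
#'
#' Fits nested binomial regressions with logit link on per-observation
#' (I, E) rows: H1 regresses on sample + group (or group alone when no
#' sample covariate is given, H0 then being intercept-only) and H0 omits
#' the group term.  The p-value is the upper chi-square tail of the
#' deviance difference with df equal to the extra parameters in H1.
#' Delta-PSI is computed from pooled counts per group.  Complete
#' separation (a group entirely at PSI 0 or 1) is handled by adding 0.5 to
#' every cell of the separated event and flagging the result.
#'
#' @param I,E Integer vectors (one element per observation row).
#' @param group Two-level factor.
#' @param sample Optional factor of sample ids (the H0 covariate).
#' @param drop_empty Drop rows with I + E = 0 (default TRUE).
#' @return List p_value, delta_psi (group level 1 minus level 2), df,
#'   deviance_h0, deviance_h1, separation (logical).
#' @export
glm_lrt <- function(I, E, group, sample = NULL, drop_empty = TRUE) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  keep <- if (drop_empty) (I + E) > 0L else rep(TRUE, length(I))
  I <- I[keep]; E <- E[keep]; group <- droplevels(group[keep])
  if (!is.null(sample)) sample <- droplevels(as.factor(sample)[keep])
  if (nlevels(group) != 2L) stop("a group lost all observations")

  gi <- split(seq_along(I), group)
  pooled <- vapply(gi, function(ix) c(sum(I[ix]), sum(E[ix])), c(0, 0))
  delta_psi <- unname(pooled[1, 1] / sum(pooled[, 1]) -
                      pooled[1, 2] / sum(pooled[, 2]))
  separation <- any(pooled[1, ] == 0) || any(pooled[2, ] == 0)
  Iu <- I; Eu <- E
  if (separation) { Iu <- I + 0.5; Eu <- E + 0.5 }

  fit_pair <- function(f1, f0, dat) {
    h1 <- suppressWarnings(stats::glm(f1, family = stats::binomial(), data = dat))
    h0 <- suppressWarnings(stats::glm(f0, family = stats::binomial(), data = dat))
    list(h1 = h1, h0 = h0)
  }
  dat <- data.frame(I = Iu, E = Eu, group = group)
  if (is.null(sample)) {
    fits <- fit_pair(cbind(I, E) ~ group, cbind(I, E) ~ 1, dat)
  } else {
    dat$sample <- sample
    fits <- fit_pair(cbind(I, E) ~ sample + group, cbind(I, E) ~ sample, dat)
  }
  if (any(is.na(stats::coef(fits$h1))))
    stop("singular design; aliased coefficients: ",
         paste(names(stats::coef(fits$h1))[is.na(stats::coef(fits$h1))],
               collapse = ", "))
  dev_diff <- fits$h0$deviance - fits$h1$deviance
  df <- fits$h0$df.residual - fits$h1$df.residual
  p <- stats::pchisq(max(dev_diff, 0), df = df, lower.tail = FALSE)
  list(p_value = p, delta_psi = delta_psi, df = df,
       deviance_h0 = fits$h0$deviance, deviance_h1 = fits$h1$deviance,
       separation = separation)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of p-values.
#' @return FDR values (standard step-up with monotonicity enforcement).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Flag specific (differentially spliced) events
#'
#' @param results data.table with fdr and delta_psi columns.
#' @param fdr_cut FDR threshold (default 0.01).
#' @param dpsi_cut |delta PSI| threshold (default 0.2).
#' @return `results` with a logical `specific` column.
#' @export
call_specific <- function(results, fdr_cut = 0.01, dpsi_cut = 0.2) {
  results <- as.data.table(results)
  results[, specific := fdr < fdr_cut & abs(delta_psi) > dpsi_cut]
  results[]
}

#' Differential splicing across events
#'
#' Runs [coverage_filter()], the [noise_filter()] on pooled group
#' confidence intervals, [glm_lrt()] per event, BH adjustment and the
#' specificity call.
#'
#' @param counts data.table event_id, sample_id, group, I, E (one row per
#'   event x sample x group).
#' @param min_total Coverage threshold (default 10).
#' @param fdr_cut,dpsi_cut Specificity thresholds (defaults 0.01, 0.2).
#' @param use_sample_covariate Include the sample term in the GLM (default
#'   TRUE when more than one sample is present).
#' @return data.table event_id, psi_a, psi_b, delta_psi, p_value, fdr,
#'   separation, specific.
#' @export
diff_splicing <- function(counts, min_total = 10L, fdr_cut = 0.01,
                          dpsi_cut = 0.2, use_sample_covariate = NULL) {
  counts <- as.data.table(counts)
  keep <- coverage_filter(counts[, .(event_id, group, I, E)], min_total)
  counts <- counts[event_id %in% keep]
  if (nrow(counts) == 0L) return(data.table())
  pooled <- counts[, .(I = sum(I), E = sum(E)), by = .(event_id, group)]
  ci <- cbind(pooled, compute_psi(pooled$I, pooled$E)[, .(psi, ci_low, ci_high)])
  wide <- dcast(ci, event_id ~ group, value.var = c("psi", "ci_low", "ci_high"))
  gl <- sort(unique(as.character(counts$group)))
  pass <- noise_filter(wide[[paste0("ci_low_", gl[1])]],
                       wide[[paste0("ci_high_", gl[1])]],
                       wide[[paste0("ci_low_", gl[2])]],
                       wide[[paste0("ci_high_", gl[2])]])
  keep2 <- wide$event_id[pass]
  counts <- counts[event_id %in% keep2]
  if (nrow(counts) == 0L) return(data.table())
  if (is.null(use_sample_covariate))
    use_sample_covariate <- length(unique(counts$sample_id)) > 1L
  res <- counts[, {
    g <- factor(group, levels = gl)
    fit <- glm_lrt(I, E, g,
                   sample = if (use_sample_covariate) sample_id else NULL)
    .(p_value = fit$p_value, delta_psi = fit$delta_psi,
      separation = fit$separation)
  }, by = event_id]
  pw <- dcast(ci, event_id ~ group, value.var = "psi")
  res <- merge(res, setnames(pw, c("event_id", "psi_a", "psi_b")),
               by = "event_id")
  res[, fdr := bh_adjust(p_value)]
  call_specific(res, fdr_cut, dpsi_cut)
}

#' Expression-matched one-tailed Fisher enrichment test
#'
#' Test and background genes are binned into expression deciles; the
#' background is down-sampled per bin to match the test genes' bin
#' distribution; each gene set is then tested for over-representation with
#' a one-tailed Fisher test, BH-corrected.
#'
#' @param test_genes,background_genes Character vectors (disjoint sets;
#'   overlap is removed from the background).
#' @param gene_sets Named list of character vectors.
#' @param expression Named numeric vector covering all genes.
#' @param n_bins Number of expression bins (default 10).
#' @param seed Integer seed for down-sampling.
#' @return data.table gene_set, odds_ratio, p_value, fdr, n_test_in_set.
#' @export
enrichment_test <- function(test_genes, background_genes, gene_sets,
                            expression, n_bins = 10L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  background_genes <- setdiff(background_genes, test_genes)
  all_genes <- c(test_genes, background_genes)
  if (!all(all_genes %in% names(expression)))
    stop("expression missing for some genes")
  br <- unique(stats::quantile(expression[all_genes],
                               probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(expression[all_genes], breaks = br, include.lowest = TRUE)
  names(bin) <- all_genes
  matched_bg <- character(0)
  n_test <- length(test_genes)
  for (b in levels(bin)) {
    tb <- test_genes[bin[test_genes] == b]
    if (length(tb) == 0L) next                      # empty test bin: skipped
    bb <- background_genes[bin[background_genes] == b]
    want <- round(length(tb) / n_test * length(background_genes))
    take <- min(length(bb), max(want, length(tb)))
    matched_bg <- c(matched_bg, if (length(bb) <= take) bb else
      sample(bb, take))
  }
  res <- rbindlist(lapply(names(gene_sets), function(gs) {
    set <- gene_sets[[gs]]
    a <- sum(test_genes %in% set)
    b <- n_test - a
    c_ <- sum(matched_bg %in% set)
    d <- length(matched_bg) - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = "greater")
    data.table(gene_set = gs, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, n_test_in_set = a)
  }))
  res[, fdr := bh_adjust(p_value)]
  res[]
}
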