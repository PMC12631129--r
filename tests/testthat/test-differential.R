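test_that("coverage filter enforces pooled and per-group read floors", {
  counts <- data.table(
    event_id = rep(c("e1", "e2", "e3"), each = 2L),
    group = rep(c("A", "B"), 3L),
    I = c(20L, 15L, 5L, 4L, 30L, 40L),
    E = c(12L, 18L, 50L, 50L, 2L, 100L))
  keep <- coverage_filter(counts, 10L)
  expect_setequal(keep, c("e1", "e3"))     # e2 dropped: pooled I = 9 < 10
  keep2 <- coverage_filter(counts, 0L)
  expect_setequal(keep2, c("e1", "e2", "e3"))
  # brute force over random tables
  set.seed(21)
  tab <- data.table(event_id = sample(paste0("e", 1:30), 60, TRUE),
                    group = rep(c("A", "B"), 30L),
                    I = rpois(60, 8), E = rpois(60, 8))
  tab <- tab[, .(I = sum(I), E = sum(E)), by = .(event_id, group)]
  got <- coverage_filter(tab, 10L)
  bf <- sapply(split(tab, tab$event_id), function(d)
    nrow(d) >= 2 && sum(d$I) >= 10 && sum(d$E) >= 10 &&
      all(tapply(d$I + d$E, d$group, sum) >= 10))
  expect_setequal(got, names(bf)[bf])
})

test_that("the four-condition noise filter equals exhaustive truth-table evaluation", {
  # all 16 configurations of (L_A>.05, H_A<.95, L_B>.05, H_B<.95)
  grid <- expand.grid(la = c(TRUE, FALSE), ha = c(TRUE, FALSE),
                      lb = c(TRUE, FALSE), hb = c(TRUE, FALSE))
  l_of <- function(flag) if (flag) 0.2 else 0.0
  h_of <- function(flag) if (flag) 0.8 else 1.0
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    got <- noise_filter(l_of(g$la), h_of(g$ha), l_of(g$lb), h_of(g$hb))
    want <- (g$la || g$lb) && (g$ha || g$hb) &&
            (g$la || g$ha) && (g$lb || g$hb)
    expect_identical(got, want, info = paste(unlist(g), collapse = ","))
  }
  # both groups pinned near 0 fail condition 1; opposite extremes are a
  # genuine splicing difference and pass all four conditions
  expect_false(noise_filter(0, 0.04, 0, 0.03))
  expect_true(noise_filter(0, 0.03, 0.97, 1))
  expect_true(noise_filter(0.1, 0.9, 0.2, 0.8))
})

test_that("GLM deviance differences match grid-refined likelihood maximization", {
  # two-group comparison without covariate
  I <- c(18L, 22L, 5L, 7L); E <- c(6L, 9L, 21L, 19L)
  g <- c("A", "A", "B", "B")
  fit <- glm_lrt(I, E, g)
  bf <- bf_devdiff_2group(I, E, g)
  expect_equal(fit$deviance_h0 - fit$deviance_h1, bf, tolerance = 1e-6)
  # sample + group design on a 2-sample, 2-group toy
  I2 <- c(15L, 9L, 20L, 6L); E2 <- c(5L, 11L, 10L, 14L)
  s2 <- c("s1", "s1", "s2", "s2"); g2 <- c("A", "B", "A", "B")
  fit2 <- glm_lrt(I2, E2, g2, sample = s2)
  bf2 <- bf_devdiff_covariate(I2, E2, s2, g2)
  expect_equal(fit2$deviance_h0 - fit2$deviance_h1, bf2, tolerance = 1e-6)
  expect_equal(fit2$df, 1L)
})

test_that("GLM p-values and delta-PSI behave at the null and under label swap", {
  I <- c(10L, 12L, 10L, 12L); E <- c(10L, 8L, 10L, 8L)
  g <- c("A", "A", "B", "B")
  fit <- glm_lrt(I, E, g)
  expect_gt(fit$p_value, 0.99)
  expect_equal(fit$delta_psi, 0)
  # swapping labels flips the sign of delta-PSI, keeps p
  ga <- c("A", "B", "A", "B"); I2 <- c(18L, 3L, 16L, 4L); E2 <- c(2L, 17L, 4L, 16L)
  f1 <- glm_lrt(I2, E2, ga)
  f2 <- glm_lrt(I2, E2, ifelse(ga == "A", "B", "A"))
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-9)
  expect_equal(f1$delta_psi, -f2$delta_psi)
  # separation is flagged and still yields a finite p
  fs <- glm_lrt(c(0L, 0L, 9L, 11L), c(10L, 12L, 1L, 0L), g)
  expect_true(fs$separation)
  expect_true(is.finite(fs$p_value))
})

test_that("type-I error is calibrated and power reaches the target", {
  set.seed(12)
  pv <- replicate(200, {
    n <- 20L; cov <- stats::rpois(2L * n, 50)
    I <- stats::rbinom(2L * n, cov, 0.5); E <- cov - I
    glm_lrt(I, E, rep(c("A", "B"), each = n))$p_value
  })
  frac <- mean(pv < 0.05)
  expect_lt(abs(frac - 0.05), 2.58 * sqrt(0.05 * 0.95 / 200) + 1e-9)
  set.seed(13)
  res <- rbindlist(lapply(1:200, function(e) {
    n <- 20L; cov <- stats::rpois(2L * n, 50)
    I <- stats::rbinom(2L * n, cov, rep(c(0.35, 0.65), each = n)); E <- cov - I
    fit <- glm_lrt(I, E, rep(c("A", "B"), each = n))
    data.table(p_value = fit$p_value, delta_psi = fit$delta_psi)
  }))
  res[, fdr := bh_adjust(p_value)]
  res <- call_specific(res)
  expect_gt(mean(res$specific), 0.8)
})

test_that("BH adjustment and the specificity call follow the stated rules", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(rep(1, 5L)), rep(1, 5L))
  res <- data.table(fdr = c(0.005, 0.005, 0.02),
                    delta_psi = c(0.25, 0.15, 0.5))
  out <- call_specific(res)
  expect_equal(out$specific, c(TRUE, FALSE, FALSE))
})

test_that("diff_splicing flags the planted cancer-specific events on the fixture", {
  units <- get_units()
  counts <- units[, .(event_id, sample_id, group = cell_type, I, E)]
  res <- diff_splicing(counts, min_total = 10L)
  fx <- get_fixture()
  planted <- fx$manifest$event_table[abs(psi_T_cell - psi_cancer) > 0.2,
                                     event_id]
  flat <- fx$manifest$event_table[psi_T_cell == psi_cancer, event_id]
  expect_true(all(planted %in% res[specific == TRUE, event_id]))
  expect_false(any(flat %in% res[specific == TRUE, event_id]))
})

test_that("expression-matched enrichment finds planted sets and stays null otherwise", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:500)
  expr <- stats::setNames(stats::rlnorm(500, 3, 1), genes)
  sets <- list(S1 = genes[1:60], S2 = genes[201:260], S3 = genes[301:360])
  # planted enrichment: test genes drawn from S1
  test_genes <- sample(sets$S1, 30L)
  bg <- setdiff(genes, test_genes)
  res <- enrichment_test(test_genes, bg, sets, expr, seed = 2)
  expect_lt(res[gene_set == "S1", p_value], 0.05)
  expect_gt(res[gene_set == "S1", odds_ratio], 1)
  # null: test genes are a random expression-matched sample
  null_hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    tg <- sample(genes, 30L)
    r <- enrichment_test(tg, setdiff(genes, tg), sets, expr, seed = s)
    any(r$fdr < 0.05)
  }, TRUE)
  expect_lte(mean(null_hits), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 20))
})
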