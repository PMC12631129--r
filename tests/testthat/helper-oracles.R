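# Independent oracles, deliberately naive: brute-force scans, grid-refined
# likelihood maximization, root-finding on binomial tails.

# all donor/acceptor splice sites by scanning every consecutive exon pair
bf_boundary_sites <- function(models) {
  ex <- as.data.table(models$exons)
  donors <- list(); acceptors <- list()
  for (tid in unique(ex$transcript_id)) {
    e <- ex[transcript_id == tid][order(start)]
    if (nrow(e) < 2L) next
    for (k in seq_len(nrow(e) - 1L)) {
      if (e$strand[1] == "+") {
        donors[[length(donors) + 1L]] <-
          data.table(chrom = e$chrom[1], strand = "+", pos = e$end[k])
        acceptors[[length(acceptors) + 1L]] <-
          data.table(chrom = e$chrom[1], strand = "+", pos = e$start[k + 1L])
      } else {
        donors[[length(donors) + 1L]] <-
          data.table(chrom = e$chrom[1], strand = "-", pos = e$start[k + 1L])
        acceptors[[length(acceptors) + 1L]] <-
          data.table(chrom = e$chrom[1], strand = "-", pos = e$end[k])
      }
    }
  }
  list(donors = unique(rbindlist(donors)),
       acceptors = unique(rbindlist(acceptors)))
}

# Clopper-Pearson bounds by root-finding on binomial tail probabilities
# (no beta quantiles anywhere)
bf_cp_interval <- function(I, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (I == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(I - 1L, n, p, lower.tail = FALSE) -
                     alpha / 2, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (I == n) 1 else
    stats::uniroot(function(p) stats::pbinom(I, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# binomial log-likelihood without constants (they cancel in differences)
.bf_ll <- function(I, E, p) sum(I * log(p) + E * log(1 - p))

# grid-refined maximization over per-group proportions vs one pooled
# proportion: deviance difference of the two-group binomial model
bf_devdiff_2group <- function(I, E, group) {
  refine <- function(f, lo, hi, rounds = 8L) {
    for (r in seq_len(rounds)) {
      g <- seq(lo, hi, length.out = 41L)
      v <- vapply(g, f, 0)
      k <- which.max(v)
      lo <- g[max(1L, k - 1L)]; hi <- g[min(41L, k + 1L)]
    }
    f((lo + hi) / 2)
  }
  gs <- split(seq_along(I), group)
  ll1 <- sum(vapply(gs, function(ix)
    refine(function(p) .bf_ll(I[ix], E[ix], p), 1e-9, 1 - 1e-9), 0))
  ll0 <- refine(function(p) .bf_ll(I, E, p), 1e-9, 1 - 1e-9)
  2 * (ll1 - ll0)
}

# grid-refined maximization of the logit-additive sample+group model
# against the sample-only model (toy sizes only)
bf_devdiff_covariate <- function(I, E, sample, group) {
  sample <- as.factor(sample); group <- as.factor(group)
  S <- nlevels(sample)
  ll_of <- function(pars, with_group) {
    eta <- pars[1] +
      ifelse(as.integer(sample) > 1L, pars[as.integer(sample)], 0)
    if (with_group) eta <- eta + ifelse(group == levels(group)[2L],
                                        pars[S + 1L], 0)
    p <- 1 / (1 + exp(-eta))
    .bf_ll(I, E, p)
  }
  refine_nd <- function(npar, with_group) {
    centre <- rep(0, npar); width <- 8
    best <- -Inf
    for (round in 1:14) {
      grid <- lapply(seq_len(npar), function(i)
        seq(centre[i] - width, centre[i] + width, length.out = 7L))
      combos <- as.matrix(do.call(expand.grid, grid))
      vals <- apply(combos, 1L, ll_of, with_group = with_group)
      k <- which.max(vals)
      centre <- combos[k, ]; best <- vals[k]
      width <- width / 2.5
    }
    best
  }
  2 * (refine_nd(S + 1L, TRUE) - refine_nd(S, FALSE))
}

# all k-mers of a string for k in kmin..kmax, by plain looping
bf_kmers <- function(aa, kmin = 8L, kmax = 11L) {
  out <- character(0)
  for (k in kmin:kmax) {
    if (nchar(aa) < k) next
    for (i in 1:(nchar(aa) - k + 1L)) out <- c(out, substr(aa, i, i + k - 1L))
  }
  unique(out)
}

# --- hand-constructed 50-nt-rule fixture ------------------------------------
# Six single-gene cases with engineered premature stops at controlled
# transcript distances from the final exon-exon junction of the exclusion
# isoform (exon lengths 120/98|99/99/99/300; CDS starts at +61).
make_nmd_fixture <- function() {
  window <- 1500L
  cases <- list(
    far      = list(L = 98L, stop_g = c(428, 430), expect = TRUE),
    d51      = list(L = 98L, stop_g = c(646, 648), expect = TRUE),
    d48      = list(L = 98L, stop_g = c(649, 651), expect = FALSE),
    d30      = list(L = 98L, stop_g = c(667, 669), expect = FALSE),
    lastexon = list(L = 98L, stop_g = c(960, 962), expect = FALSE),
    inframe  = list(L = 99L, stop_g = NULL, expect = FALSE)
  )
  glen <- length(cases) * window
  chars <- rep("A", glen)
  gtf_rows <- list(); ev_rows <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]; off <- (ci - 1L) * window
    gid <- sprintf("NMD%02d", ci); tid <- paste0(gid, ".A")
    exons <- list(c(1L, 120L), c(201L, 200L + cs$L), c(401L, 499L),
                  c(601L, 699L), c(801L, 1100L))
    cds <- list(c(61L, 120L), c(201L, 200L + cs$L), c(401L, 499L),
                c(601L, 699L), c(801L, if (cs$L == 98L) 1038L else 1037L))
    # lay GCT repeats along the spliced CDS (normal frame), ATG start,
    # TAA terminal stop
    gpos <- unlist(lapply(cds, function(iv) seq.int(iv[1], iv[2]))) + off
    fill <- strsplit(strrep("GCT", ceiling(length(gpos) / 3)), "")[[1]]
    chars[gpos] <- fill[seq_along(gpos)]
    chars[gpos[1:3]] <- c("A", "T", "G")
    n <- length(gpos)
    chars[gpos[(n - 2L):n]] <- c("T", "A", "A")
    if (!is.null(cs$stop_g))
      chars[(cs$stop_g[1]:cs$stop_g[2]) + off] <- c("T", "A", "A")
    for (iv in exons)
      gtf_rows[[length(gtf_rows) + 1L]] <- sprintf(
        "chrN\ttest\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
        iv[1] + off, iv[2] + off, gid, tid, gid)
    for (iv in cds)
      gtf_rows[[length(gtf_rows) + 1L]] <- sprintf(
        "chrN\ttest\tCDS\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
        iv[1] + off, iv[2] + off, gid, tid, gid)
    ev_rows[[length(ev_rows) + 1L]] <- data.table(
      event_id = paste0("CE:nmd:", names(cases)[ci]), as_type = "CE",
      chrom = "chrN", strand = "+", gene_id = gid,
      excl_start = 121L + off, excl_end = 400L + off,
      i1_start = 121L + off, i1_end = 200L + off,
      i2_start = 201L + cs$L + off, i2_end = 400L + off,
      ir_site1 = NA_integer_, ir_site2 = NA_integer_,
      mxe_incl_start = NA_integer_, mxe_incl_end = NA_integer_,
      mxe_excl_start = NA_integer_, mxe_excl_end = NA_integer_,
      novelty = "known", proximal_is_inclusion = NA, flag = NA_character_,
      expect_nmd = cs$expect)
  }
  gtf <- tempfile(fileext = ".gtf")
  writeLines(unlist(gtf_rows), gtf)
  models <- load_annotation(gtf, "primary_annotation")
  unlink(gtf)
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrN"
  list(models = models, index = build_boundary_index(models),
       genome = genome, events = rbindlist(ev_rows))
}
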