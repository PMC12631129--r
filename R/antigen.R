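# Tumor-antigen chain: atypical-isoform calling against normal references
# and stroma, translation of atypical isoforms into proteome-unique
# 8-11-mer peptides, external MHC rank integration, and the splice-derived
# tumor antigen burden (ATB).

# proportion of one isoform side
.side_prop <- function(I, E, side) if (side == "inclusion") I / (I + E) else E / (I + E)

.side_ci_low <- function(I, E, side, conf_level = 0.95) {
  x <- if (side == "inclusion") I else E
  ifelse(x == 0, 0, stats::qbeta((1 - conf_level) / 2, x, (I + E) - x + 1))
}

#' Call tumor-specific atypical isoforms against normal tissue references
#'
#' An event first passes a detectability gate in the tested cell type
#' (I >= 5, E >= 5, and both 95% CI bounds of the PSI inside
#' (`noise_lo`, `noise_hi`)).  An isoform side (inclusion or exclusion) is
#' then atypical when its proportion is at least `fold_mean` times the
#' mean proportion across normal tissues AND the Clopper-Pearson lower
#' bound of its proportion is at least `fold_max` times the proportion in
#' every individual normal tissue.
#'
#' @param cancer data.table event_id, I, E (pooled counts in the tested
#'   cells).
#' @param normals data.table tissue, event_id, I, E.
#' @param fold_mean,fold_max Fold thresholds (defaults 10 and 4).
#' @param min_count Detectability floor on I and E (default 5).
#' @param noise_lo,noise_hi CI noise bounds (defaults 0.05, 0.95).
#' @return data.table event_id, side, proportion, ci_low, mean_normal,
#'   max_normal for each atypical event-side.
#' @export
call_atypical_vs_normal <- function(cancer, normals, fold_mean = 10,
                                    fold_max = 4, min_count = 5L,
                                    noise_lo = 0.05, noise_hi = 0.95) {
  cancer <- as.data.table(cancer)
  normals <- as.data.table(normals)
  ci <- compute_psi(cancer$I, cancer$E)
  gate <- cancer$I >= min_count & cancer$E >= min_count &
    ci$ci_low > noise_lo & ci$ci_high < noise_hi
  cancer <- cancer[gate]
  out <- list()
  for (side in c("inclusion", "exclusion")) {
    p <- .side_prop(cancer$I, cancer$E, side)
    lowb <- .side_ci_low(cancer$I, cancer$E, side)
    np <- normals[, .(p = .side_prop(I, E, side)), by = .(tissue, event_id)]
    nstat <- np[, .(mean_normal = mean(p), max_normal = max(p)), by = event_id]
    m <- merge(cbind(cancer[, .(event_id)], p = p, ci_low = lowb),
               nstat, by = "event_id")
    hit <- m[p >= fold_mean * mean_normal & ci_low >= fold_max * max_normal]
    if (nrow(hit))
      out[[side]] <- cbind(hit[, .(event_id)], side = side,
                           hit[, .(proportion = p, ci_low, mean_normal,
                                   max_normal)])
  }
  if (length(out) == 0L)
    return(data.table(event_id = character(), side = character(),
                      proportion = numeric(), ci_low = numeric(),
                      mean_normal = numeric(), max_normal = numeric()))
  rbindlist(out)[order(event_id, side)]
}

#' Retain candidates whose atypical isoform is cancer- (not stroma-) borne
#'
#' The atypical proportion in cancer cells must be at least `fold_mean`
#' times the mean stromal proportion, its CI lower bound at least
#' `fold_ci` times the stromal proportion in every individual patient,
#' and the isoform must be undetectable (zero supporting reads) in every
#' sample of the tissue-of-origin reference.
#'
#' @param candidates Output of [call_atypical_vs_normal()].
#' @param cancer data.table event_id, I, E (pooled cancer cells).
#' @param stroma data.table patient, event_id, I, E (per-patient stromal
#'   aggregates).
#' @param origin Optional data.table tissue, event_id, I, E: the normal
#'   tissue-of-origin reference.
#' @param fold_mean,fold_ci Fold thresholds (defaults 5 and 2).
#' @return Filtered candidate table.
#' @export
call_tumor_specific_vs_stroma <- function(candidates, cancer, stroma,
                                          origin = NULL, fold_mean = 5,
                                          fold_ci = 2) {
  candidates <- as.data.table(candidates)
  cancer <- as.data.table(cancer)
  stroma <- as.data.table(stroma)
  keep <- logical(nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    ev <- candidates$event_id[r]; side <- candidates$side[r]
    cc <- cancer[event_id == ev]
    if (nrow(cc) == 0L) next
    p <- .side_prop(cc$I, cc$E, side)
    lowb <- .side_ci_low(cc$I, cc$E, side)
    st <- stroma[event_id == ev & I + E > 0]
    sp <- if (nrow(st)) .side_prop(st$I, st$E, side) else 0
    ok <- p >= fold_mean * mean(sp) && all(lowb >= fold_ci * sp)
    if (ok && !is.null(origin)) {
      og <- as.data.table(origin)[event_id == ev]
      atyp_reads <- if (side == "inclusion") og$I else og$E
      ok <- length(atyp_reads) == 0L || all(atyp_reads == 0L)
    }
    keep[r] <- ok
  }
  candidates[keep]
}

#' Translate an atypical isoform into proteome-unique 8-11-mer peptides
#'
#' Eligible events are CE, A5SS, A3SS and IR within coding regions that
#' are not predicted NMD targets.  Both isoforms of the event are rebuilt
#' on the representative transcript and translated; all k-mers
#' (k = `kmin`..`kmax`) present in the atypical protein but absent from
#' the normal isoform's protein and absent as substrings of every
#' reference-proteome sequence are returned.
#'
#' @param event One event row (with coding_effect and nmd columns).
#' @param side `"inclusion"` or `"exclusion"`: the atypical side.
#' @param index A `boundary_index`.
#' @param genome `DNAStringSet`.
#' @param proteome `AAStringSet` of normal protein sequences.
#' @param kmin,kmax Peptide length range (defaults 8 and 11).
#' @return Character vector of unique peptides (possibly empty).
#' @export
translate_atypical <- function(event, side, index, genome, proteome,
                               kmin = 8L, kmax = 11L) {
  ev <- as.data.table(event)[1L]
  if (!ev$as_type %in% c("CE", "A5SS", "A3SS", "IR"))
    stop("event type not eligible for antigen translation: ", ev$as_type)
  if (isTRUE(ev$nmd)) stop("NMD-positive events are excluded upstream")
  models <- index$models
  rep_tx <- .representative_tx(models, ev$gene_id)
  if (is.null(rep_tx)) return(character(0))
  rep_exons <- .rep_chain(models, rep_tx$transcript_id)
  cds <- models$cds[transcript_id == rep_tx$transcript_id]
  anchor <- if (rep_tx$strand == "-") max(cds$end) else min(cds$start)
  chains <- .event_isoform_chains(ev, rep_exons)
  other <- setdiff(c("inclusion", "exclusion"), side)
  tr_a <- .translate_event_chain(chains[[side]], anchor, rep_tx$strand,
                                 genome, ev$chrom)
  tr_n <- .translate_event_chain(chains[[other]], anchor, rep_tx$strand,
                                 genome, ev$chrom)
  if (is.null(tr_a) || is.null(tr_n)) return(character(0))
  km <- setdiff(.kmers(tr_a$aa, kmin, kmax), .kmers(tr_n$aa, kmin, kmax))
  if (length(km) == 0L) return(character(0))
  in_prot <- vapply(km, function(p)
    any(Biostrings::vcountPattern(p, proteome) > 0L), TRUE)
  sort(km[!in_prot])
}

#' Attach external MHC binding ranks to candidate peptides
#'
#' @param peptides Character vector of candidate peptides.
#' @param rank_table data.table peptide, allele, percent_rank (from an
#'   external binding predictor).
#' @param patient_alleles Up to 6 allele names.
#' @param strong_cut Strong-binder threshold on %rank (default 0.5).
#' @return List best_percent_rank (minimum over alleles and peptides; Inf
#'   when nothing is ranked), strong (logical), best_peptide.
#' @export
attach_mhc_ranks <- function(peptides, rank_table, patient_alleles,
                             strong_cut = 0.5) {
  if (length(patient_alleles) == 0L) stop("no patient alleles supplied")
  rank_table <- as.data.table(rank_table)
  sub <- rank_table[peptide %in% peptides & allele %in% patient_alleles]
  unranked <- setdiff(peptides, unique(sub$peptide))
  if (length(unranked))
    warning(length(unranked),
            " peptides missing from the rank table; treated as non-binders")
  if (nrow(sub) == 0L)
    return(list(best_percent_rank = Inf, strong = FALSE,
                best_peptide = NA_character_))
  best <- sub[which.min(percent_rank)]
  list(best_percent_rank = best$percent_rank,
       strong = best$percent_rank < strong_cut,
       best_peptide = best$peptide)
}

#' Counts-per-million gene expression
#'
#' @param gene_counts data.table gene_id, count (one library).
#' @return data.table gene_id, cpm (1e6 * count / total).
#' @export
compute_cpm <- function(gene_counts) {
  gene_counts <- as.data.table(gene_counts)
  tot <- sum(gene_counts$count)
  gene_counts[, .(gene_id, cpm = 1e6 * count / tot)]
}

#' Splice-derived tumor antigen burden (ATB)
#'
#' The ATB of a sample is the sum, over strong-MHC-binding atypical
#' isoforms, of isoform abundance = atypical proportion (PSI or 1 - PSI)
#' times the CPM of the host gene in cancer cells.
#'
#' @param candidates data.table event_id, gene_id, side, proportion,
#'   strong (only strong binders contribute).
#' @param cpm data.table gene_id, cpm for the sample's cancer cells.
#' @return List atb (number) and contributions (data.table event_id,
#'   side, abundance).  Genes missing from `cpm` contribute 0 with a
#'   warning.
#' @export
compute_atb <- function(candidates, cpm) {
  candidates <- as.data.table(candidates)[strong == TRUE]
  cpm <- as.data.table(cpm)
  if (nrow(candidates) == 0L)
    return(list(atb = 0,
                contributions = data.table(event_id = character(),
                                           side = character(),
                                           abundance = numeric())))
  m <- merge(candidates, cpm, by = "gene_id", all.x = TRUE)
  if (anyNA(m$cpm)) {
    warning(sum(is.na(m$cpm)), " candidate genes missing expression; ",
            "their contribution is 0")
    m[is.na(cpm), cpm := 0]
  }
  m[, abundance := proportion * cpm]
  list(atb = sum(m$abundance),
       contributions = m[, .(event_id, side, abundance)])
}
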