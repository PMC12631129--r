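# Synthetic fixture generator: a toy genome and annotation carrying one
# planted event of every splicing type (plus an unannotated one), tagged
# reads with cell barcodes and UMIs, normal-tissue references, a reference
# proteome and an MHC rank table, all tied together by a ground-truth
# manifest.  Everything is synthetic and desk-scale.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                     paste0), c("A","C","G","T"), paste0))
.NONSTOP_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# --- gene builders -----------------------------------------------------------
# Local 1-based coordinates inside a 2000 bp window; strand-aware.
# Each builder returns transcripts (exon/cds interval lists in genomic
# order), which transcripts get codons written (in order), and the planted
# event descriptors.

.core_gene_builders <- function() {
  list(
    CE_inframe = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(301,390), c(501,800)),
                 cds   = list(c(101,200), c(301,390), c(501,652))),
        B = list(exons = list(c(1,200), c(501,800)),
                 cds   = list(c(101,200), c(501,652)))),
      write_cds = "A",
      events = list(list(
        as_type = "CE", excl = c(201, 500),
        incl = list(c(201,300), c(391,500)),
        coding_effect = "in-frame", nmd = FALSE, novelty = "known",
        psi = c(T_cell = 0.2, cancer = 0.8), atypical_side = NA))),
    AFE = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(1001,1400)),
                 cds   = list(c(1101,1250))),
        B = list(exons = list(c(601,800), c(1001,1400)),
                 cds   = list(c(1101,1250)))),
      write_cds = "A",
      events = list(list(
        as_type = "AFE", excl = c(201, 1000),
        incl = list(c(801,1000)),
        coding_effect = "noncoding", nmd = NA, novelty = "known",
        psi = c(T_cell = 0.3, cancer = 0.7), atypical_side = NA))),
    ALE = list(
      strand = "-",
      tx = list(
        A = list(exons = list(c(601,800), c(1001,1400)),
                 cds   = list(c(1101,1250))),
        B = list(exons = list(c(1,200), c(1001,1400)),
                 cds   = list(c(1101,1250)))),
      write_cds = "A",
      events = list(list(
        as_type = "ALE", excl = c(201, 1000),
        incl = list(c(801,1000)),
        coding_effect = "noncoding", nmd = NA, novelty = "known",
        psi = c(T_cell = 0.6, cancer = 0.6), atypical_side = NA))),
    A5SS = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,259), c(401,700)),
                 cds   = list(c(101,259), c(401,550))),
        B = list(exons = list(c(1,200), c(401,700)), cds = NULL)),
      write_cds = "A",
      # GCT repeats are stop-free in every reading frame, so the
      # frameshifted (exclusion) isoform always gains a novel peptide tail
      prelock = list(list(pos = 401, chars = rep(c("G","C","T"), 20L))),
      events = list(list(
        as_type = "A5SS", excl = c(201, 400),
        incl = list(c(260,400)),
        coding_effect = "coding-disruptive", nmd = FALSE, novelty = "known",
        psi = c(T_cell = 0.9, cancer = 0.4), atypical_side = "exclusion"))),
    A3SS = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(401,700)),
                 cds   = list(c(101,200), c(401,522))),
        B = list(exons = list(c(1,200), c(461,700)),
                 cds   = list(c(101,200), c(461,522)))),
      write_cds = "A",
      events = list(list(
        as_type = "A3SS", excl = c(201, 460),
        incl = list(c(201,400)),
        coding_effect = "in-frame", nmd = FALSE, novelty = "known",
        psi = c(T_cell = 0.5, cancer = 0.5), atypical_side = NA))),
    MXE = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(301,400), c(701,1000)),
                 cds   = list(c(101,200), c(301,400), c(701,803))),
        B = list(exons = list(c(1,200), c(501,600), c(701,1000)),
                 cds   = list(c(101,200), c(501,600), c(701,803)))),
      write_cds = c("A", "B"),
      events = list(list(
        as_type = "MXE", excl = c(201, 500),
        incl = list(c(201,300)),
        mxe_exons = list(incl = c(301,400), excl = c(501,600)),
        coding_effect = "in-frame", nmd = NA, novelty = "known",
        psi = c(T_cell = 0.5, cancer = 0.5), atypical_side = NA))),
    IR = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(241,500)),
                 cds   = list(c(101,200), c(241,344))),
        B = list(exons = list(c(1,500)), cds = NULL)),
      write_cds = "A",
      # stop-free retained intron in every frame: the retention isoform's
      # frameshifted tail is guaranteed novel residues
      prelock = list(list(pos = 201, chars = rep(c("G","C","T"), 14L)[1:40])),
      events = list(list(
        as_type = "IR", excl = c(201, 240),
        incl = list(), ir_sites = c(200, 240),
        coding_effect = "coding-disruptive", nmd = FALSE, novelty = "known",
        psi = c(T_cell = 0.1, cancer = 0.5), atypical_side = "inclusion"))),
    UN = list(
      strand = "*", tx = list(), write_cds = character(),
      events = list(list(
        as_type = "UN", excl = c(201, 500),
        incl = list(c(201,300)),
        coding_effect = "unknown", nmd = NA, novelty = "novel",
        psi = c(T_cell = 0.5, cancer = 0.5), atypical_side = NA))),
    CE_fsNMD = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(301,391), c(501,700), c(801,1000)),
                 cds   = list(c(101,200), c(301,391), c(501,700), c(801,862))),
        B = list(exons = list(c(1,200), c(501,700), c(801,1000)), cds = NULL)),
      write_cds = "A",
      # plant a stop codon in the frameshifted (exclusion) frame early in
      # exon 3; harmless in the annotated frame (see prelock)
      prelock = list(list(pos = 501, chars = c("G","G","T","A","A"))),
      events = list(list(
        as_type = "CE", excl = c(201, 500),
        incl = list(c(201,300), c(392,500)),
        coding_effect = "coding-disruptive", nmd = TRUE, novelty = "known",
        psi = c(T_cell = 0.5, cancer = 0.5), atypical_side = NA))),
    CE_fsnonNMD = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(301,392), c(501,900)),
                 cds   = list(c(101,200), c(301,392), c(501,602))),
        B = list(exons = list(c(1,200), c(501,900)), cds = NULL)),
      write_cds = "A",
      events = list(list(
        as_type = "CE", excl = c(201, 500),
        incl = list(c(201,300), c(393,500)),
        coding_effect = "coding-disruptive", nmd = FALSE, novelty = "known",
        psi = c(T_cell = 0.5, cancer = 0.5), atypical_side = NA))),
    CE_UTR = list(
      strand = "+",
      tx = list(
        A = list(exons = list(c(1,200), c(301,400), c(501,700)),
                 cds   = list(c(51,200))),
        B = list(exons = list(c(1,200), c(501,700)),
                 cds   = list(c(51,200)))),
      write_cds = "A",
      events = list(list(
        as_type = "CE", excl = c(201, 500),
        incl = list(c(201,300), c(401,500)),
        coding_effect = "noncoding", nmd = NA, novelty = "known",
        psi = c(T_cell = 0.3, cancer = 0.3), atypical_side = NA))),
    FILLER = list(
      strand = "+",
      tx = list(A = list(exons = list(c(1,1800)), cds = list(c(101,1600)))),
      write_cds = "A",
      events = list())
  )
}

.const_gene_builder <- function() {
  list(strand = "+",
       tx = list(A = list(exons = list(c(1,300), c(501,900)),
                          cds = list(c(101,300), c(501,702)))),
       write_cds = "A",
       events = list())
}

# genomic positions of a CDS in transcription order
.cds_positions <- function(intervals, strand) {
  ivs <- intervals[order(vapply(intervals, `[`, 0, 1))]
  pos <- unlist(lapply(ivs, function(iv) seq.int(iv[1], iv[2])))
  if (strand == "-") pos <- rev(pos)
  pos
}

# write ATG + non-stop codons + TAA through (possibly partially locked)
# genomic positions; complement-aware for minus-strand models
.write_codons <- function(chars, locked, gpos, strand) {
  L <- length(gpos)
  stopifnot(L %% 3 == 0)
  n_codon <- L / 3L
  get_base <- function(p) if (strand == "-") .COMP[[chars[p]]] else chars[p]
  set_base <- function(p, b) {
    chars[p] <<- if (strand == "-") .COMP[[b]] else b
    locked[p] <<- TRUE
  }
  for (i in seq_len(n_codon)) {
    idx <- gpos[(3L * i - 2L):(3L * i)]
    lk <- locked[idx]
    cur <- vapply(idx, get_base, "")
    cand <- if (i == 1L) "ATG" else if (i == n_codon) "TAA" else .NONSTOP_CODONS
    ok <- cand[vapply(cand, function(cd) {
      b <- strsplit(cd, "")[[1L]]
      all(b[lk] == cur[lk])
    }, TRUE)]
    if (length(ok) == 0L)
      stop("internal: locked bases incompatible with codon layout")
    cd <- strsplit(sample(ok, 1L), "")[[1L]]
    for (k in 1:3) if (!lk[k]) set_base(idx[k], cd[k])
  }
  list(chars = chars, locked = locked)
}

#' Generate a toy genome and annotation with planted splicing events
#'
#' Builds a single-chromosome genome in which consecutive 2 kb windows hold
#' genes realising every splicing type: cassette exons (in-frame,
#' frameshift-with-NMD, frameshift-without-NMD, and one in the 3' UTR),
#' alternative first and last exons, alternative 5' and 3' splice sites,
#' mutually exclusive exons, a retained intron, an annotation-free (UN)
#' junction pair, a single-isoform filler gene used for background reads,
#' and constitutive two-exon genes up to `n_genes`.  Coding sequences are
#' written as stop-free codons; one gene carries an engineered stop in the
#' frameshifted frame so that its exclusion isoform is a canonical
#' 50-nt-rule NMD target.
#'
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param n_genes Total gene count (>= 8; the first windows hold the typed
#'   genes, extra windows hold constitutive genes).  Default 48 (~100 kb).
#' @return An `ase_fixture` list: `genome` (named `DNAStringSet`), `models`
#'   (a `tx_models`), and `manifest` with the planted-event table, true
#'   PSIs per cell type and reference protein sequences.
#' @export
generate_genome_and_annotation <- function(seed = 1L, n_genes = 48L) {
  stopifnot(n_genes >= 8L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  builders <- .core_gene_builders()
  tags <- names(builders)
  if (n_genes < length(tags)) tags <- tags[seq_len(n_genes)]
  tags <- c(tags, rep("CONST", max(0L, n_genes - length(tags))))

  window <- 2000L
  glen <- n_genes * window + 1000L
  chrom <- "chrT"
  chars <- sample(c("A","C","G","T"), glen, replace = TRUE)
  locked <- logical(glen)

  exon_rows <- list(); cds_rows <- list(); tx_rows <- list()
  events <- list()
  genes <- list()

  for (gi in seq_along(tags)) {
    tag <- tags[gi]
    b <- if (tag == "CONST") .const_gene_builder() else builders[[tag]]
    off <- (gi - 1L) * window
    gene_id <- sprintf("GSYN%04d", gi)
    gene_name <- sprintf("SYN%s%d", tag, gi)
    genes[[gene_id]] <- list(gene_id = gene_id, gene_name = gene_name,
                             tag = tag, strand = b$strand, offset = off)

    for (pl in b$prelock %||% list()) {
      p <- pl$pos + off
      idx <- seq.int(p, p + length(pl$chars) - 1L)
      chars[idx] <- pl$chars
      locked[idx] <- TRUE
    }
    for (txn in names(b$tx)) {
      txd <- b$tx[[txn]]
      tx_id <- paste0(gene_id, ".", txn)
      for (iv in txd$exons)
        exon_rows[[length(exon_rows) + 1L]] <-
          data.table(type = "exon", chrom = chrom, start = iv[1] + off,
                     end = iv[2] + off, strand = b$strand,
                     transcript_id = tx_id, gene_id = gene_id,
                     gene_name = gene_name)
      for (iv in txd$cds %||% list())
        cds_rows[[length(cds_rows) + 1L]] <-
          data.table(type = "CDS", chrom = chrom, start = iv[1] + off,
                     end = iv[2] + off, strand = b$strand,
                     transcript_id = tx_id, gene_id = gene_id,
                     gene_name = gene_name)
    }
    for (txn in b$write_cds) {
      txd <- b$tx[[txn]]
      gpos <- .cds_positions(lapply(txd$cds, function(iv) iv + off), b$strand)
      w <- .write_codons(chars, locked, gpos, b$strand)
      chars <- w$chars; locked <- w$locked
    }
    for (ev in b$events) {
      ev$gene_id <- if (tag == "UN") NA_character_ else gene_id
      ev$tag <- tag
      ev$chrom <- chrom
      ev$strand <- b$strand
      ev$excl <- ev$excl + off
      ev$incl <- lapply(ev$incl, function(iv) iv + off)
      if (!is.null(ev$ir_sites)) ev$ir_sites <- ev$ir_sites + off
      if (!is.null(ev$mxe_exons))
        ev$mxe_exons <- lapply(ev$mxe_exons, function(iv) iv + off)
      ev$key <- make_event_id(ev$chrom, ev$excl, ev$incl, ev$as_type)
      events[[ev$key]] <- ev
    }
  }

  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- chrom

  gtf <- rbindlist(c(exon_rows, cds_rows))
  gtf_path <- tempfile(fileext = ".gtf")
  .write_gtf(gtf, gtf_path)
  models <- load_annotation(gtf_path, "primary_annotation")
  unlink(gtf_path)

  # sanity: every written CDS translates without internal stops
  for (tid in models$transcripts[frame_ok == TRUE, transcript_id]) {
    aa <- as.character(Biostrings::translate(
      extract_coding_sequence(models, tid, genome)))
    stopifnot(substr(aa, 1, 1) == "M",
              !grepl("\\*", substr(aa, 1, nchar(aa) - 1L)),
              substr(aa, nchar(aa), nchar(aa)) == "*")
  }

  manifest <- list(
    seed = seed, n_genes = n_genes, chrom = chrom, genome_length = glen,
    cell_types = c("T_cell", "cancer"),
    genes = genes, events = events,
    event_table = .manifest_event_table(events),
    filler_gene = names(genes)[match("FILLER", vapply(genes, `[[`, "", "tag"))]
  )
  out <- list(genome = genome, models = models, manifest = manifest)
  class(out) <- "ase_fixture"
  out
}

.manifest_event_table <- function(events) {
  rbindlist(lapply(events, function(ev) data.table(
    event_id = ev$key, as_type = ev$as_type, gene_id = ev$gene_id,
    tag = ev$tag, chrom = ev$chrom, strand = ev$strand,
    excl_start = ev$excl[1], excl_end = ev$excl[2],
    coding_effect = ev$coding_effect, nmd = ev$nmd, novelty = ev$novelty,
    psi_T_cell = ev$psi[["T_cell"]], psi_cancer = ev$psi[["cancer"]],
    atypical_side = as.character(ev$atypical_side))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.write_gtf <- function(dt, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                   dt$gene_id, dt$transcript_id, dt$gene_name)
  lines <- paste(dt$chrom, "synthetic", dt$type, dt$start, dt$end, ".",
                 dt$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
}

#' Write fixture genome and annotation to disk
#'
#' @param fixture An `ase_fixture`.
#' @param dir Output directory.
#' @return Named list of written file paths (fasta, gtf).
#' @export
write_fixture_files <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(fixture$genome, fasta)
  gtf <- file.path(dir, "annotation.gtf")
  ex <- fixture$models$exons
  cd <- fixture$models$cds
  tx <- fixture$models$transcripts
  tab <- rbind(
    merge(ex, tx[, .(transcript_id, gene_id, gene_name)],
          by = "transcript_id")[, .(type = "exon", chrom, start, end, strand,
                                    transcript_id, gene_id, gene_name)],
    if (nrow(cd)) merge(cd, tx[, .(transcript_id, gene_id, gene_name)],
          by = "transcript_id")[, .(type = "CDS", chrom, start, end, strand,
                                    transcript_id, gene_id, gene_name)])
  setorder(tab, chrom, start, transcript_id)
  .write_gtf(tab, gtf)
  list(fasta = fasta, gtf = gtf)
}

# --- read simulation ---------------------------------------------------------

#' Default cell design for the fixture
#'
#' @param n_samples Number of samples.
#' @param cells_per_type Cells per (sample, cell type).
#' @return data.table with cell_barcode, sample_id, cell_type.
#' @export
fixture_cell_design <- function(n_samples = 4L, cells_per_type = 25L) {
  grid <- CJ(sample_id = sprintf("S%d", seq_len(n_samples)),
             cell_type = c("T_cell", "cancer"),
             i = seq_len(cells_per_type))
  grid[, cell_barcode := sprintf("%s-%s-C%03d", sample_id, cell_type, i)]
  grid[, .(cell_barcode, sample_id, cell_type)]
}

# SAM records for one molecule of an event side
.molecule_read <- function(ev, side, genome) {
  chrom <- ev$chrom
  gseq <- genome[[chrom]]
  seg <- function(s, e) as.character(Biostrings::subseq(gseq, s, e))
  anchor <- 30L
  if (side == "inclusion" && ev$as_type == "IR") {
    s <- ev$excl[1]; e <- ev$excl[2]
    pos <- s - anchor - 1L
    len <- (e + anchor + 1L) - pos + 1L
    return(list(pos = pos, cigar = paste0(len, "M"),
                seq = seg(pos, pos + len - 1L)))
  }
  jxs <- if (side == "inclusion") ev$incl else list(ev$excl)
  jxs <- jxs[order(vapply(jxs, `[`, 0, 1))]
  pos <- jxs[[1L]][1] - anchor
  cigar <- paste0(anchor, "M")
  seqs <- seg(pos, jxs[[1L]][1] - 1L)
  for (k in seq_along(jxs)) {
    jl <- jxs[[k]][2] - jxs[[k]][1] + 1L
    cigar <- paste0(cigar, jl, "N")
    nxt_end <- if (k < length(jxs)) jxs[[k + 1L]][1] - 1L else jxs[[k]][2] + anchor
    mlen <- nxt_end - jxs[[k]][2]
    cigar <- paste0(cigar, mlen, "M")
    seqs <- paste0(seqs, seg(jxs[[k]][2] + 1L, nxt_end))
  }
  list(pos = pos, cigar = cigar, seq = seqs)
}

#' Simulate tagged reads for the fixture and write a sorted, indexed BAM
#'
#' Draws molecules per event and cell at the manifest's true PSI.  In
#' `"exact"` mode inclusion counts are deterministic
#' (`round(molecules * psi)`), for oracle tests; in `"sampled"` mode they
#' are binomial draws.  Each molecule emits 1-3 duplicate reads sharing
#' (cell barcode, UMI).  Background (junction-free) reads are placed on the
#' filler gene with start positions decaying geometrically from the 5' end
#' with strength `bias_5prime` (0 = uniform).
#'
#' @param fixture An `ase_fixture`.
#' @param cells Cell design from [fixture_cell_design()] (default).
#' @param molecules_per_event Molecules per event per cell (default 10).
#' @param bias_5prime Geometric decay rate of background read starts in
#'   (0, 1); 0 gives uniform starts.
#' @param n_background Number of background reads (default 2000).
#' @param mode `"exact"` or `"sampled"`.
#' @param seed Integer seed.
#' @param out_dir Directory for the BAM (created if needed).
#' @param cb_tag,umi_tag Tag names to emit.
#' @return List with `bam` (path), `truth` (data.table event_id, cell,
#'   cell_type, sample_id, I, E) and `cells`.
#' @export
simulate_reads <- function(fixture, cells = fixture_cell_design(),
                           molecules_per_event = 10L, bias_5prime = 0,
                           n_background = 2000L,
                           mode = c("exact", "sampled"), seed = 1L,
                           out_dir = tempfile("fixture_bam_"),
                           cb_tag = "CB", umi_tag = "UB") {
  mode <- match.arg(mode)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cells <- as.data.table(cells)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  events <- fixture$manifest$events
  chrom <- fixture$manifest$chrom
  recs <- list()
  truth <- list()
  umi_counter <- new.env(parent = emptyenv())
  next_umi <- function(cell) {
    n <- (umi_counter[[cell]] %||% 0L) + 1L
    umi_counter[[cell]] <- n
    sprintf("UMI%06d", n)
  }

  emit <- function(ev, side, cell, n_mol, dup_phase) {
    if (n_mol <= 0L) return(invisible(NULL))
    tmpl <- .molecule_read(ev, side, fixture$genome)
    for (m in seq_len(n_mol)) {
      umi <- next_umi(cell)
      ndup <- if (mode == "exact") 1L + ((dup_phase + m) %% 3L) else sample(3L, 1L)
      for (d in seq_len(ndup)) {
        recs[[length(recs) + 1L]] <<- data.table(
          qname = sprintf("%s:%s:%s:%d", cell, umi, ev$key, d),
          pos = tmpl$pos, cigar = tmpl$cigar, seq = tmpl$seq,
          cell = cell, umi = umi)
      }
    }
  }

  for (ev in events) {
    psi <- ev$psi
    for (ci in seq_len(nrow(cells))) {
      cell <- cells$cell_barcode[ci]
      ctype <- cells$cell_type[ci]
      p <- psi[[ctype]]
      m <- molecules_per_event
      I <- if (mode == "exact") as.integer(floor(m * p + 0.5)) else
        stats::rbinom(1L, m, p)
      E <- m - I
      emit(ev, "inclusion", cell, I, ci)
      emit(ev, "exclusion", cell, E, ci + 1L)
      truth[[length(truth) + 1L]] <- data.table(
        event_id = ev$key, cell = cell, cell_type = ctype,
        sample_id = cells$sample_id[ci], I = I, E = E)
    }
  }

  # background reads on the filler gene (junction-free coverage)
  fg <- fixture$manifest$filler_gene
  if (!is.na(fg) && n_background > 0L) {
    off <- fixture$manifest$genes[[fg]]$offset
    span <- 1700L
    starts <- if (bias_5prime > 0)
      1L + (stats::rgeom(n_background, bias_5prime) %% span)
    else
      sample.int(span, n_background, replace = TRUE)
    cellv <- cells$cell_barcode[1L + (seq_len(n_background) - 1L) %% nrow(cells)]
    for (i in seq_len(n_background)) {
      pos <- off + starts[i]
      recs[[length(recs) + 1L]] <- data.table(
        qname = sprintf("bg:%d", i), pos = pos, cigar = "80M",
        seq = as.character(Biostrings::subseq(fixture$genome[[chrom]],
                                              pos, pos + 79L)),
        cell = cellv[i], umi = next_umi(cellv[i]))
    }
  }

  reads <- rbindlist(recs)
  setorder(reads, pos, qname)
  sam <- file.path(out_dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, fixture$manifest$genome_length))
  body <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\t%s:Z:%s\t%s:Z:%s",
                  reads$qname, chrom, reads$pos, reads$cigar, reads$seq,
                  strrep("I", nchar(reads$seq)),
                  cb_tag, reads$cell, umi_tag, reads$umi)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  list(bam = bam, truth = rbindlist(truth), cells = cells)
}

# --- translation helpers used for reference generation -----------------------

# exon chain of the altered / normal isoform of an event, by patching the
# representative chain within the exclusion-intron span (see detection.R
# for the identical logic on detected events)
.fixture_isoform_chain <- function(ev, rep_exons) {
  span <- ev$excl
  patch <- function(incl_introns) {
    exonic_in <- setdiff(seq.int(span[1], span[2]),
                         unlist(lapply(incl_introns,
                                       function(iv) seq.int(iv[1], iv[2]))))
    outside <- unlist(lapply(rep_exons, function(iv) seq.int(iv[1], iv[2])))
    outside <- outside[outside < span[1] | outside > span[2]]
    .positions_to_intervals(sort(c(outside, exonic_in)))
  }
  list(inclusion = patch(ev$incl),
       exclusion = patch(list(ev$excl)))
}

.positions_to_intervals <- function(pos) {
  if (length(pos) == 0L) return(list())
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i)
    c(pos[brk[i] + 1L], pos[brk[i + 1L]]))
}

# translate an isoform chain from the genomic start-codon anchor to the
# first stop (or chain end); plus-strand fixture genes only
.translate_chain <- function(chain, cds_anchor, genome, chrom) {
  pos <- unlist(lapply(chain, function(iv) seq.int(iv[1], iv[2])))
  ai <- match(cds_anchor, pos)
  if (is.na(ai)) return(NULL)
  pos <- pos[ai:length(pos)]
  pos <- pos[seq_len(3L * (length(pos) %/% 3L))]
  if (length(pos) < 3L) return(NULL)
  sq <- paste(strsplit(as.character(genome[[chrom]]), "")[[1L]][pos],
              collapse = "")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(sq),
                                           if.fuzzy.codon = "solve"))
  sub("\\*.*$", "", aa)
}

.kmers <- function(aa, kmin = 8L, kmax = 11L) {
  n <- nchar(aa)
  out <- character(0)
  for (k in kmin:kmax) {
    if (n >= k) out <- c(out, substring(aa, 1:(n - k + 1L), k:n))
  }
  unique(out)
}

#' Generate normal references, proteome and MHC rank table for the fixture
#'
#' Normal tissues express only the normal isoform of every event except for
#' a configurable `contamination` fraction of atypical-isoform reads.  The
#' proteome holds the proteins of all frame-complete annotated transcripts.
#' The rank table marks a designated subset of each planted antigen
#' candidate's unique peptides as strong MHC binders (%rank 0.25) and the
#' rest as non-binders (%rank 5).
#'
#' @param fixture An `ase_fixture`.
#' @param n_tissues Number of normal tissues (default 5).
#' @param contamination Fraction of atypical-isoform reads in normal
#'   tissues (default 0).
#' @param reads_per_event Total reads per event per tissue (default 200).
#' @param seed Integer seed.
#' @return List with `normal_counts` and `origin_counts` (data.tables
#'   tissue, event_id, I, E), `proteome` (`AAStringSet`), `rank_table`
#'   (peptide, allele, percent_rank), `alleles`, and `designated`
#'   (data.table event_id, atypical_side, peptide: the strong binders).
#' @export
generate_references <- function(fixture, n_tissues = 5L, contamination = 0,
                                reads_per_event = 200L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  events <- fixture$manifest$events
  models <- fixture$models
  genome <- fixture$genome
  chrom <- fixture$manifest$chrom

  mk_counts <- function(contam) {
    rbindlist(lapply(events, function(ev) {
      # atypical side gets `contam` proportion; otherwise tissues sit at
      # the T-cell PSI (the "normal" usage)
      p_incl <- if (is.na(ev$atypical_side)) ev$psi[["T_cell"]]
        else if (ev$atypical_side == "inclusion") contam else 1 - contam
      I <- as.integer(floor(reads_per_event * p_incl + 0.5))
      data.table(event_id = ev$key, I = I, E = reads_per_event - I)
    }))
  }
  normal_counts <- rbindlist(lapply(seq_len(n_tissues), function(t)
    cbind(tissue = sprintf("tissue%02d", t), mk_counts(contamination))))
  origin_counts <- rbindlist(lapply(1:3, function(t)
    cbind(tissue = sprintf("origin%02d", t), mk_counts(0))))

  prot_ids <- models$transcripts[frame_ok == TRUE, transcript_id]
  prots <- Biostrings::AAStringSet(vapply(prot_ids, function(tid) {
    sub("\\*$", "", as.character(Biostrings::translate(
      extract_coding_sequence(models, tid, genome))))
  }, ""))
  names(prots) <- prot_ids

  # planted antigen candidates: unique peptides of the atypical isoform
  designated <- list(); weak <- list()
  for (ev in events) {
    if (is.na(ev$atypical_side)) next
    gid <- ev$gene_id
    rep_tx <- models$transcripts[gene_id == gid & cds_len > 0L][order(-cds_len)][1L]
    rep_ex <- models$exons[transcript_id == rep_tx$transcript_id]
    rep_chain <- lapply(seq_len(nrow(rep_ex)), function(i)
      c(rep_ex$start[i], rep_ex$end[i]))
    rep_cds <- models$cds[transcript_id == rep_tx$transcript_id]
    anchor <- min(rep_cds$start)   # plus-strand candidates only
    chains <- .fixture_isoform_chain(ev, rep_chain)
    aa_atyp <- .translate_chain(chains[[ev$atypical_side]], anchor,
                                genome, chrom)
    other <- setdiff(c("inclusion", "exclusion"), ev$atypical_side)
    aa_norm <- .translate_chain(chains[[other]], anchor, genome, chrom)
    km <- setdiff(.kmers(aa_atyp), .kmers(aa_norm))
    in_prot <- vapply(km, function(p)
      any(Biostrings::vcountPattern(p, prots) > 0L), TRUE)
    km <- sort(km[!in_prot])
    if (length(km) == 0L) next
    strong <- head(km, 3L)
    designated[[ev$key]] <- data.table(event_id = ev$key,
                                       atypical_side = ev$atypical_side,
                                       peptide = strong)
    weak[[ev$key]] <- setdiff(km, strong)
  }
  designated <- rbindlist(designated)
  alleles <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02",
               "HLA-B*08:01", "HLA-C*04:01", "HLA-C*07:01")
  rank_rows <- list()
  for (i in seq_len(nrow(designated))) {
    pr <- rep(5, length(alleles)); pr[2L] <- 0.25
    rank_rows[[length(rank_rows) + 1L]] <-
      data.table(peptide = designated$peptide[i], allele = alleles,
                 percent_rank = pr)
  }
  for (w in head(unlist(weak), 40L))
    rank_rows[[length(rank_rows) + 1L]] <-
      data.table(peptide = w, allele = alleles, percent_rank = 5)
  rank_table <- rbindlist(rank_rows)

  list(normal_counts = normal_counts, origin_counts = origin_counts,
       proteome = prots, rank_table = rank_table, alleles = alleles,
       designated = designated)
}
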