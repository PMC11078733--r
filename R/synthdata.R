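# Synthetic-data generation: combinatorial-indexing libraries and cell
# populations with known ground truth, emulating the read structure
# (barcodes + UMI + heterogeneity spacer + amplicon), the sequencing-error
# process, barcode-collision doublets, bimodal editing outcomes and
# lineage-barcode clones.  Every generator takes an explicit seed and is
# byte-reproducible.

# run code with a private RNG state so fixture construction does not
# disturb the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""),
    character(1))
}

# greedy barcode design: random candidates, rejected when within Hamming
# distance 2 of an accepted barcode, so Hamming-1 correction is unambiguous
.design_barcodes <- function(n, width) {
  out <- character(0)
  while (length(out) < n) {
    cand <- .random_dna(2L * (n - length(out)) + 8L, width)
    for (cd in cand) {
      if (length(out) == n) break
      if (length(out) == 0 || min(.hamming_to(out, cd)) >= 3L)
        out <- c(out, cd)
    }
  }
  out
}

#' Default barcode whitelists and allele tables for synthetic libraries
#'
#' Deterministic stand-in designs (fixed internal seeds): two 96-entry
#' barcode whitelists with minimum pairwise Hamming distance 3, a
#' mitochondrial-style edit amplicon with wild-type, missense, silent and
#' double-edit alleles at two diagnostic offsets, a barnyard amplicon whose
#' single diagnostic base distinguishes the two cell lines, and a
#' lineage-barcode amplicon.
#'
#' @param n number of barcodes in the whitelist.
#' @return the corresponding whitelist / allele table object.
#' @export
default_rt_whitelist <- function(n = 96L) {
  .with_seed(20101L, whitelist(.design_barcodes(n, 10L), name = "rt"))
}

#' @rdname default_rt_whitelist
#' @export
default_lig_whitelist <- function(n = 96L) {
  .with_seed(20102L, whitelist(.design_barcodes(n, 10L), name = "ligation"))
}

#' @rdname default_rt_whitelist
#' @export
default_edit_table <- function() {
  ref <- "TACTCACCCATCAACAACCGCTATGTATTTCGTACA"
  allele_table("mt_amp", ref, offsets = c(13L, 21L),
               alleles = c(wt = "AG", missense = "GG", silent = "AA",
                           both = "GA"),
               tags = c(wt = "wild-type", missense = "missense",
                        silent = "silent", both = "both"))
}

#' @rdname default_rt_whitelist
#' @export
default_barnyard_table <- function() {
  ref <- "CCTAGGAATCACCTCCCATTCCGATACATCACTGCA"
  allele_table("barnyard_amp", ref, offsets = 15L,
               alleles = c(hela = "C", t293 = "T"),
               tags = c(hela = "hela", t293 = "293t"))
}

#' @rdname default_rt_whitelist
#' @export
default_lineage_barcodes <- function(n = 200L) {
  .with_seed(20103L, .design_barcodes(n, 14L))
}

#' @rdname default_rt_whitelist
#' @export
default_lineage_table <- function(n = 200L) {
  lineage_table("lineage", "GGTCTACGAGCT", default_lineage_barcodes(n))
}

# substitute allele bases into the amplicon reference
.allele_sequences <- function(table) {
  vapply(names(table$alleles), function(a) {
    s <- table$reference
    bases <- strsplit(table$alleles[[a]], "", fixed = TRUE)[[1]]
    for (k in seq_along(table$offsets))
      substr(s, table$offsets[k], table$offsets[k]) <- bases[k]
    s
  }, character(1))
}

# inject per-base substitution errors at rate err
.add_errors <- function(seqs, err) {
  if (err <= 0) return(seqs)
  L <- nchar(seqs)
  k <- stats::rbinom(length(seqs), L, err)
  hit <- which(k > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L[i], k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

# emit reads for a molecule table: one row per UMI with cell barcodes,
# amplicon sequence and reads-per-UMI count
.emit_reads <- function(umi_df, layout, err) {
  n <- sum(umi_df$reads)
  idx <- rep(seq_len(nrow(umi_df)), umi_df$reads)
  spacer_len <- sample(layout$spacer_lengths, n, replace = TRUE)
  spacers <- vapply(spacer_len, function(k)
    if (k == 0) "" else paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = ""), character(1))
  reads <- paste0(umi_df$lig[idx], umi_df$umi[idx], umi_df$rt[idx],
                  spacers, umi_df$amp_seq[idx])
  .add_errors(reads, err)
}

.rumis <- function(n, mean, size = 4) {
  pmax(1L, stats::rnbinom(n, mu = mean, size = size))
}

.rreads <- function(n, mean = 5) {
  1L + stats::rgeom(n, prob = 1 / mean)
}

#' Synthesize a barnyard library
#'
#' Mixes two homoplasmic cell lines in equal proportions and plants
#' heterotypic doublets as barcode-path collisions: a doublet is one
#' barcode path carrying the molecules of one cell from each line.
#' Optionally adds low-coverage ambient background barcodes so the
#' knee-calling step has two populations to separate.
#'
#' @param n_cells number of real cell barcodes (paths).
#' @param doublet_rate fraction of paths planted as heterotypic doublets.
#' @param umis_per_cell mean UMIs per cell (negative binomial, size 4).
#' @param reads_per_umi mean reads per UMI (shifted geometric, support >= 1).
#' @param error_rate per-base substitution probability.
#' @param background_barcodes number of ambient barcodes (about 2 UMIs
#'   each) appended to the library.
#' @param seed RNG seed (mandatory; the output is byte-reproducible).
#' @param rt_wl,lig_wl,table,layout library design objects.
#' @return list with `reads` (character vector), `truth` (`data.table`:
#'   `cell_id`, `label` in `{HELA, 293T, DOUBLET, BACKGROUND}`), plus the
#'   design objects used (`layout`, `whitelists`, `table`).
#' @export
make_barnyard <- function(n_cells = 5000L, doublet_rate = 0.01,
                          umis_per_cell = 130, reads_per_umi = 5,
                          error_rate = 0.002, background_barcodes = 0L,
                          seed, rt_wl = default_rt_whitelist(),
                          lig_wl = default_lig_whitelist(),
                          table = default_barnyard_table(),
                          layout = read_layout()) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  n_total <- n_cells + background_barcodes
  paths <- unique(data.table::data.table(
    rt = sample(rt_wl$sequences, 4L * n_total, replace = TRUE),
    lig = sample(lig_wl$sequences, 4L * n_total, replace = TRUE)))
  if (nrow(paths) < n_total)
    stop("barcode space too small for the requested number of cells")
  paths <- paths[seq_len(n_total)]
  n_doublet <- round(n_cells * doublet_rate)
  label <- c(sample(rep(c("HELA", "293T"),
                        length.out = n_cells - n_doublet)),
             rep("DOUBLET", n_doublet),
             rep("BACKGROUND", background_barcodes))
  label[seq_len(n_cells)] <- sample(label[seq_len(n_cells)])
  amp_seqs <- .allele_sequences(table)
  n_umis <- ifelse(label == "BACKGROUND", pmax(1L, stats::rpois(n_total, 2)),
                   .rumis(n_total, umis_per_cell))
  umi_rows <- lapply(seq_len(n_total), function(i) {
    k <- n_umis[i]
    line_allele <- switch(label[i],
      HELA = rep("hela", k),
      `293T` = rep("t293", k),
      BACKGROUND = sample(c("hela", "t293"), k, replace = TRUE),
      # heterotypic doublet: two cells' molecules behind one path
      DOUBLET = sample(c("hela", "t293"), k, replace = TRUE))
    data.table::data.table(path = i, umi = .random_dna(k, 8L),
                           allele = line_allele)
  })
  umis <- data.table::rbindlist(umi_rows)
  umis[, `:=`(rt = paths$rt[path], lig = paths$lig[path],
              amp_seq = amp_seqs[allele],
              reads = .rreads(.N, reads_per_umi))]
  reads <- .emit_reads(umis, layout, error_rate)
  truth <- data.table::data.table(
    cell_id = paste("S1", paths$lig, paths$rt, sep = ":"),
    label = label)
  list(reads = reads, truth = truth, layout = layout,
       whitelists = list(rt = rt_wl, ligation = lig_wl), table = table)
}

#' Synthesize an edited cell population with bimodal heteroplasmy
#'
#' Per-cell true missense heteroplasmy follows a two-component mixture: a
#' point mass at zero (cells that escaped editing) and a Beta component
#' concentrated at high heteroplasmy, reproducing the bimodal outcome of
#' mitochondrial base editing.  The silent heteroplasmy occupies a Beta-
#' distributed share of the remainder.  Observed per-cell heteroplasmy is
#' obtained by multinomially sampling each cell's UMIs from its true
#' fractions, so the observable table carries realistic counting noise.
#'
#' @param n_cells number of cells.
#' @param zero_weight mixture weight of the unedited (zero) component.
#' @param beta_shape1,beta_shape2 Beta parameters of the edited component.
#' @param silent_shape1,silent_shape2 Beta parameters of the silent share
#'   of the non-missense fraction.
#' @param umis_per_cell mean UMIs per cell (negative binomial, size 4).
#' @param seed RNG seed (mandatory).
#' @return list with `truth` (`cell_id`, `true_missense`, `true_silent`)
#'   and `observed` (`cell_id`, `missense_het`, `silent_het`, `wt_het`,
#'   `total_umis`).
#' @export
make_edited_population <- function(n_cells = 5000L, zero_weight = 0.3,
                                   beta_shape1 = 8, beta_shape2 = 2,
                                   silent_shape1 = 2, silent_shape2 = 8,
                                   umis_per_cell = 130, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  edited <- stats::runif(n_cells) >= zero_weight
  m <- ifelse(edited, stats::rbeta(n_cells, beta_shape1, beta_shape2), 0)
  s <- (1 - m) * stats::rbeta(n_cells, silent_shape1, silent_shape2)
  tot <- .rumis(n_cells, umis_per_cell)
  cnt <- .resample_counts(cbind(m, s, 1 - m - s), tot)
  obs <- cnt / rowSums(cnt)
  ids <- sprintf("cell%05d", seq_len(n_cells))
  list(truth = data.table::data.table(cell_id = ids, true_missense = m,
                                      true_silent = s),
       observed = data.table::data.table(cell_id = ids,
                                         missense_het = obs[, 1L],
                                         silent_het = obs[, 2L],
                                         wt_het = obs[, 3L],
                                         total_umis = rowSums(cnt)))
}

#' Synthesize a lineage-traced two-timepoint experiment
#'
#' Founding clones each carry one unique ancestry barcode and a fixed true
#' heteroplasmy (heteroplasmy within a cell does not change over the time
#' course).  Between the two timepoints, lineage sizes evolve either
#' neutrally or with division probability weighted by the inverse-sigmoid
#' fitness of the lineage heteroplasmy; lineages can drop out.  Output is
#' a pair of UMI tables (mitochondrial edit amplicon plus lineage-barcode
#' amplicon) ready for [collapse_umis()], together with the full truth.
#'
#' @param n_cells cells sampled per timepoint.
#' @param n_lineages number of founding clones.
#' @param params optional [sigmoid_params()]; `NULL` means neutral growth.
#' @param generations effective doublings between the timepoints.
#' @param zero_weight,beta_shape1,beta_shape2 lineage-heteroplasmy mixture
#'   (see [make_edited_population()]).
#' @param umis_per_cell mean mitochondrial UMIs per cell.
#' @param lineage_umis_per_cell mean lineage-barcode UMIs per cell.
#' @param reads_per_umi mean reads per UMI (all UMIs get >= 3 reads with
#'   the default so the consensus filter mostly retains them).
#' @param seed RNG seed (mandatory).
#' @return list with `umi_day0`, `umi_day5` (UMI tables), `truth_lineages`
#'   (`lineage`, `true_missense`, `true_silent`, `freq_day0`, `freq_day5`),
#'   `truth_cells_day0`, `truth_cells_day5` (`cell_id`, `lineage`), and
#'   `table`/`lineage_tab` design objects.
#' @export
make_lineage_timecourse <- function(n_cells = 1000L, n_lineages = 100L,
                                    params = NULL, generations = 5L,
                                    zero_weight = 0.2, beta_shape1 = 6,
                                    beta_shape2 = 3, umis_per_cell = 40,
                                    lineage_umis_per_cell = 30,
                                    reads_per_umi = 6, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  # pools up to the designed whitelist size reuse it (so the emitted
  # barcodes are parseable at read level); larger pools use random
  # distinct 14-mers, which UMI-table-level analyses accept unchanged
  barcodes <- if (n_lineages <= 200L) {
    default_lineage_barcodes(200L)[seq_len(n_lineages)]
  } else {
    unique(.random_dna(3L * n_lineages, 14L))[seq_len(n_lineages)]
  }
  edited <- stats::runif(n_lineages) >= zero_weight
  m <- ifelse(edited, stats::rbeta(n_lineages, beta_shape1, beta_shape2), 0)
  s <- (1 - m) * stats::rbeta(n_lineages, 2, 8)
  # lineage frequencies: exchangeable founders, then generations of
  # fitness-weighted multinomial doubling at the lineage level
  freq0 <- as.numeric(stats::rmultinom(1L, 10L * n_lineages,
                                       rep(1, n_lineages))) / (10 * n_lineages)
  w <- if (is.null(params)) rep(1, n_lineages) else fitness(m, params)
  freq1 <- freq0
  for (g in seq_len(generations)) {
    growth <- freq1 * w
    freq1 <- as.numeric(stats::rmultinom(1L, 10L * n_lineages,
                                         growth / sum(growth))) /
      (10 * n_lineages)
  }
  sample_tp <- function(freqs, tp) {
    lin <- sample.int(n_lineages, n_cells, replace = TRUE, prob = freqs)
    ids <- sprintf("%s_cell%05d", tp, seq_len(n_cells))
    mt_umis <- .rumis(n_cells, umis_per_cell)
    cnt <- .resample_counts(cbind(m[lin], s[lin], 1 - m[lin] - s[lin]),
                            mt_umis)
    rows <- lapply(seq_len(n_cells), function(i) {
      al <- rep(c("missense", "silent", "wt"), cnt[i, ])
      k <- length(al)
      lk <- .rumis(1L, lineage_umis_per_cell)
      data.table::data.table(
        cell_id = ids[i],
        amplicon = c(rep("mt_amp", k), rep("lineage", lk)),
        umi = .random_dna(k + lk, 8L),
        allele = c(al, rep(barcodes[lin[i]], lk)))
    })
    umis <- data.table::rbindlist(rows)
    umis[, reads := .rreads(.N, reads_per_umi) + 2L]
    list(umi = umis[], cells = data.table::data.table(
      cell_id = ids, lineage = barcodes[lin]))
  }
  tp0 <- sample_tp(freq0, "d0")
  tp1 <- sample_tp(freq1, "d5")
  list(umi_day0 = tp0$umi, umi_day5 = tp1$umi,
       truth_lineages = data.table::data.table(
         lineage = barcodes, true_missense = m, true_silent = s,
         freq_day0 = freq0, freq_day5 = freq1),
       truth_cells_day0 = tp0$cells, truth_cells_day5 = tp1$cells,
       table = default_edit_table(), lineage_tab = default_lineage_table())
}
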