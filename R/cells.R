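# Cell-level analysis: UMI -> consensus allele, knee-plot cell calling,
# per-cell heteroplasmy, barnyard classification, saturation and relative
# abundance summaries.

#' Resolve one UMI to a consensus allele
#'
#' A UMI sometimes carries reads reporting different alleles (PCR or
#' sequencing errors).  The consensus rule requires at least three reads per
#' UMI and assigns the allele supported by at least 2/3 of them; UMIs with
#' fewer than three reads, or with no 2/3 majority, are discarded.
#'
#' @param counts named non-negative integer vector of read counts per
#'   allele for one UMI.
#' @return the winning allele name, or `NA_character_` for a discarded UMI.
#' @examples
#' resolve_umi_allele(c(A = 3))            # "A"
#' resolve_umi_allele(c(A = 2, B = 1))     # "A": 2/3 exactly
#' resolve_umi_allele(c(A = 1, B = 1))     # NA: fewer than 3 reads
#' resolve_umi_allele(c(A = 2, B = 2))     # NA: no 2/3 majority
#' @export
resolve_umi_allele <- function(counts) {
  if (length(counts) == 0 || all(counts == 0))
    stop("counts must contain at least one positive entry")
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total < 3L) return(NA_character_)
  top <- which.max(counts)
  if (3L * counts[top] >= 2L * total) names(counts)[top] else NA_character_
}

#' Collapse a UMI table to consensus allele counts per cell
#'
#' Applies the UMI consensus rule ([resolve_umi_allele()]) to every
#' (cell, amplicon, UMI) group and tallies consensus UMIs per allele.
#'
#' @param umi_table `data.table` from [build_umi_table()].
#' @return `data.table` with columns `cell_id`, `amplicon`, `allele`,
#'   `umis`; attribute `discarded_umis` holds the number of UMIs dropped by
#'   the consensus filter.
#' @export
collapse_umis <- function(umi_table) {
  stopifnot(all(c("cell_id", "amplicon", "umi", "allele", "reads") %in%
                  names(umi_table)))
  # vectorized consensus: per UMI group, total reads and best allele
  g <- umi_table[, .(reads = sum(reads)), by = .(cell_id, amplicon, umi, allele)]
  tot <- g[, .(total = sum(reads), top = max(reads),
               top_allele = allele[which.max(reads)]),
           by = .(cell_id, amplicon, umi)]
  tot[, keep := total >= 3L & 3L * top >= 2L * total]
  n_discarded <- sum(!tot$keep)
  cons <- tot[keep == TRUE,
              .(umis = .N), by = .(cell_id, amplicon, allele = top_allele)]
  data.table::setkey(cons, cell_id, amplicon)
  data.table::setattr(cons, "discarded_umis", n_discarded)
  cons[]
}

#' Total consensus UMIs per cell
#'
#' @param cell_counts output of [collapse_umis()].
#' @param exclude_amplicons amplicons (e.g. the lineage-barcode amplicon)
#'   whose UMIs are excluded from the coverage used for cell calling.
#' @return `data.table` with `cell_id`, `total_umis`, sorted decreasing.
#' @export
cell_coverage <- function(cell_counts, exclude_amplicons = character(0)) {
  cov <- cell_counts[!amplicon %in% exclude_amplicons,
                     .(total_umis = sum(umis)), by = cell_id]
  data.table::setorder(cov, -total_umis)
  cov[]
}

#' Call valid cells at the knee of the UMI rank curve
#'
#' Real cells and background barcodes separate on a log10 UMI-count versus
#' log10 rank curve.  In automatic mode the threshold is placed at the point
#' of maximum perpendicular distance from the straight line joining the
#' curve's endpoints; a manual `min_umis` always wins (e.g. a fixed
#' threshold of 64 UMIs, or 2 to keep every barcode with more than one
#' UMI).  If the curve has no discernible knee (maximum deviation close to
#' zero, or too few candidate barcodes), the function warns and falls back
#' to the 99th percentile of UMI counts.
#'
#' @param coverage `data.table` from [cell_coverage()] (columns `cell_id`,
#'   `total_umis`), or a named numeric vector of per-cell UMI totals.
#' @param min_umis optional manual threshold; overrides the knee.
#' @return list of class `scilite_knee` with `threshold`, `retained`
#'   (cell ids), `curve` (rank, total_umis), and `method` (`"auto"`,
#'   `"manual"` or `"fallback"`).
#' @export
call_cells <- function(coverage, min_umis = NULL) {
  if (!is.data.frame(coverage)) {
    coverage <- data.table::data.table(cell_id = names(coverage),
                                       total_umis = as.numeric(coverage))
  } else {
    coverage <- data.table::as.data.table(coverage)
  }
  data.table::setorder(coverage, -total_umis)
  curve <- coverage[, .(cell_id, total_umis, rank = seq_len(.N))]
  if (!is.null(min_umis)) {
    thr <- as.numeric(min_umis)
    method <- "manual"
  } else {
    if (nrow(curve) < 10L)
      stop("automatic knee calling needs at least 10 candidate cells")
    x <- log10(curve$rank)
    y <- log10(curve$total_umis)
    # perpendicular distance from the chord between the curve endpoints
    # locates the shoulder of the cell population ...
    dx <- x[length(x)] - x[1L]
    dy <- y[length(y)] - y[1L]
    nrm <- sqrt(dx^2 + dy^2)
    dist <- abs(dx * (y[1L] - y) - dy * (x[1L] - x)) / nrm
    if (max(dist) < 0.05 || diff(range(y)) < .Machine$double.eps) {
      warning("no knee detected on the rank curve; ",
              "falling back to the 99th percentile of UMI counts")
      thr <- as.numeric(stats::quantile(curve$total_umis, 0.99, type = 1))
      method <- "fallback"
    } else {
      # ... and the threshold is placed at the steepest descent of the
      # distinct-count step curve at or beyond the shoulder (the cliff
      # separating cells from ambient barcodes); the midpoint of the
      # steepest segment keeps the whole upper population
      shoulder_rank <- curve$rank[which.max(dist)]
      steps <- curve[, .(last_rank = max(rank)), by = total_umis]
      xs <- log10(steps$last_rank)
      ys <- log10(steps$total_umis)
      ok <- which(steps$last_rank >= shoulder_rank)
      if (length(ok) >= 2L) {
        seg <- ok[-length(ok)]
        slope <- (ys[seg + 1L] - ys[seg]) / pmax(xs[seg + 1L] - xs[seg], 1e-9)
        j <- seg[which.min(slope)]
        thr <- 10^((ys[j] + ys[j + 1L]) / 2)
      } else {
        thr <- curve$total_umis[which.max(dist)]
      }
      method <- "auto"
    }
  }
  thr <- max(thr, 1)
  structure(list(threshold = thr,
                 retained = curve[total_umis >= thr, cell_id],
                 curve = curve[, .(rank, total_umis)],
                 method = method),
            class = "scilite_knee")
}

#' @export
print.scilite_knee <- function(x, ...) {
  cat("knee threshold: ", x$threshold, " UMIs (", x$method, "); ",
      length(x$retained), " cells retained\n", sep = "")
  invisible(x)
}

#' Per-cell heteroplasmy from consensus UMI counts
#'
#' Heteroplasmy of an allele in a cell is the number of consensus UMIs for
#' that allele divided by the total UMIs of the same amplicon in that cell.
#' For edit-type allele tables the derived summaries follow the edit
#' semantics: `missense_het` counts UMIs of every missense-containing allele
#' (the single missense edit and the missense+silent double edit), while
#' `silent_het` counts only UMIs showing the silent edit alone; the double
#' edit stays in the denominator of both.
#'
#' @param cell_counts `data.table` from [collapse_umis()].
#' @param table the [allele_table()] of the amplicon being summarized.
#' @param cells optional cell ids to keep (e.g. knee-retained cells).
#' @return `data.table` with one row per cell: per-allele fraction columns
#'   (`frac_<allele>`), `missense_het`, `silent_het`, `wt_het`,
#'   `total_umis`.
#' @export
compute_heteroplasmy <- function(cell_counts, table, cells = NULL) {
  stopifnot(inherits(table, "scilite_allele_table"), table$mode == "diagnostic")
  x <- cell_counts[amplicon == table$amplicon]
  if (!is.null(cells)) x <- x[cell_id %in% cells]
  allele_names <- names(table$alleles)
  if (nrow(x) == 0) return(.empty_het(allele_names))
  wide <- data.table::dcast(x, cell_id ~ allele, value.var = "umis", fill = 0L)
  for (a in allele_names)
    if (!a %in% names(wide)) data.table::set(wide, j = a, value = 0L)
  cnt <- as.matrix(wide[, ..allele_names])
  total <- rowSums(cnt)
  frac <- cnt / total
  tags <- table$tags[allele_names]
  out <- data.table::data.table(cell_id = wide$cell_id)
  for (a in allele_names)
    data.table::set(out, j = paste0("frac_", a), value = frac[, a])
  out[, missense_het := rowSums(frac[, tags %in% c("missense", "both"),
                                     drop = FALSE])]
  out[, silent_het := rowSums(frac[, tags == "silent", drop = FALSE])]
  out[, wt_het := rowSums(frac[, tags == "wild-type", drop = FALSE])]
  out[, total_umis := as.integer(total)]
  out[]
}

.empty_het <- function(allele_names) {
  out <- data.table::data.table(cell_id = character(0))
  for (a in allele_names)
    data.table::set(out, j = paste0("frac_", a), value = numeric(0))
  out[, c("missense_het", "silent_het", "wt_het") :=
        list(numeric(0), numeric(0), numeric(0))]
  out[, total_umis := integer(0)]
  out[]
}

#' Classify barnyard cells
#'
#' In a barnyard experiment two cell lines with distinguishable alleles are
#' mixed; a retained cell whose allele fractions are dominated by one line
#' is assigned to that line, and cells with mixed alleles are considered
#' doublets.
#'
#' @param het `data.table` from [compute_heteroplasmy()] on an allele table
#'   carrying cell-line tags (`"hela"`, `"293t"`).
#' @param table the barnyard [allele_table()].
#' @param purity minimum fraction of a cell's UMIs that must come from one
#'   line for a singlet call (default 0.9).
#' @return `data.table` with `cell_id` and `class` in
#'   `{"HELA", "293T", "DOUBLET"}`.
#' @export
barnyard_classify <- function(het, table, purity = 0.9) {
  tags <- table$tags
  hela_alleles <- names(tags)[tags == "hela"]
  t293_alleles <- names(tags)[tags == "293t"]
  if (!length(hela_alleles) || !length(t293_alleles))
    stop("allele table must tag both cell lines ('hela', '293t')")
  hela_frac <- rowSums(as.matrix(het[, paste0("frac_", hela_alleles),
                                     with = FALSE]))
  t293_frac <- rowSums(as.matrix(het[, paste0("frac_", t293_alleles),
                                     with = FALSE]))
  cls <- ifelse(hela_frac >= purity, "HELA",
                ifelse(t293_frac >= purity, "293T", "DOUBLET"))
  data.table::data.table(cell_id = het$cell_id, class = cls,
                         hela_frac = hela_frac, t293_frac = t293_frac)
}

#' Heterotypic doublet rate
#'
#' @param classes `data.table` from [barnyard_classify()] (or a character
#'   vector of classes).
#' @return fraction of retained cells classified `DOUBLET`.
#' @export
heterotypic_doublet_rate <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  if (length(classes) == 0) stop("no classified cells")
  mean(classes == "DOUBLET")
}

#' UMI saturation curve by read downsampling
#'
#' Subsamples the accepted reads without replacement at each requested
#' fraction, re-runs UMI collapse and cell calling, and reports the median
#' consensus UMIs per retained cell — the standard saturation diagnostic of
#' sequencing depth.
#'
#' @param parsed accepted-read table from [parse_reads()] (rejected rows are
#'   ignored).
#' @param fractions numeric fractions in (0, 1].
#' @param seed RNG seed for the subsampling.
#' @param min_umis manual cell-calling threshold applied at every depth
#'   (`NULL` for automatic knee calling per depth).
#' @return `data.table` with `fraction`, `reads`, `median_umis`,
#'   `n_cells`.
#' @export
saturation_curve <- function(parsed, fractions = c(0.1, 0.25, 0.5, 0.75, 1),
                             seed = 1L, min_umis = NULL) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  keep <- parsed[is.na(reason)]
  n <- nrow(keep)
  set.seed(seed)
  out <- lapply(sort(fractions), function(f) {
    idx <- if (f == 1) seq_len(n) else sample.int(n, size = round(f * n))
    ut <- build_umi_table(keep[idx])
    cc <- collapse_umis(ut)
    cov <- cell_coverage(cc)
    kr <- call_cells(cov, min_umis = min_umis)
    ret <- cov[cell_id %in% kr$retained]
    data.table::data.table(fraction = f, reads = length(idx),
                           median_umis = stats::median(ret$total_umis),
                           n_cells = nrow(ret))
  })
  data.table::rbindlist(out)
}

#' Relative transcript abundance across conditions
#'
#' Per condition, the median total UMIs per retained cell divided by the
#' reference condition's median; a readout of relative target-transcript
#' abundance.
#'
#' @param coverages named list of per-condition coverage tables (from
#'   [cell_coverage()], knee-filtered by the caller).
#' @param reference name of the reference condition.
#' @return `data.table` with `condition`, `median_umis`,
#'   `relative_abundance` (`NA` for empty conditions).
#' @export
relative_abundance <- function(coverages, reference) {
  if (!reference %in% names(coverages)) stop("reference condition not present")
  med <- vapply(coverages, function(x) {
    if (is.null(x) || nrow(x) == 0) NA_real_
    else stats::median(as.numeric(x$total_umis))
  }, numeric(1))
  data.table::data.table(condition = names(coverages),
                         median_umis = med,
                         relative_abundance = med / med[[reference]])
}
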