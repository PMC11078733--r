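# Lineage tracing: clonal ancestry-barcode assignment, per-lineage
# heteroplasmy dynamics between timepoints, and lineage-dropout statistics.

#' Assign a cell to a clonal lineage barcode
#'
#' Cells occasionally show UMIs for several lineage barcodes (ambient
#' molecules, barcode collisions).  Assignment applies two filters: lineage
#' barcodes supported by fewer than 10 UMIs are removed, and the remaining
#' top barcode must have at least four times the UMIs of the second-ranked
#' barcode; otherwise the cell is left unassigned.
#'
#' @param counts named non-negative numeric vector of UMI counts per
#'   candidate lineage barcode in one cell.
#' @param min_umis minimum UMIs per candidate barcode (default 10).
#' @param ratio required top / second ratio (default 4; inclusive).
#' @return the assigned barcode name, or `NA_character_` when unassigned.
#' @examples
#' assign_lineage(c(L1 = 40))            # "L1"
#' assign_lineage(c(L1 = 40, L2 = 9))    # "L1": L2 removed by the <10 filter
#' assign_lineage(c(L1 = 40, L2 = 15))   # NA: 40 < 4 * 15
#' assign_lineage(c(L1 = 60, L2 = 15))   # "L1": "at least four times" holds
#' @export
assign_lineage <- function(counts, min_umis = 10, ratio = 4) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts >= min_umis]
  if (length(counts) == 0) return(NA_character_)
  if (length(counts) == 1) return(names(counts))
  ord <- order(counts, decreasing = TRUE)
  top <- counts[ord[1L]]
  second <- counts[ord[2L]]
  if (top >= ratio * second) names(counts)[ord[1L]] else NA_character_
}

#' Assign lineages for every cell in a UMI-collapsed table
#'
#' @param cell_counts `data.table` from [collapse_umis()] containing the
#'   lineage-barcode amplicon (allele column = matched lineage barcode).
#' @param lineage_amplicon name of the lineage amplicon.
#' @param min_umis,ratio filters passed to [assign_lineage()].
#' @return `data.table` with `cell_id`, `lineage` (`NA` when unassigned)
#'   and `lineage_umis` (UMIs supporting the assigned barcode).
#' @export
assign_lineages <- function(cell_counts, lineage_amplicon = "lineage",
                            min_umis = 10, ratio = 4) {
  x <- cell_counts[amplicon == lineage_amplicon]
  if (nrow(x) == 0)
    return(data.table::data.table(cell_id = character(0),
                                  lineage = character(0),
                                  lineage_umis = numeric(0)))
  x[, pass := umis >= min_umis]
  res <- x[, {
    k <- umis[pass]
    b <- allele[pass]
    if (length(k) == 0) {
      list(lineage = NA_character_, lineage_umis = NA_real_)
    } else if (length(k) == 1L) {
      list(lineage = b[1L], lineage_umis = as.numeric(k[1L]))
    } else {
      o <- order(k, decreasing = TRUE)
      if (k[o[1L]] >= ratio * k[o[2L]])
        list(lineage = b[o[1L]], lineage_umis = as.numeric(k[o[1L]]))
      else list(lineage = NA_character_, lineage_umis = NA_real_)
    }
  }, by = cell_id]
  res[]
}

#' Per-lineage heteroplasmy dynamics between two timepoints
#'
#' Summarizes each lineage at each timepoint by its (unweighted) mean
#' missense and silent heteroplasmy and cell count, classifies every
#' lineage by presence (`day0-only`, `day5-only`, `both`) and, for lineages
#' seen at both timepoints, reports the change in mean heteroplasmy.
#'
#' @param het0,het1 per-cell heteroplasmy tables ([compute_heteroplasmy()])
#'   at the first and second timepoint.
#' @param assign0,assign1 lineage assignments ([assign_lineages()]) at the
#'   two timepoints; unassigned cells are dropped.
#' @param labels names of the two timepoints (used in the presence class).
#' @return list with `per_lineage` (lineage, timepoint, n_cells, mean
#'   missense/silent heteroplasmy), `classes` (lineage, class) and `deltas`
#'   (lineage, delta_missense, delta_silent) for class `both`.
#' @export
lineage_dynamics <- function(het0, het1, assign0, assign1,
                             labels = c("day0", "day5")) {
  j0 <- merge(het0, assign0[!is.na(lineage)], by = "cell_id")
  j1 <- merge(het1, assign1[!is.na(lineage)], by = "cell_id")
  s0 <- j0[, .(n_cells = .N, mean_missense = mean(missense_het),
               mean_silent = mean(silent_het)), by = lineage]
  s1 <- j1[, .(n_cells = .N, mean_missense = mean(missense_het),
               mean_silent = mean(silent_het)), by = lineage]
  s0[, timepoint := labels[1L]]
  s1[, timepoint := labels[2L]]
  per_lineage <- data.table::rbindlist(list(s0, s1), use.names = TRUE)
  all_lin <- union(s0$lineage, s1$lineage)
  cls <- data.table::data.table(lineage = all_lin)
  cls[, class := ifelse(lineage %in% s0$lineage & lineage %in% s1$lineage,
                        "both",
                        ifelse(lineage %in% s0$lineage,
                               paste0(labels[1L], "-only"),
                               paste0(labels[2L], "-only")))]
  shared <- merge(s0, s1, by = "lineage", suffixes = c("_0", "_1"))
  if (nrow(shared) == 0)
    warning("no lineages shared between the two timepoints")
  deltas <- shared[, .(lineage,
                       delta_missense = mean_missense_1 - mean_missense_0,
                       delta_silent = mean_silent_1 - mean_silent_0)]
  list(per_lineage = per_lineage[], classes = cls[], deltas = deltas[])
}

#' Test whether dropped-out lineages differ in heteroplasmy
#'
#' Compares the per-cell heteroplasmy (at the first timepoint) of cells
#' belonging to lineages seen only at the first timepoint against cells in
#' lineages persisting to the second timepoint, using the two-sample
#' Kolmogorov-Smirnov test (asymptotic p) and the two-sided Mann-Whitney
#' test.  Under selection against high heteroplasmy, dropped-out lineages
#' are expected to show higher heteroplasmy.
#'
#' @param dynamics output of [lineage_dynamics()].
#' @param het0 per-cell heteroplasmy at the first timepoint.
#' @param assign0 lineage assignments at the first timepoint.
#' @param value heteroplasmy column compared (default `"missense_het"`).
#' @return list with per-group medians and sizes, `D`, `ks_p`, `mw_p`
#'   (statistics are `NA` when either group has fewer than two cells).
#' @export
dropout_test <- function(dynamics, het0, assign0, value = "missense_het") {
  cls <- dynamics$classes
  j <- merge(het0, assign0[!is.na(lineage)], by = "cell_id")
  j <- merge(j, cls, by = "lineage")
  # at the first timepoint the only "-only" lineages with cells are the
  # first-timepoint-only (dropped-out) ones
  x <- j[grepl("-only$", class)][[value]]
  y <- j[class == "both"][[value]]
  res <- list(n_dropped = length(x), n_persistent = length(y),
              median_dropped = stats::median(x),
              median_persistent = stats::median(y),
              D = NA_real_, ks_p = NA_real_, mw_p = NA_real_)
  if (length(x) >= 2 && length(y) >= 2) {
    ks <- suppressWarnings(stats::ks.test(x, y))
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    res$D <- unname(ks$statistic)
    res$ks_p <- ks$p.value
    res$mw_p <- mw$p.value
  }
  res
}
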