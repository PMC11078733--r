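test_that("UMI consensus rule: worked examples", {
  expect_identical(resolve_umi_allele(c(A = 3)), "A")
  expect_identical(resolve_umi_allele(c(A = 2, B = 1)), "A")  # exactly 2/3
  expect_true(is.na(resolve_umi_allele(c(A = 1, B = 1))))     # < 3 reads
  expect_true(is.na(resolve_umi_allele(c(A = 2, B = 2))))     # no majority
  expect_error(resolve_umi_allele(c(A = 0, B = 0)), "positive")
})

test_that("UMI collapse conserves UMIs and matches the per-UMI rule", {
  set.seed(7)
  n_umi <- 400L
  ut <- data.table::data.table(
    cell_id = sample(sprintf("c%02d", 1:20), n_umi, replace = TRUE),
    amplicon = "mt_amp",
    umi = sprintf("u%04d", seq_len(n_umi)))
  long <- ut[rep(seq_len(n_umi), each = 3)]
  long[, allele := sample(c("wt", "missense", "silent"), .N, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2))]
  long <- long[, .(reads = .N), by = .(cell_id, amplicon, umi, allele)]
  # randomly drop some rows so some UMIs fall under 3 reads
  long <- long[runif(.N) > 0.2]
  cc <- collapse_umis(long)
  n_total_umis <- long[, data.table::uniqueN(paste(cell_id, umi))]
  expect_equal(sum(cc$umis) + attr(cc, "discarded_umis"), n_total_umis)

  # agreement with the scalar rule on every UMI
  per_umi <- long[, .(expected = oracle_consensus(
    stats::setNames(reads, allele))), by = .(cell_id, amplicon, umi)]
  expected <- per_umi[!is.na(expected),
                      .(umis = .N), by = .(cell_id, amplicon, expected)]
  merged <- merge(cc, expected,
                  by.x = c("cell_id", "amplicon", "allele"),
                  by.y = c("cell_id", "amplicon", "expected"), all = TRUE)
  expect_true(all(merged$umis.x == merged$umis.y))
})

test_that("heteroplasmy fractions follow the edit semantics and sum to one", {
  tab <- tiny_edit_table()
  cc <- data.table::data.table(
    cell_id = "c1", amplicon = "mt_amp",
    allele = c("missense", "both", "silent", "wt"),
    umis = c(3L, 1L, 1L, 1L))
  het <- compute_heteroplasmy(cc, tab)
  expect_equal(het$missense_het, 4 / 6)   # double edit counted as missense
  expect_equal(het$silent_het, 1 / 6)     # and excluded from silent
  expect_equal(het$total_umis, 6L)

  # all wild-type
  het_wt <- compute_heteroplasmy(
    data.table::data.table(cell_id = "c2", amplicon = "mt_amp",
                           allele = "wt", umis = 10L), tab)
  expect_equal(het_wt$missense_het, 0)
  expect_equal(het_wt$silent_het, 0)

  # random tables: fractions sum to 1 for every cell
  set.seed(8)
  rnd <- data.table::data.table(
    cell_id = rep(sprintf("r%02d", 1:30), each = 4),
    amplicon = "mt_amp",
    allele = rep(c("wt", "missense", "silent", "both"), 30),
    umis = rpois(120, 5) + 1L)
  hr <- compute_heteroplasmy(rnd, tab)
  frac_cols <- paste0("frac_", names(tab$alleles))
  expect_equal(rowSums(as.matrix(hr[, ..frac_cols])), rep(1, 30))
  expect_true(all(hr$missense_het >= 0 & hr$missense_het <= 1))
})

test_that("knee calling separates planted cell and background populations", {
  set.seed(21)
  counts <- c(rnbinom(1000, mu = 500, size = 8), pmax(1, rpois(10000, 2)))
  names(counts) <- sprintf("bc%05d", seq_along(counts))
  kr <- call_cells(counts)
  real <- names(counts)[1:1000]
  expect_gte(mean(kr$retained %in% real), 0.99)   # precision
  expect_gte(mean(real %in% kr$retained), 0.99)   # recall
  expect_identical(kr$method, "auto")

  # manual override always wins
  km <- call_cells(counts, min_umis = 64)
  expect_equal(km$threshold, 64)
  expect_identical(km$method, "manual")

  # featureless curve falls back with a warning
  flat <- stats::setNames(rep(5, 100), sprintf("f%03d", 1:100))
  expect_warning(kf <- call_cells(flat), "knee")
  expect_identical(kf$method, "fallback")
})

test_that("barnyard classification and doublet-rate estimation", {
  tab <- default_barnyard_table()
  het <- data.table::data.table(cell_id = c("a", "b", "c"),
                                frac_hela = c(1, 0.5, 0.05),
                                frac_t293 = c(0, 0.5, 0.95),
                                missense_het = 0, silent_het = 0,
                                wt_het = 0, total_umis = 20L)
  cls <- barnyard_classify(het, tab)
  expect_identical(cls$class, c("HELA", "DOUBLET", "293T"))
  expect_equal(heterotypic_doublet_rate(cls), 1 / 3)
  expect_equal(heterotypic_doublet_rate(rep("HELA", 5)), 0)
})

test_that("saturation curve reproduces the full-depth median and saturates", {
  lib <- make_barnyard(n_cells = 120, doublet_rate = 0, umis_per_cell = 30,
                       reads_per_umi = 8, error_rate = 0, seed = 31)
  parsed <- parse_reads(lib$reads, lib$layout, lib$whitelists, lib$table)
  sat <- saturation_curve(parsed, fractions = c(0.1, 0.5, 1), seed = 5,
                          min_umis = 2)
  expect_equal(nrow(sat), 3L)
  # non-decreasing with depth
  expect_true(all(diff(sat$median_umis) >= 0))
  # fraction 1 equals the direct full-depth computation
  cov <- cell_coverage(collapse_umis(build_umi_table(parsed)))
  full <- stats::median(cov[total_umis >= 2, total_umis])
  expect_equal(sat[fraction == 1, median_umis], full)
  expect_error(saturation_curve(parsed, fractions = 0), "fraction")
})

test_that("relative abundance is median-normalized to the reference", {
  mkcov <- function(v) data.table::data.table(cell_id = seq_along(v),
                                              total_umis = v)
  res <- relative_abundance(list(ref = mkcov(rep(100, 50)),
                                 half = mkcov(rep(50, 50)),
                                 none = mkcov(numeric(0))),
                            reference = "ref")
  expect_equal(res[condition == "ref", relative_abundance], 1)
  expect_equal(res[condition == "half", relative_abundance], 0.5)
  expect_true(is.na(res[condition == "none", relative_abundance]))
  expect_error(relative_abundance(list(a = mkcov(1)), "missing"), "reference")
})
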