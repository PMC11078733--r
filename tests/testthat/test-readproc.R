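test_that("whitelist correction matches exhaustive nearest-neighbour search", {
  # documented behaviour on hand-built lists
  wl <- whitelist(c("AAAA", "CCCC"))
  expect_identical(correct_sequence("AAAA", wl), "AAAA")
  expect_identical(correct_sequence("AAAT", wl), "AAAA")
  wl2 <- suppressWarnings(whitelist(c("AAAA", "AATT")))
  res <- correct_sequence("AATA", wl2, detail = TRUE)
  expect_true(is.na(res$corrected))
  expect_identical(res$status, "ambiguous")
  expect_error(correct_sequence("AAA", wl), "width")

  # randomized oracle comparison
  set.seed(42)
  wl_seqs <- unique(replicate(60, paste(sample(c("A", "C", "G", "T"), 8,
                                               replace = TRUE), collapse = "")))
  wl3 <- suppressWarnings(whitelist(wl_seqs))
  observed <- c(
    sample(wl_seqs, 100, replace = TRUE),
    vapply(sample(wl_seqs, 100, replace = TRUE), mutate_at, character(1),
           pos = sample(8, 1)),
    replicate(200, paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                         collapse = "")))
  expect_identical(unname(correct_sequence(observed, wl3)),
                   oracle_correct(observed, wl_seqs))
})

test_that("parsing round-trips error-free synthetic libraries with zero rejections", {
  lib <- make_barnyard(n_cells = 150, doublet_rate = 0, umis_per_cell = 10,
                       reads_per_umi = 3, error_rate = 0, seed = 11)
  parsed <- parse_reads(lib$reads, lib$layout, lib$whitelists, lib$table)
  expect_equal(nrow(parsed), length(lib$reads))   # conservation
  expect_equal(sum(!is.na(parsed$reason)), 0L)
  ut <- build_umi_table(parsed)
  expect_equal(sum(ut$reads), length(lib$reads))
  expect_true(all(ut$cell_id %in% lib$truth$cell_id))
})

test_that("single substitutions are corrected and double substitutions rejected", {
  rt <- sep_rt_wl(); lig <- sep_lig_wl()
  tab <- tiny_edit_table()
  wls <- list(rt = rt, ligation = lig)
  clean <- build_read(lig$sequences[1], "ACGTACGT", rt$sequences[2], "GT",
                      tab, "missense")
  p0 <- parse_reads(clean, read_layout(), wls, tab)
  expect_identical(p0$allele, "missense")
  expect_identical(p0$rt, rt$sequences[2])

  # one substitution in the RT barcode (offset 19 = within rt segment)
  one_err <- mutate_at(clean, 19)
  p1 <- parse_reads(one_err, read_layout(), wls, tab)
  expect_identical(p1[, .(rt, ligation, umi, amplicon, allele)],
                   p0[, .(rt, ligation, umi, amplicon, allele)])

  # two substitutions in the ligation barcode
  two_err <- mutate_at(clean, c(2, 5))
  p2 <- parse_reads(two_err, read_layout(), wls, tab)
  expect_identical(p2$reason, "bad-barcode")

  # base matching no configured allele at a diagnostic offset
  amp_start <- 28 + 2 + 1  # prefix 28 + spacer 2, 1-based
  bad_diag <- clean
  substr(bad_diag, amp_start + tab$offsets[1] - 1,
         amp_start + tab$offsets[1] - 1) <- "C"   # alleles use only A/G here
  expect_identical(parse_reads(bad_diag, read_layout(), wls, tab)$reason,
                   "bad-allele")
  # one mismatch in the constant region is tolerated
  const_pos <- setdiff(seq_len(tab$width), tab$offsets)[25]
  soft <- mutate_at(clean, amp_start + const_pos - 1)
  expect_identical(parse_reads(soft, read_layout(), wls, tab)$allele,
                   "missense")
  # unrecognizable amplicon
  garbage <- paste0(substr(clean, 1, 28), strrep("A", 40))
  expect_identical(parse_reads(garbage, read_layout(), wls, tab)$reason,
                   "no-anchor")
})

test_that("spacer lengths are resolved by anchor matching", {
  rt <- sep_rt_wl(); lig <- sep_lig_wl()
  tab <- tiny_edit_table()
  reads <- vapply(0:3, function(k)
    build_read(lig$sequences[1], "AAAACCCC", rt$sequences[1],
               strrep("C", k), tab, "silent"), character(1))
  p <- parse_reads(reads, read_layout(), list(rt = rt, ligation = lig), tab)
  expect_true(all(is.na(p$reason)))
  expect_true(all(p$allele == "silent"))
})

test_that("UMI tables aggregate reads per cell, amplicon, UMI and allele", {
  rt <- sep_rt_wl(); lig <- sep_lig_wl()
  tab <- tiny_edit_table()
  wls <- list(rt = rt, ligation = lig)
  r1 <- build_read(lig$sequences[1], "ACGTACGT", rt$sequences[1], "", tab, "wt")
  r2 <- build_read(lig$sequences[2], "ACGTACGT", rt$sequences[1], "", tab, "wt")
  parsed <- parse_reads(c(r1, r1, r1, r2), read_layout(), wls, tab)
  ut <- build_umi_table(parsed)
  expect_equal(nrow(ut), 2L)            # two distinct barcode paths
  expect_equal(sort(ut$reads), c(1L, 3L))
  expect_equal(length(unique(ut$cell_id)), 2L)

  empty <- build_umi_table(parsed[0])
  expect_equal(nrow(empty), 0L)
})

test_that("bulk allele counting follows the edit semantics", {
  tab <- tiny_edit_table()
  seqs <- scilite:::.allele_sequences(tab)
  reads <- c(rep(seqs[["missense"]], 2), seqs[["both"]], seqs[["silent"]],
             seqs[["wt"]], strrep("G", tab$width))
  res <- count_bulk_alleles(reads, tab)
  expect_equal(res$missense_het, 3 / 5)  # missense counts the double edit
  expect_equal(res$silent_het, 1 / 5)    # silent excludes it
  expect_equal(unname(res$counts[["discarded"]]), 1L)
  # non-discarded fractions sum to one
  expect_equal(res$missense_het + res$silent_het +
                 unname(res$counts[["wt"]]) / res$total, 1)

  all_wt <- count_bulk_alleles(rep(seqs[["wt"]], 10), tab)
  expect_equal(all_wt$missense_het, 0)
  expect_equal(all_wt$silent_het, 0)

  none <- count_bulk_alleles(rep(strrep("G", tab$width), 4), tab)
  expect_true(is.na(none$missense_het))
  expect_true(is.na(none$silent_het))
})

test_that("FASTQ round trip preserves sequences", {
  seqs <- c("ACGTACGTAA", "TTGGCCAATT")
  fp <- tempfile(fileext = ".fastq.gz")
  write_fastq(seqs, fp)
  expect_identical(read_fastq(fp), setNames(seqs, sprintf("read%06d", 1:2)))
  unlink(fp)
})
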