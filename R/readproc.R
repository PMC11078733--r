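# Read-level processing: layout description, barcode whitelists, allele
# tables, Hamming-1 error correction, read parsing and UMI-table assembly.

#' Describe the structure of a combinatorial-indexing read
#'
#' A read is an ordered run of segments: cell-barcode segments added during
#' reverse transcription and ligation, a UMI, a variable-length
#' "heterogeneity spacer" that phases otherwise identical amplicons across
#' sequencing cycles, and the targeted amplicon itself.  The exact base-level
#' coordinates are protocol-specific, so the layout is configuration, not
#' code; the defaults here are documented stand-ins with the canonical
#' segment ordering (ligation barcode, UMI, RT barcode, spacer, amplicon).
#'
#' @param segments list of segment descriptors, each a list with `name`,
#'   `kind` (one of `"barcode"`, `"umi"`, `"spacer"`, `"amplicon"`) and
#'   `length` (a positive integer; for the spacer, a vector of allowed
#'   lengths; for the trailing amplicon, `NA` meaning "rest of read").
#' @return An object of class `scilite_layout`.
#' @examples
#' lay <- read_layout()
#' lay$spacer_lengths
#' @export
read_layout <- function(segments = list(
                          list(name = "ligation", kind = "barcode", length = 10L),
                          list(name = "umi",      kind = "umi",     length = 8L),
                          list(name = "rt",       kind = "barcode", length = 10L),
                          list(name = "spacer",   kind = "spacer",  length = 0:3),
                          list(name = "amplicon", kind = "amplicon", length = NA))) {
  kinds <- vapply(segments, `[[`, character(1), "kind")
  if (sum(kinds == "umi") != 1L)
    stop("layout must contain exactly one umi segment")
  if (!any(kinds == "barcode"))
    stop("layout must contain at least one barcode segment")
  if (sum(kinds == "spacer") > 1L)
    stop("at most one spacer segment is supported")
  if (which(kinds == "amplicon") != length(segments))
    stop("the amplicon segment must come last")
  pre <- segments[seq_len(which(kinds == "amplicon") - 1L)]
  for (s in pre) {
    if (s$kind == "spacer") next
    if (!is.numeric(s$length) || length(s$length) != 1L || is.na(s$length) || s$length <= 0)
      stop("segment '", s$name, "' must have a single positive length")
  }
  spacer_lengths <- 0L
  if (any(kinds == "spacer")) {
    spacer_lengths <- sort(unique(as.integer(segments[[which(kinds == "spacer")]]$length)))
    if (any(spacer_lengths < 0) || length(spacer_lengths) == 0 || any(!is.finite(spacer_lengths)))
      stop("spacer lengths must be a finite set of non-negative integers")
  }
  fixed <- pre[vapply(pre, function(s) s$kind != "spacer", logical(1))]
  structure(list(
    segments = segments,
    fixed_segments = fixed,
    prefix_length = sum(vapply(fixed, function(s) as.integer(s$length), integer(1))),
    spacer_lengths = spacer_lengths
  ), class = "scilite_layout")
}

#' Barcode whitelist
#'
#' Holds the set of expected sequences for one barcode round.  Correction of
#' one substitution error is only unambiguous when the minimum pairwise
#' Hamming distance within the list is at least 3; a smaller separation
#' triggers a warning at construction.
#'
#' @param sequences character vector of equal-length DNA strings (A/C/G/T).
#' @param name label for the barcode round (e.g. `"rt"`, `"ligation"`).
#' @return An object of class `scilite_whitelist`.
#' @export
whitelist <- function(sequences, name = "barcode") {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0) stop("empty whitelist")
  if (anyDuplicated(sequences)) stop("whitelist contains duplicate sequences")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("whitelist sequences must all have the same length")
  if (any(grepl("[^ACGT]", sequences))) stop("whitelist sequences must be over {A,C,G,T}")
  min_d <- NA_integer_
  if (length(sequences) > 1L && length(sequences) <= 2000L) {
    m <- .seq_char_matrix(sequences)
    d <- w
    for (i in seq_len(length(sequences) - 1L)) {
      di <- colSums(t(m[-seq_len(i), , drop = FALSE]) != m[i, ])
      d <- min(d, di)
    }
    min_d <- as.integer(d)
    if (min_d < 3L)
      warning("minimum pairwise Hamming distance in whitelist '", name, "' is ",
              min_d, "; single-substitution correction may be ambiguous")
  }
  structure(list(name = name, sequences = sequences, width = w,
                 min_hamming = min_d), class = "scilite_whitelist")
}

#' @export
print.scilite_whitelist <- function(x, ...) {
  cat("whitelist '", x$name, "': ", length(x$sequences), " sequences of width ",
      x$width, " (min pairwise Hamming ", x$min_hamming, ")\n", sep = "")
  invisible(x)
}

# split equal-length strings into an n x width character matrix
.seq_char_matrix <- function(x) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

# Hamming distances between each of x (equal width) and a single string ref
.hamming_to <- function(x, ref) {
  xm <- .seq_char_matrix(x)
  rv <- strsplit(ref, "", fixed = TRUE)[[1]]
  rowSums(xm != matrix(rv, nrow = length(x), ncol = length(rv), byrow = TRUE))
}

#' Correct observed sequences against a whitelist
#'
#' Maps each observed sequence to the unique whitelist member within Hamming
#' distance 1, the standard barcode error-correction rule for single
#' substitution errors.  Observations with no member at distance <= 1, or
#' with two or more members tied at distance 1, are rejected.
#'
#' @param observed character vector of observed sequences, same width as the
#'   whitelist.
#' @param wl a [whitelist()].
#' @param detail if `TRUE`, return a data.frame with the correction status
#'   (`"exact"`, `"corrected"`, `"none"`, `"ambiguous"`) alongside the
#'   corrected sequence.
#' @return character vector of corrected sequences with `NA` for rejected
#'   observations (or a data.frame when `detail = TRUE`).
#' @examples
#' wl <- whitelist(c("AAAAAAAAAA", "CCCCCCCCCC"))
#' correct_sequence(c("AAAAAAAAAA", "AAAAAAAAAT", "AACCAAAAAA"), wl)
#' @export
correct_sequence <- function(observed, wl, detail = FALSE) {
  stopifnot(inherits(wl, "scilite_whitelist"))
  observed <- as.character(observed)
  bad_len <- nchar(observed) != wl$width
  if (any(bad_len, na.rm = TRUE))
    stop("observed sequences must have width ", wl$width)
  out <- rep(NA_character_, length(observed))
  status <- rep("none", length(observed))
  hit <- match(observed, wl$sequences)
  exact <- !is.na(hit)
  out[exact] <- observed[exact]
  status[exact] <- "exact"
  if (any(!exact)) {
    uo <- unique(observed[!exact])
    um <- .seq_char_matrix(uo)
    wm <- .seq_char_matrix(wl$sequences)
    # distance of every unique unmatched observation to every whitelist member
    d <- matrix(0L, nrow = length(uo), ncol = length(wl$sequences))
    for (j in seq_len(wl$width))
      d <- d + outer(um[, j], wm[, j], "!=")
    n1 <- rowSums(d == 1L)
    corr <- rep(NA_character_, length(uo))
    st <- ifelse(n1 >= 2L, "ambiguous", "none")
    ok <- n1 == 1L
    if (any(ok)) {
      corr[ok] <- wl$sequences[apply(d[ok, , drop = FALSE], 1L, which.min)]
      st[ok] <- "corrected"
    }
    idx <- match(observed[!exact], uo)
    out[!exact] <- corr[idx]
    status[!exact] <- st[idx]
  }
  if (detail) data.frame(corrected = out, status = status) else out
}

#' Allele table for a targeted amplicon
#'
#' Defines one amplicon by its constant (reference) sequence and the set of
#' alleles distinguished by diagnostic bases at fixed offsets within it.
#' Each allele carries a semantic tag used downstream when heteroplasmy is
#' computed: `"missense"` and `"silent"` mark the two edit classes, `"both"`
#' marks molecules carrying both edits (counted with the missense class,
#' excluded from the silent class), `"wild-type"` the unedited allele, and
#' cell-line tags (for example `"hela"`, `"293t"`) mark line-of-origin
#' variants used in barnyard experiments.
#'
#' @param amplicon name of the amplicon.
#' @param reference constant amplicon sequence (the wild-type context); the
#'   leading bases double as the anchor used to resolve the spacer length.
#' @param offsets 1-based positions of the diagnostic bases within the
#'   amplicon segment.
#' @param alleles named character vector: allele name -> diagnostic bases
#'   (one base per offset, concatenated).
#' @param tags named character vector: allele name -> semantic tag.
#' @param anchor_length number of leading reference bases used as the
#'   spacer-resolution anchor.
#' @return An object of class `scilite_allele_table`.
#' @examples
#' at <- allele_table("ND4", "ACGTACGTACGTACGTACGTACGT", offsets = c(13, 17),
#'                    alleles = c(wt = "TA", mis = "CA", sil = "TG", both = "CG"),
#'                    tags = c(wt = "wild-type", mis = "missense",
#'                             sil = "silent", both = "both"))
#' @export
allele_table <- function(amplicon, reference, offsets, alleles, tags,
                         anchor_length = 12L) {
  reference <- toupper(reference)
  offsets <- as.integer(offsets)
  if (any(offsets < 1L) || any(offsets > nchar(reference)))
    stop("diagnostic offsets must fall within the amplicon reference")
  if (is.null(names(alleles)) || is.null(names(tags)))
    stop("alleles and tags must be named")
  if (!setequal(names(alleles), names(tags)))
    stop("alleles and tags must name the same alleles")
  if (any(nchar(alleles) != length(offsets)))
    stop("each allele must give one diagnostic base per offset")
  if (anyDuplicated(alleles))
    stop("allele diagnostic patterns must be mutually exclusive")
  tags <- tags[names(alleles)]
  anchor_length <- min(as.integer(anchor_length), nchar(reference))
  structure(list(
    amplicon = amplicon, reference = reference, width = nchar(reference),
    offsets = offsets, alleles = alleles, tags = tags,
    anchor = substr(reference, 1L, anchor_length),
    mode = "diagnostic"
  ), class = "scilite_allele_table")
}

#' Lineage-barcode table
#'
#' Describes an expressed clonal ancestry-barcode amplicon: a constant
#' context whose variable region is matched against the list of expected
#' lineage barcodes with a tolerance of one mismatch (the same correction
#' rule applied to cell barcodes).  The matched barcode plays the role of
#' the "allele" in the UMI table.
#'
#' @param amplicon name for the lineage amplicon.
#' @param anchor constant leading sequence used for spacer resolution and
#'   amplicon identification.
#' @param barcodes character vector of expected lineage barcodes (equal
#'   length).
#' @return An object of class `scilite_allele_table` with `mode =
#'   "whitelist"`.
#' @export
lineage_table <- function(amplicon, anchor, barcodes) {
  wl <- whitelist(barcodes, name = amplicon)
  anchor <- toupper(anchor)
  structure(list(
    amplicon = amplicon, reference = anchor,
    width = nchar(anchor) + wl$width,
    offsets = integer(0), alleles = NULL, tags = NULL,
    anchor = anchor, barcode_whitelist = wl,
    barcode_start = nchar(anchor) + 1L,
    mode = "whitelist"
  ), class = "scilite_allele_table")
}

# mismatches between substrings of reads (at 1-based position pos) and ref
.mismatch_at <- function(reads, pos, ref) {
  w <- nchar(ref)
  sub <- substr(reads, pos, pos + w - 1L)
  full <- nchar(sub) == w
  out <- rep(w + 1L, length(reads))   # too short to contain the anchor
  if (any(full)) out[full] <- .hamming_to(sub[full], ref)
  out
}

#' Parse combinatorial-indexing reads
#'
#' Splits each read into its layout segments, corrects every barcode and the
#' amplicon constant region within a Hamming distance of 1, resolves the
#' heterogeneity-spacer length by anchor matching, and reads the allele off
#' the diagnostic offsets (or matches the lineage barcode, for whitelist
#' amplicons).  Reads failing any step are kept with a rejection reason so
#' that read counts are conserved.
#'
#' Spacer resolution tries every allowed spacer length and every amplicon
#' table, accepting the combination whose anchor matches with at most one
#' mismatch; ties go to the shortest spacer.  Base qualities are ignored.
#'
#' @param seqs character vector of read sequences (see [read_fastq()]).
#' @param layout a [read_layout()].
#' @param whitelists named list of [whitelist()] objects, one per barcode
#'   segment in the layout (names must match segment names).
#' @param tables a single allele/lineage table or a list of them.
#' @param sample sample label (e.g. the Illumina index) prepended to the
#'   cell id.
#' @return A `data.table` with one row per read: `sample`, one column per
#'   barcode segment, `umi`, `amplicon`, `allele`, and `reason` (`NA` for
#'   accepted reads; otherwise `"no-anchor"`, `"bad-barcode"`,
#'   `"ambiguous-correction"` or `"bad-allele"`).
#' @export
parse_reads <- function(seqs, layout = read_layout(), whitelists, tables,
                        sample = "S1") {
  stopifnot(inherits(layout, "scilite_layout"))
  if (inherits(tables, "scilite_allele_table")) tables <- list(tables)
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  reason <- rep(NA_character_, n)

  # fixed prefix segments
  pos <- 1L
  seg_vals <- list()
  for (s in layout$fixed_segments) {
    seg_vals[[s$name]] <- substr(seqs, pos, pos + s$length - 1L)
    pos <- pos + as.integer(s$length)
  }
  too_short <- nchar(seqs) < layout$prefix_length + min(layout$spacer_lengths) + 1L
  reason[too_short] <- "no-anchor"

  # barcode correction
  bc_names <- vapply(Filter(function(s) s$kind == "barcode", layout$fixed_segments),
                     `[[`, character(1), "name")
  for (b in bc_names) {
    wl <- whitelists[[b]]
    if (is.null(wl)) stop("no whitelist supplied for barcode segment '", b, "'")
    obs <- seg_vals[[b]]
    res <- rep(NA_character_, n)
    st <- rep("none", n)
    okw <- !too_short & nchar(obs) == wl$width
    if (any(okw)) {
      cr <- correct_sequence(obs[okw], wl, detail = TRUE)
      res[okw] <- cr$corrected
      st[okw] <- cr$status
    }
    newly <- is.na(reason) & is.na(res)
    reason[newly] <- ifelse(st[newly] == "ambiguous", "ambiguous-correction",
                            "bad-barcode")
    seg_vals[[b]] <- res
  }

  # spacer + amplicon resolution: best (fewest anchor mismatches, then
  # shortest spacer, then table order) among anchors matching with <= 1 mm
  amp_start <- rep(NA_integer_, n)
  amp_table <- rep(NA_integer_, n)
  best_mm <- rep(2L, n)
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    for (sp in layout$spacer_lengths) {
      p0 <- layout$prefix_length + sp + 1L
      mm <- .mismatch_at(seqs, p0, tab$anchor)
      better <- mm < best_mm
      amp_start[better] <- p0
      amp_table[better] <- ti
      best_mm[better] <- mm[better]
    }
  }
  no_anchor <- is.na(reason) & best_mm > 1L
  reason[no_anchor] <- "no-anchor"

  amplicon <- rep(NA_character_, n)
  allele <- rep(NA_character_, n)
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    sel <- which(is.na(reason) & amp_table == ti)
    if (!length(sel)) next
    amplicon[sel] <- tab$amplicon
    if (tab$mode == "diagnostic") {
      # constant region must match with <= 1 mismatch outside the
      # diagnostic offsets; diagnostic bases must match an allele exactly
      region <- substr(seqs[sel], amp_start[sel], amp_start[sel] + tab$width - 1L)
      short <- nchar(region) < tab$width
      res <- rep(NA_character_, length(sel))
      why <- rep(NA_character_, length(sel))
      why[short] <- "no-anchor"
      if (any(!short)) {
        const_pos <- setdiff(seq_len(tab$width), tab$offsets)
        refv <- strsplit(tab$reference, "", fixed = TRUE)[[1]]
        rm_ <- .seq_char_matrix(region[!short])
        mism <- rowSums(rm_[, const_pos, drop = FALSE] !=
                          matrix(refv[const_pos], nrow = sum(!short),
                                 ncol = length(const_pos), byrow = TRUE))
        diag_bases <- apply(rm_[, tab$offsets, drop = FALSE], 1L,
                            paste0, collapse = "")
        al <- names(tab$alleles)[match(diag_bases, tab$alleles)]
        al[mism > 1L] <- NA_character_
        res[!short] <- al
        why[!short] <- ifelse(mism > 1L, "no-anchor",
                              ifelse(is.na(al), "bad-allele", NA_character_))
      }
      allele[sel] <- res
      reason[sel][!is.na(why)] <- why[!is.na(why)]
    } else {
      wl <- tab$barcode_whitelist
      bc <- substr(seqs[sel], amp_start[sel] + tab$barcode_start - 1L,
                   amp_start[sel] + tab$barcode_start + wl$width - 2L)
      full <- nchar(bc) == wl$width
      res <- rep(NA_character_, length(sel))
      st <- rep("none", length(sel))
      if (any(full)) {
        cr <- correct_sequence(bc[full], wl, detail = TRUE)
        res[full] <- cr$corrected
        st[full] <- cr$status
      }
      allele[sel] <- res
      miss <- is.na(res)
      reason[sel][miss] <- ifelse(st[miss] == "ambiguous",
                                  "ambiguous-correction", "bad-allele")
    }
  }

  out <- data.table::data.table(sample = rep(sample, n))
  for (b in bc_names) data.table::set(out, j = b, value = seg_vals[[b]])
  umi_name <- vapply(Filter(function(s) s$kind == "umi", layout$fixed_segments),
                     `[[`, character(1), "name")
  data.table::set(out, j = "umi", value = seg_vals[[umi_name]])
  data.table::set(out, j = "amplicon", value = amplicon)
  data.table::set(out, j = "allele", value = allele)
  data.table::set(out, j = "reason", value = reason)
  out[!is.na(reason), c("amplicon", "allele") := list(NA_character_, NA_character_)]
  out[]
}

#' Build the UMI table from parsed reads
#'
#' Aggregates accepted reads into the central intermediate of the pipeline:
#' per cell, per amplicon and per UMI, the number of reads supporting each
#' allele.  The cell id joins the sample index and the barcode segments in
#' layout order with a fixed separator, so it is bit-identical across runs.
#'
#' @param parsed a `data.table` from [parse_reads()] (rejected rows are
#'   dropped here).
#' @param sep separator used in the cell id.
#' @return A `data.table` with columns `cell_id`, `amplicon`, `umi`,
#'   `allele`, `reads`.
#' @export
build_umi_table <- function(parsed, sep = ":") {
  keep <- parsed[is.na(reason)]
  if (nrow(keep) == 0)
    return(data.table::data.table(cell_id = character(0), amplicon = character(0),
                                  umi = character(0), allele = character(0),
                                  reads = integer(0)))
  bc_cols <- setdiff(names(keep), c("umi", "amplicon", "allele", "reason"))
  keep[, cell_id := do.call(paste, c(.SD, sep = sep)), .SDcols = bc_cols]
  out <- keep[, .(reads = .N), by = .(cell_id, amplicon, umi, allele)]
  data.table::setkey(out, cell_id, amplicon, umi)
  out[]
}

#' Count alleles in bulk amplicon reads
#'
#' Iterates over bulk amplicon reads, testing for the expected alleles at
#' the expected diagnostic positions.  Reads whose diagnostic bases match no
#' configured allele are discarded.  Heteroplasmy fractions follow the edit
#' semantics: the missense fraction counts every missense-containing allele
#' (including the double-edit allele), the silent fraction counts reads with
#' only the silent edit; both are divided by all non-discarded reads.
#'
#' @param seqs character vector of read sequences (or a FASTQ path).
#' @param table an [allele_table()].
#' @param spacer_lengths allowed spacer lengths ahead of the amplicon
#'   (default: no spacer).
#' @return list with `counts` (named integer, plus `discarded`),
#'   `missense_het` and `silent_het` (`NA` when no read survives).
#' @examples
#' at <- allele_table("amp", "ACGTACGTACGT", offsets = c(5, 9),
#'                    alleles = c(wt = "AA", mis = "TA", sil = "AG", both = "TG"),
#'                    tags = c(wt = "wild-type", mis = "missense",
#'                             sil = "silent", both = "both"))
#' @export
count_bulk_alleles <- function(seqs, table, spacer_lengths = 0L) {
  stopifnot(inherits(table, "scilite_allele_table"), table$mode == "diagnostic")
  if (length(seqs) == 1 && file.exists(seqs)) seqs <- read_fastq(seqs)
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  counts <- stats::setNames(integer(length(table$alleles)), names(table$alleles))
  discarded <- 0L
  if (n > 0) {
    start <- rep(NA_integer_, n)
    best <- rep(2L, n)
    for (sp in sort(spacer_lengths)) {
      mm <- .mismatch_at(seqs, sp + 1L, table$anchor)
      better <- mm < best
      start[better] <- sp + 1L
      best[better] <- mm[better]
    }
    ok <- best <= 1L & !is.na(start) &
      nchar(seqs) >= ifelse(is.na(start), Inf, start) + max(table$offsets) - 1L
    al <- rep(NA_character_, n)
    if (any(ok)) {
      bases <- vapply(table$offsets, function(o)
        substr(seqs[ok], start[ok] + o - 1L, start[ok] + o - 1L), character(sum(ok)))
      if (sum(ok) == 1L) bases <- matrix(bases, nrow = 1L)
      diag_bases <- apply(bases, 1L, paste0, collapse = "")
      al[ok] <- names(table$alleles)[match(diag_bases, table$alleles)]
    }
    tabulated <- table(factor(al, levels = names(table$alleles)))
    counts[] <- as.integer(tabulated)
    discarded <- n - sum(counts)
  }
  total <- sum(counts)
  tags <- table$tags
  mis <- sum(counts[tags %in% c("missense", "both")])
  sil <- sum(counts[tags == "silent"])
  list(counts = c(counts, discarded = discarded),
       missense_het = if (total > 0) mis / total else NA_real_,
       silent_het = if (total > 0) sil / total else NA_real_,
       total = total)
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ or gzipped FASTQ file.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write sequences to a FASTQ file
#'
#' Writes reads with constant placeholder base qualities (qualities are not
#' used anywhere in the pipeline).  A `.gz` suffix selects gzip compression.
#'
#' @param seqs character vector of read sequences.
#' @param path output path.
#' @param ids optional read names.
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::PhredQuality(vapply(nchar(seqs), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write / read a UMI table as TSV
#' @param x UMI table from [build_umi_table()].
#' @param path TSV path.
#' @export
write_umi_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_umi_table
#' @export
read_umi_table <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("cell_id", "amplicon",
                                                    "umi", "allele")))
}
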