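# Shared fixtures, all built in code.

# widely separated whitelists (pairwise Hamming >= 5) so that planting two
# substitutions can never be silently "corrected" to a different member
sep_rt_wl <- function() {
  whitelist(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT",
              "AACCGGTTAA", "CCGGTTAACC"), name = "rt")
}
sep_lig_wl <- function() {
  whitelist(c("ACACACACAC", "GTGTGTGTGT", "AAGGAAGGAA", "CCTTCCTTCC",
              "AGAGAGAGAG", "TCTCTCTCTC"), name = "ligation")
}

# four-allele edit amplicon reused across read-level tests
tiny_edit_table <- function() default_edit_table()

# assemble a read by the layout contract: ligation + umi + rt + spacer +
# amplicon-with-allele
build_read <- function(lig, umi, rt, spacer, table, allele) {
  seqs <- scilite:::.allele_sequences(table)
  paste0(lig, umi, rt, spacer, seqs[[allele]])
}

# mutate string s at positions pos to a different fixed base
mutate_at <- function(s, pos) {
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  }
  s
}

# brute-force nearest-neighbour oracle for whitelist correction: an exact
# match wins outright; otherwise a unique distance-1 member is accepted
oracle_correct <- function(observed, wl_seqs) {
  vapply(observed, function(o) {
    d <- scilite:::.hamming_to(wl_seqs, o)
    if (any(d == 0L)) return(wl_seqs[d == 0L])
    cand <- which(d == 1L)
    if (length(cand) == 1L) wl_seqs[cand] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# brute-force oracle for the UMI consensus rule
oracle_consensus <- function(counts) {
  total <- sum(counts)
  if (total < 3) return(NA_character_)
  winners <- names(counts)[3 * counts >= 2 * total & counts > 0]
  if (length(winners) == 1L) winners else NA_character_
}

# brute-force oracle for lineage assignment
oracle_lineage <- function(counts, min_umis = 10, ratio = 4) {
  counts <- counts[counts >= min_umis]
  if (length(counts) == 0) return(NA_character_)
  srt <- sort(counts, decreasing = TRUE)
  if (length(srt) == 1L || srt[1L] >= ratio * srt[2L]) {
    names(counts)[counts == srt[1L]][1L]
  } else NA_character_
}

# trapezoid integral
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
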