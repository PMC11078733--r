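#' @importFrom data.table := .N .I .SD data.table
NULL

.datatable.aware <- TRUE

# non-standard-evaluation column names used inside data.table expressions
utils::globalVariables(c(
  ".", "..allele_names", "allele", "amplicon", "cell_id", "class",
  "delta_missense", "delta_silent", "keep", "lineage", "mean_missense",
  "mean_missense_0", "mean_missense_1", "mean_silent", "mean_silent_0",
  "mean_silent_1", "missense_het", "pass", "path", "rank", "reads",
  "reason", "silent_het", "timepoint", "top", "top_allele", "total",
  "total_umis", "umi", "umis"))
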