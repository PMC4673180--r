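#' Bundled example miRNA count tables
#'
#' Two small tables of grouped miRNA read counts from a published
#' glioblastoma cohort: one healthy white-matter control column (HC) and
#' four group columns (LTC, LTP, STC, STP: long/short-term survivor tumor
#' centers and peritumor areas). The `"overexpressed"` table lists miRNAs
#' up in every group vs the control, the `"underexpressed"` table miRNAs
#' down in every group; they exercise [group_vs_control_fc()] and
#' [select_shared_modulated()] on real count magnitudes (including a zero
#' control cell that forces pseudocount handling).
#'
#' @param which `"overexpressed"` or `"underexpressed"`.
#' @return matrix of counts, miRNAs as rownames, columns HC/LTC/LTP/STC/STP.
#' @export
example_mirna_counts <- function(which = c("overexpressed", "underexpressed")) {
  which <- match.arg(which)
  path <- system.file("extdata", sprintf("mirna_counts_%s.tsv", which),
                      package = "gbmirnome", mustWork = TRUE)
  read_count_matrix(path)
}
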