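#' Breast cancer gene panel
#'
#' The 19-gene panel used for the panel-enrichment analysis: 18 genes
#' shared between a curated list of known cancer predisposition genes and
#' two commercial breast/gyn panels, plus BARD1 (frequently mutated in
#' triple-negative breast cancer). Only the symbols are packaged; the
#' mapping from symbols to genomic intervals is always supplied as a BED
#' (by the user or by [simulate_cohort()]), never hard-coded.
#'
#' @return Character vector of 19 gene symbols.
#' @export
breast_panel_genes <- function() {
  c("ATM", "BRCA1", "BRCA2", "BRIP1", "CDH1", "CHEK2", "MLH1", "MSH2",
    "MSH6", "NBN", "PALB2", "PMS2", "PTEN", "RAD51C", "RAD51D", "STK11",
    "TP53", "MUTYH", "BARD1")
}
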