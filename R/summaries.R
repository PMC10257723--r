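#' Published cohort summary counts bundled with the package
#'
#' Two small plain-text tables summarising a 1.52-million-individual
#' North-Western European meta-analysis of homozygosity deficits, usable as
#' worked-example inputs:
#'
#' * `genes` — the 25 genes whose protein-altering variants showed a strong
#'   deficit of homozygosity, with combined observed and expected homozygote
#'   counts (`variant_class` is `"plof"` or `"moderate"`).
#' * `gene_sets` — 2x2 counts of (strong deficit vs not) x (in set vs not)
#'   for gene-level pLOF units in two expected-count strata, for three gene
#'   sets: autosomal-recessive disease genes (`ar_omim`), genes essential
#'   for human cell-line growth (`cellline_essential`) and genes lethal or
#'   subviable when knocked out in mice (`mouse_lethal`).
#'
#' @return A list with tibbles `genes` and `gene_sets`.
#' @examples
#' tabs <- cohort_summary_tables()
#' sum(tabs$genes$expected) - sum(tabs$genes$observed)  # population burden
#' @export
cohort_summary_tables <- function() {
  genes <- read_annotation_free(
    system.file("extdata", "deficit_gene_counts.tsv", package = "lethalscan"))
  sets <- read_annotation_free(
    system.file("extdata", "geneset_enrichment_counts.tsv",
                package = "lethalscan"))
  list(genes = genes, gene_sets = sets)
}

read_annotation_free <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
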