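## Bundled reference summaries of the pan-cancer TCGA Agilent 244K cohort
## and the five-database pathway collection this methodology was developed
## on. Shipped as plain TSV under inst/extdata; used for bookkeeping
## consistency checks (per-cancer counts vs. stated totals).

read_reference_pair <- function(stem) {
  per <- utils::read.delim(
    system.file("extdata", paste0(stem, ".tsv"), package = "pathscape"),
    stringsAsFactors = FALSE)
  totals_df <- utils::read.delim(
    system.file("extdata", paste0(stem, "_totals.tsv"), package = "pathscape"),
    stringsAsFactors = FALSE)
  list(table = per, totals = setNames(totals_df$value, totals_df$quantity))
}

#' Reference cohort summary: per-cancer sample counts and stated totals
#'
#' @return list with `table` (cancer_label, cancer_type, n_samples) and
#'   `totals` (named vector: downloaded_samples, unique_samples,
#'   removed_samples).
#' @export
reference_cohort_summary <- function() read_reference_pair("tcga_agilent_cohort")

#' Reference pathway-collection summary: per-database counts and total
#'
#' @return list with `table` (source, database, n_pathways) and `totals`
#'   (named vector: filtered_pathways).
#' @export
reference_pathway_summary <- function() read_reference_pair("pathway_collection")
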