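# Readers/writers for the plain-text dialects the pipeline exchanges.

#' Read long-format plate readings
#'
#' Expects columns `sample_id, analyte, replicate, concentration_pg_ml,
#' bead_count`.
#'
#' @param path CSV file path.
#' @return Tibble of plate readings.
#' @export
read_plate_readings <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  assert_cols(out, c("sample_id", "analyte", "replicate",
                     "concentration_pg_ml", "bead_count"), path)
  out
}

#' Read sample metadata
#'
#' Expects at least `sample_id`; typically also `genotype, age_days, sex`.
#'
#' @param path CSV file path.
#' @return Tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  assert_cols(out, "sample_id", path)
  out
}

#' Read a gene-class-annotated count table
#'
#' Expects `gene, class` followed by one column per sample.
#'
#' @param path CSV file path.
#' @return Tibble of counts.
#' @export
read_count_table <- function(path) {
  out <- as_tibble(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE))
  assert_cols(out, c("gene", "class"), path)
  out
}

#' Read a gene-pair interaction edge table
#'
#' Expects tab- or comma-separated columns `gene_a, gene_b, score`.
#'
#' @param path TSV/CSV file path.
#' @return Tibble of edges.
#' @export
read_edge_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  out <- as_tibble(utils::read.delim(path, sep = sep,
                                     stringsAsFactors = FALSE))
  assert_cols(out, c("gene_a", "gene_b", "score"), path)
  out
}

#' Write a cleaned cytokine matrix (wide CSV)
#'
#' @param data Wide tibble from [clean_cytokines()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cytokine_matrix <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
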