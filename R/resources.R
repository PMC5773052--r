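#' Built-in fixture dictionaries and lexicons
#'
#' Loads the small name dictionaries shipped with the package: protein
#' names with UniProtKB accessions and source taxid, subcellular-location
#' names with GO Cellular Component ids, organism names with NCBI taxids,
#' the default tagger stopword list, the protein-marker lexicon (GFP/RFP
#' and friends), a Swiss-Prot style protein-to-GO annotation table, and a
#' STRING-to-UniProtKB id mapping table. These are deliberately tiny,
#' curated fixtures — enough to exercise every pipeline stage without
#' external downloads, not a production dictionary.
#'
#' @return A named list of tibbles/vectors: `proteins` (`name`, `norm_id`,
#'   `taxid`), `locations` (`name`, `norm_id`), `organisms` (`name`,
#'   `norm_id`), `stopwords` (character), `markers` (character),
#'   `swissprot` (`uniprot_ac`, `go_id`), `string_map` (`string_id`,
#'   `uniprot_ac`).
#' @export
lx_default_dictionaries <- function() {
  list(
    proteins = read_tsv_table(extdata_path("proteins.tsv"),
                              c("name", "norm_id", "taxid")),
    locations = read_tsv_table(extdata_path("locations.tsv"),
                               c("name", "norm_id")),
    organisms = read_tsv_table(extdata_path("organisms.tsv"),
                               c("name", "norm_id")),
    stopwords = readLines(extdata_path("stopwords.txt"), warn = FALSE),
    markers = read_tsv_table(extdata_path("markers.tsv"), "name")$name,
    swissprot = read_tsv_table(extdata_path("swissprot_go.tsv"),
                               c("uniprot_ac", "go_id")),
    string_map = read_tsv_table(extdata_path("string_to_uniprot.tsv"),
                                c("string_id", "uniprot_ac"))
  )
}

#' Read a marker lexicon from TSV
#'
#' @param path TSV file with a `name` column.
#' @return Character vector of marker names.
#' @export
read_marker_lexicon <- function(path) {
  read_tsv_table(path, "name")$name
}

#' Read a protein-to-GO annotation table from TSV
#'
#' @param path TSV file with columns `uniprot_ac`, `go_id`.
#' @return Tibble with those columns.
#' @export
read_annotation_table <- function(path) {
  read_tsv_table(path, c("uniprot_ac", "go_id"))
}
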