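#' Packaged karyopherin catalog
#'
#' Loads the catalog of karyopherins (importins and exportins) used to
#' classify nuclear-interactome gene lists. The packaged default lists the
#' karyopherin hits of a SANS nuclear interactome screen: eight protein
#' importers, the protein exporter XPO1 (CRM1/exportin-1) and two RNA-cargo
#' exporters.
#'
#' @param path optional path to a CSV with columns `gene`, `protein`, `role`
#'   (`protein_importer`, `protein_exporter`, `rna_exporter`) and
#'   `recognition`; defaults to the packaged catalog.
#' @return A data frame of class `karyopherin_catalog`.
#' @export
karyopherin_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "karyopherin_catalog.csv",
                                package = "nucshuttle", mustWork = TRUE)
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "protein", "role", "recognition")
  miss <- setdiff(need, names(cat))
  if (length(miss)) stopf("catalog missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(toupper(cat$gene)))
    stopf("catalog gene symbols must be unique")
  ok_roles <- c("protein_importer", "protein_exporter", "rna_exporter")
  if (!all(cat$role %in% ok_roles))
    stopf("catalog roles must be one of: %s", paste(ok_roles, collapse = ", "))
  class(cat) <- c("karyopherin_catalog", "data.frame")
  cat
}

#' Screen a gene list against the karyopherin catalog
#'
#' Case-insensitive symbol matching; duplicated input symbols are deduplicated
#' with a warning.
#'
#' @param genes character vector of gene symbols (e.g. an interactome list).
#' @param catalog a [karyopherin_catalog()]; defaults to the packaged one.
#' @return A list of class `karyopherin_screen` with `matched` (catalog rows
#'   hit by the input, with the matching input symbol), `unmatched` (input
#'   symbols not in the catalog) and `counts` (named role counts, including
#'   zeros).
#' @export
screen_karyopherins <- function(genes, catalog = karyopherin_catalog()) {
  if (length(genes) == 0L) stopf("empty gene list")
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  up <- toupper(genes)
  if (anyDuplicated(up)) {
    warnf("duplicate gene symbols deduplicated: %s",
          paste(unique(genes[duplicated(up)]), collapse = ", "))
    genes <- genes[!duplicated(up)]
    up <- unique(up)
  }
  hit <- match(up, toupper(catalog$gene))
  matched <- catalog[hit[!is.na(hit)], , drop = FALSE]
  matched$input_symbol <- genes[!is.na(hit)]
  counts <- vapply(c("protein_importer", "protein_exporter", "rna_exporter"),
                   function(r) sum(matched$role == r), integer(1))
  structure(list(matched = matched, unmatched = genes[is.na(hit)],
                 counts = counts),
            class = "karyopherin_screen")
}

#' Quantify the nuclear percentage from a pair of fractionation blot lanes
#'
#' Band intensities are normalized to the total protein loaded per lane
#' (`N_i = band / total_protein`); the nuclear percentage is
#' `100 * N_nuclear / (N_nuclear + N_cytoplasmic)`. Histone H3 serves as a
#' binary purity check: if the cytoplasmic lane carries more than
#' `purity_tolerance` of the nuclear lane's histone H3 signal, the result is
#' flagged for nuclear cross-contamination (and symmetrically for tubulin).
#'
#' @param lanes a `blot_lanes` data frame with exactly one `nuclear` and one
#'   `cytoplasmic` row (columns `fraction`, `band_intensity`, `total_protein`,
#'   optionally `histone_h3` and `tubulin`).
#' @param purity_tolerance marker leak fraction above which a purity flag is
#'   raised.
#' @return A list of class `fractionation_result` with `nuclear_percent`,
#'   `cytoplasmic_percent` and `purity_flags`.
#' @export
quantify_fractionation <- function(lanes, purity_tolerance = 0.10) {
  stopifnot(is.data.frame(lanes))
  nuc <- lanes[lanes$fraction == "nuclear", , drop = FALSE]
  cyt <- lanes[lanes$fraction == "cytoplasmic", , drop = FALSE]
  if (nrow(nuc) != 1L || nrow(cyt) != 1L)
    stopf("expected exactly one nuclear and one cytoplasmic lane")
  if (any(lanes$band_intensity < 0)) stopf("band intensities must be >= 0")
  if (any(lanes$total_protein <= 0)) stopf("total protein must be positive")
  n_n <- nuc$band_intensity / nuc$total_protein
  n_c <- cyt$band_intensity / cyt$total_protein
  if (n_n + n_c <= 0) stopf("both normalized band intensities are zero")
  flags <- character(0)
  if (!is.null(lanes$histone_h3) && nuc$histone_h3 > 0 &&
      cyt$histone_h3 > purity_tolerance * nuc$histone_h3)
    flags <- c(flags, "histone_h3_in_cytoplasmic_lane")
  if (!is.null(lanes$tubulin) && !any(is.na(lanes$tubulin)) &&
      cyt$tubulin > 0 && nuc$tubulin > purity_tolerance * cyt$tubulin)
    flags <- c(flags, "tubulin_in_nuclear_lane")
  structure(list(nuclear_percent = 100 * n_n / (n_n + n_c),
                 cytoplasmic_percent = 100 * n_c / (n_n + n_c),
                 purity_flags = flags),
            class = "fractionation_result")
}

#' Read a newline-delimited gene list
#'
#' @param path text file with one gene symbol per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return A character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
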