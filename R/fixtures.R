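#' Load a packaged annotated gene table
#'
#' Two curated tables of polysome-associated transcripts ship with the
#' package as plain TSV: `"table1_oxphos"` (50 transcripts encoding
#' mitochondrial OXPHOS proteins, complexes I-V, enriched on mutant
#' polysomes) and `"table2_translation"` (109 transcripts of the
#' translation machinery, sections Translation / Ribosome / mRNA
#' processing, depleted from mutant polysomes). Unicode minus signs were
#' normalized to ASCII at fixture build time; gene identifiers are
#' opaque strings.
#'
#' @param name fixture name, `"table1_oxphos"` or `"table2_translation"`.
#' @param section optional section label to filter on (e.g. `"Complex V"`,
#'   `"Ribosome"`).
#' @return data frame with columns `accession`, `gene_name`,
#'   `description`, `section`, `log2fc`.
#' @examples
#' nrow(load_table_fixture("table1_oxphos"))                      # 50
#' nrow(load_table_fixture("table2_translation", "Ribosome"))     # 62
#' @export
load_table_fixture <- function(name, section = NULL) {
  files <- c(table1_oxphos = "table1_oxphos.tsv",
             table2_translation = "table2_translation.tsv")
  if (!name %in% names(files))
    stop_fmt("unknown fixture '%s' (available: %s)", name,
             paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "teprof",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$log2fc <- as.numeric(tab$log2fc)
  stopifnot(all(is.finite(tab$log2fc)), all(nzchar(tab$section)))
  if (!is.null(section)) {
    if (!section %in% tab$section)
      stop_fmt("section '%s' not present in %s", section, name)
    tab <- tab[tab$section == section, , drop = FALSE]
  }
  tab
}
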