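# Packaged reference tables for the Hub1/Snu66 system: the truncation
# peptide library, per-group interface RMSD summaries of docked models, and
# per-residue interaction counts with cooperativity scores. Values are
# packaged verbatim as published reference data; the interaction counts and
# scores come from a third-party scoring engine and are inputs to the
# aggregation operations here, never recomputed.

#' Load a packaged reference table
#'
#' @param name One of:
#'   * `"table2"` -- truncation peptide library (ID, Sequence, Length).
#'   * `"table4"` -- interface RMSD of docked models, by representation
#'     (CA / all-atom) and selection group (medoid / filtered / lowest).
#'   * `"table5"` -- per-receptor-residue interaction counts for each
#'     peptide plus a per-peptide cooperativity score; returned as an
#'     [interaction_table()].
#' @return A data.frame (`table2`, `table4`) or an `interaction_table`
#'   (`table5`).
#' @export
#' @examples
#' tab5 <- load_fixture("table5")
#' colSums(tab5$counts)
load_fixture <- function(name) {
  files <- c(table2 = "table2_peptide_library.tsv",
             table4 = "table4_irms.tsv",
             table5 = "table5_interaction_counts.tsv")
  if (!name %in% names(files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(files), collapse = ", "))
  }
  path <- system.file("extdata", files[[name]], package = "pepint",
                      mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (name == "table5") {
    counts <- as.matrix(df[, setdiff(names(df), c("ID", "CooperativityScore"))])
    rownames(counts) <- df$ID
    return(interaction_table(counts, coop_scores = df$CooperativityScore))
  }
  df
}
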