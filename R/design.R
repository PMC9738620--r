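# Truncation-scan peptide library design: stepwise single-residue deletions
# from a parent sequence, in three phases (N-terminal scan, C-terminal scan
# from the shortest N-scan product, one double-end truncation).

#' Generate a truncation peptide library
#'
#' Phase 1 removes one residue at a time from the N-terminus, from
#' `length(parent) - 1` down to `n_del_to_length`. Phase 2 continues from
#' the final phase-1 peptide, removing one residue at a time from the
#' C-terminus down to `c_del_to_length`. Phase 3 (optional) adds a single
#' peptide with `double_spec[1]` N-terminal and `double_spec[2]` C-terminal
#' residues removed from the parent. Entries are labelled
#' `"Peptide-1" ... "Peptide-N"` in that order, with the parent included
#' first under `parent_id`.
#'
#' @param parent One-letter parent sequence (standard residues only).
#' @param n_del_to_length Phase-1 stopping length (default 10).
#' @param c_del_to_length Phase-2 stopping length (default 5).
#' @param double_spec Integer pair `c(n_cut, c_cut)` for the double
#'   truncation, or `NULL` to skip it (default `c(5, 3)`).
#' @param parent_id Label for the parent row (default "Snu66 peptide",
#'   after the system the scheme was designed around).
#' @return Object of class `peptide_library`: data.frame `entries` with
#'   `id`, `sequence`, `length`, `scheme`.
#' @export
#' @examples
#' lib <- truncation_library("LSIEETNEIREKLGMKPI")
#' lib$entries[lib$entries$id == "Peptide-11", ]
truncation_library <- function(parent, n_del_to_length = 10,
                               c_del_to_length = 5, double_spec = c(5, 3),
                               parent_id = "Snu66 peptide") {
  parent <- toupper(parent)
  letters1 <- strsplit(parent, "")[[1]]
  bad <- setdiff(letters1, names(aa1_to_aa3))
  if (length(bad) > 0) {
    stop("non-standard residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  len <- nchar(parent)
  if (!(len > n_del_to_length && n_del_to_length >= c_del_to_length &&
        c_del_to_length >= 1)) {
    stop("need length(parent) > n_del_to_length >= c_del_to_length >= 1")
  }
  entries <- data.frame(id = parent_id, sequence = parent, length = len,
                        scheme = "parent", stringsAsFactors = FALSE)
  n_pep <- 0L
  add <- function(seq, scheme) {
    n_pep <<- n_pep + 1L
    entries <<- rbind(entries, data.frame(
      id = paste0("Peptide-", n_pep), sequence = seq, length = nchar(seq),
      scheme = scheme, stringsAsFactors = FALSE))
  }
  if (len - 1 >= n_del_to_length) {
    for (l in seq(len - 1, n_del_to_length)) {
      add(substr(parent, len - l + 1, len), "N-del")
    }
  }
  base <- substr(parent, len - n_del_to_length + 1, len)
  if (n_del_to_length - 1 >= c_del_to_length) {
    for (l in seq(n_del_to_length - 1, c_del_to_length)) {
      add(substr(base, 1, l), "C-del")
    }
  }
  if (!is.null(double_spec)) {
    n_cut <- as.integer(double_spec[1]); c_cut <- as.integer(double_spec[2])
    if (n_cut < 0 || c_cut < 0 || n_cut + c_cut >= len) {
      stop("infeasible double truncation: ", n_cut, ",", c_cut,
           " on length ", len)
    }
    add(substr(parent, n_cut + 1, len - c_cut), "double")
  }
  structure(list(entries = entries, parent = parent), class = "peptide_library")
}

#' @export
print.peptide_library <- function(x, ...) {
  cat("peptide_library:", nrow(x$entries) - 1, "peptides from parent",
      x$parent, "\n")
  invisible(x)
}

#' Tabulate or export a peptide library
#'
#' @param lib A [truncation_library()] result.
#' @param path Optional output file; when given, a TSV with columns
#'   ID/Sequence/Length is written.
#' @param fasta Optional FASTA output path.
#' @return The report data.frame (invisibly when written to file).
#' @export
library_report <- function(lib, path = NULL, fasta = NULL) {
  stopifnot(inherits(lib, "peptide_library"))
  out <- data.frame(ID = lib$entries$id, Sequence = lib$entries$sequence,
                    Length = lib$entries$length, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    writeLines(as.vector(rbind(paste0(">", gsub(" ", "_", out$ID)),
                               out$Sequence)), fasta)
  }
  if (is.null(path) && is.null(fasta)) out else invisible(out)
}
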