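# Packaged curated data.

#' Curated H-2Db ligand table
#'
#' The packaged machine-readable survey of H-2Db-restricted peptide ligands
#' with crystal structures: PDB code(s), epitope description, one-letter
#' sequence, length, and a distinct-epitope flag (FALSE for entries that
#' duplicate another epitope or were excluded from the structural
#' analyses). Entries resolving the same epitope in several PDB files share
#' one row with slash-separated codes. The 2VE6 entry is an altered
#' (photocleavable) peptide whose deposited coordinates carry a
#' non-canonical unit at p7; its parent sequence is tabulated.
#'
#' @param distinct_only logical; keep only distinct-epitope entries
#' @return data.frame with columns pdb_code, description, sequence,
#'   length, distinct_flag
#' @export
h2db_ligands <- function(distinct_only = FALSE) {
  path <- system.file("extdata", "h2db_ligands.tsv", package = "pmhcbuild",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$distinct_flag <- as.logical(tab$distinct_flag)
  stopifnot(all(nchar(tab$sequence) == tab$length))
  if (distinct_only) tab <- tab[tab$distinct_flag, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Named sequence vector of the distinct H-2Db ligands
#' @return character vector of peptide sequences named by PDB code(s)
#' @export
h2db_sequences <- function() {
  tab <- h2db_ligands(distinct_only = TRUE)
  stats::setNames(tab$sequence, tab$pdb_code)
}
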