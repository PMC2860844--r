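# Coordinate containers and PDB-format input/output.
#
# A `pmhc_structure` is a light wrapper around a flat atom table (one row
# per heavy atom, file order preserved):
#   record elety element resid chain resno icode x y z occ
# A `pmhc_complex` pairs an MHC receptor structure with a single bound
# peptide chain (positions p1..pn from the N terminus).

new_structure <- function(id, atoms, metadata = list()) {
  required <- c("record", "elety", "element", "resid", "chain", "resno",
                "icode", "x", "y", "z", "occ")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) stop("atom table lacks columns: ",
                            paste(missing, collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, metadata = metadata),
            class = "pmhc_structure")
}

#' @export
print.pmhc_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<pmhc_structure> %s: %d atoms, %d residues, chains: %s\n",
              x$id, nrow(x$atoms), nrow(res),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Per-atom residue grouping index (file order)
#' @noRd
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, atoms$resid, sep = "|")
}

#' Residue-level summary of a structure
#'
#' @param structure a `pmhc_structure`
#' @return data.frame with one row per residue in file order: chain, resno,
#'   icode, resid, code1, n_atoms, backbone (TRUE iff N, CA, C, O all
#'   present), canonical
#' @export
residue_table <- function(structure) {
  atoms <- structure$atoms
  key <- residue_key(atoms)
  idx <- which(!duplicated(key))
  ord <- split(seq_len(nrow(atoms)), factor(key, levels = key[idx]))
  res <- data.frame(
    chain = atoms$chain[idx], resno = atoms$resno[idx],
    icode = atoms$icode[idx], resid = atoms$resid[idx],
    stringsAsFactors = FALSE
  )
  res$code1 <- aa_three2one(res$resid)
  res$n_atoms <- lengths(ord)
  res$backbone <- vapply(ord, function(i)
    all(c("N", "CA", "C", "O") %in% atoms$elety[i]), logical(1))
  res$canonical <- is_canonical_aa(res$resid)
  rownames(res) <- NULL
  res
}

#' Extract the coordinate matrix of a structure
#' @param structure a `pmhc_structure`
#' @param sel optional logical/integer atom selection
#' @return n x 3 numeric matrix (Angstrom)
#' @export
get_coords <- function(structure, sel = NULL) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#' @param structure a `pmhc_structure`
#' @param coords n x 3 matrix matching the atom count (or selection)
#' @param sel optional atom selection the rows of `coords` refer to
#' @return the modified structure
#' @export
set_coords <- function(structure, coords, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(structure$atoms))
  structure$atoms[sel, c("x", "y", "z")] <- coords
  structure
}

#' One-letter sequence of a (single-chain) structure
#' @param structure a `pmhc_structure`
#' @return character scalar
#' @export
structure_sequence <- function(structure) {
  paste(residue_table(structure)$code1, collapse = "")
}

is_water <- function(resid) toupper(resid) %in% c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB-format coordinate file
#'
#' Parses fixed-column ATOM/HETATM records (delegating to
#' \code{bio3d::read.pdb}), drops hydrogens and deuteriums, resolves
#' alternate locations by keeping blank or 'A', and preserves file order.
#'
#' @param source path to a PDB file, or a character scalar containing
#'   PDB-format text (detected by embedded newlines)
#' @param id structure label; defaults to the file base name
#' @return a `pmhc_structure`
#' @export
read_pdb <- function(source, id = NULL) {
  if (length(source) == 1 && grepl("\n", source)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(source, "\n")[[1]], path)
    on.exit(unlink(path))
    if (is.null(id)) id <- "text"
  } else {
    path <- source
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(coord)) stop("empty or record-free PDB input: no ATOM/HETATM lines")
  for (i in which(coord)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed coordinate record at line ", i,
                             ": too short")
    for (f in c(31, 39, 47)) {
      val <- suppressWarnings(as.numeric(substr(ln, f, f + 7)))
      if (is.na(val)) stop("malformed coordinate field at line ", i,
                           ": '", substr(ln, f, f + 7), "'")
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  noelem <- is.na(elem) | elem == ""
  elem[noelem] <- element_from_name(trimws(at$elety[noelem]))
  keep <- !(toupper(elem) %in% c("H", "D"))
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (!nrow(at)) stop("no heavy atoms in PDB input")
  atoms <- data.frame(
    record = at$type,
    elety = trimws(at$elety),
    element = toupper(trimws(elem)),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  new_structure(id, atoms)
}

#' Write a structure as fixed-column PDB ATOM/HETATM records
#'
#' Coordinates are written at 3 decimals; a TER record closes every chain
#' and the file ends with END.
#'
#' @param structure a `pmhc_structure`
#' @param dest output file path
#' @return `dest`, invisibly
#' @export
write_pdb <- function(structure, dest) {
  atoms <- structure$atoms
  lines <- character(0)
  serial <- 0L
  if (nrow(atoms)) {
    bad <- nchar(atoms$elety) > 4
    if (any(bad)) stop("atom name too long for PDB format: ",
                       paste(unique(atoms$elety[bad]), collapse = ", "))
    chains <- unique(atoms$chain)
    for (ch in chains) {
      rows <- which(atoms$chain == ch)
      for (i in rows) {
        serial <- serial + 1L
        a <- atoms[i, ]
        name <- if (nchar(a$elety) < 4 && nchar(a$element) == 1)
          sprintf(" %-3s", a$elety) else sprintf("%-4s", a$elety)
        lines[length(lines) + 1L] <- sprintf(
          "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, serial %% 100000L, name, "", a$resid, a$chain,
          a$resno %% 10000L, a$icode, a$x, a$y, a$z, a$occ, 0,
          a$element)
      }
      serial <- serial + 1L
      last <- atoms[rows[length(rows)], ]
      lines[length(lines) + 1L] <- sprintf(
        "TER   %5d      %3s %1s%4d%1s",
        serial %% 100000L, last$resid, last$chain, last$resno %% 10000L,
        last$icode)
    }
  }
  lines[length(lines) + 1L] <- "END"
  writeLines(lines, dest)
  invisible(dest)
}

#' Serialize a structure to PDB-format text
#' @param structure a `pmhc_structure`
#' @return character scalar of PDB text
#' @export
pdb_text <- function(structure) {
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  write_pdb(structure, path)
  paste(readLines(path), collapse = "\n")
}

subset_structure <- function(structure, sel, id = structure$id) {
  new_structure(id, structure$atoms[sel, , drop = FALSE], structure$metadata)
}

#' Construct a pMHC complex object
#'
#' @param mhc `pmhc_structure` holding the receptor chains (alpha chain and
#'   optionally beta-2 microglobulin)
#' @param peptide `pmhc_structure` holding a single peptide chain of 8-12
#'   residues with complete backbones
#' @param provenance named list (template id, donor id, seed, stage, ...)
#' @param energy optional energy breakdown
#' @return a `pmhc_complex`
#' @export
new_pmhc <- function(mhc, peptide, provenance = list(), energy = NULL) {
  res <- residue_table(peptide)
  n <- nrow(res)
  if (length(unique(res$chain)) != 1)
    stop("peptide must be a single chain")
  if (n < 8 || n > 12)
    stop("peptide length ", n, " outside the presented-epitope range 8-12")
  if (!all(res$backbone))
    stop("peptide residue(s) with incomplete backbone at position(s): ",
         paste(which(!res$backbone), collapse = ", "))
  if (any(peptide$atoms$chain %in% mhc$atoms$chain))
    stop("peptide chain id collides with an MHC chain id")
  structure(list(mhc = mhc, peptide = peptide, provenance = provenance,
                 energy = energy),
            class = "pmhc_complex")
}

#' @export
print.pmhc_complex <- function(x, ...) {
  cat(sprintf("<pmhc_complex> peptide %s (%d-mer) on MHC %s (%d atoms)\n",
              peptide_sequence(x), peptide_length(x), x$mhc$id,
              nrow(x$mhc$atoms)))
  if (!is.null(x$energy))
    cat(sprintf("  score: total %.3f\n", x$energy$total))
  invisible(x)
}

#' Peptide length of a complex
#' @param cpx a `pmhc_complex`
#' @return integer
#' @export
peptide_length <- function(cpx) nrow(residue_table(cpx$peptide))

#' Peptide one-letter sequence of a complex
#' @param cpx a `pmhc_complex`
#' @return character scalar
#' @export
peptide_sequence <- function(cpx) structure_sequence(cpx$peptide)

#' Split a structure into MHC receptor and bound peptide
#'
#' The single protein chain of length 8-12 becomes the peptide (p1 at its N
#' terminus); all other protein chains become the receptor. Waters and
#' non-peptidic ligands are dropped. Residues lacking N/CA/C atoms are not
#' considered peptidic.
#'
#' @param structure a `pmhc_structure`
#' @param id complex label recorded in provenance
#' @return a `pmhc_complex`
#' @export
split_pmhc <- function(structure, id = structure$id) {
  atoms <- structure$atoms
  key <- residue_key(atoms)
  res <- residue_table(structure)
  res_key <- paste(res$chain, res$resno, res$icode, res$resid, sep = "|")
  # amino-acid-like residues: minimal backbone present, not water
  amino <- !is_water(res$resid) &
    vapply(seq_len(nrow(res)), function(i) {
      sel <- key == res_key[i]
      all(c("N", "CA", "C") %in% atoms$elety[sel])
    }, logical(1))
  keep_atoms <- key %in% res_key[amino]
  chains <- unique(res$chain[amino])
  nres <- vapply(chains, function(ch) sum(amino & res$chain == ch), integer(1))
  cand <- chains[nres >= 8 & nres <= 12]
  if (length(cand) == 0)
    stop("no candidate peptide chain (8-12 residues) found")
  if (length(cand) > 1)
    stop("ambiguous peptide assignment; candidate chains: ",
         paste(sprintf("%s(%d aa)", cand, nres[match(cand, chains)]),
               collapse = ", "))
  pep_sel <- keep_atoms & atoms$chain == cand
  mhc_sel <- keep_atoms & atoms$chain != cand
  peptide <- subset_structure(structure, pep_sel, id = paste0(id, "_pep"))
  pep_res <- residue_table(peptide)
  if (!all(pep_res$backbone))
    stop("peptide chain ", cand, " has incomplete backbone at position(s): ",
         paste(which(!pep_res$backbone), collapse = ", "),
         " (structures with incomplete epitopes are excluded)")
  if (!any(mhc_sel)) stop("no receptor chains remain after peptide selection")
  mhc <- subset_structure(structure, mhc_sel, id = paste0(id, "_mhc"))
  new_pmhc(mhc, peptide, provenance = list(source = id))
}

#' Merge MHC and peptide into one structure (e.g. for writing or scoring)
#' @param cpx a `pmhc_complex`
#' @param id label for the merged structure
#' @return a `pmhc_structure`
#' @export
merge_pmhc <- function(cpx, id = "complex") {
  new_structure(id, rbind(cpx$mhc$atoms, cpx$peptide$atoms))
}

#' Read peptide sequences from a FASTA file
#' @param path FASTA file with 8-12 residue protein sequences
#' @return named character vector of upper-case sequences
#' @export
read_peptide_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fas <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                            forceDNAtolower = FALSE)
  seqs <- toupper(vapply(fas, function(s) as.character(s)[1], character(1)))
  names(seqs) <- vapply(fas, function(s) attr(s, "name"), character(1))
  seqs
}
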