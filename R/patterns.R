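# Allele-specific backbone pattern extraction and downstream sequence /
# contact analytics: per-position mean backbone geometry with dispersion,
# deviation reports with exception flagging, anchor-position composition,
# side-chain burial classification, and conserved cleft-residue
# hydrogen-bond reporting.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# per-position backbone coordinate array (pos x atom x 3) of a peptide
backbone_array <- function(peptide) {
  res <- residue_table(peptide)
  atoms <- peptide$atoms
  key <- residue_key(atoms)
  ukey <- unique(key)
  arr <- array(NA_real_, dim = c(nrow(res), 4, 3),
               dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
  for (i in seq_len(nrow(res))) {
    sel <- which(key == ukey[i])
    idx <- match(BACKBONE_ATOMS, atoms$elety[sel])
    arr[i, , ] <- as.matrix(atoms[sel[idx], c("x", "y", "z")])
  }
  arr
}

#' Extract the shared backbone conformation of a set of complexes
#'
#' Fits every member onto the frame complex (by default the first member)
#' using MHC Calpha atoms, then computes per-position mean backbone (N, CA,
#' C, O) coordinates and the RMS dispersion of members about that mean.
#' All members must share one allele label; mixed peptide lengths are split
#' into one pattern per length class (with a warning).
#'
#' @param complexes list of `pmhc_complex` objects
#' @param allele allele label attached to the pattern (e.g. "H-2Db")
#' @param frame index of the member whose MHC defines the common frame
#' @return a `backbone_pattern`, or a list of them (one per length) when
#'   lengths are mixed
#' @export
extract_pattern <- function(complexes, allele = "unknown", frame = 1L) {
  stopifnot(length(complexes) >= 1)
  alleles <- unique(vapply(
    complexes, function(c) c$provenance$allele %||% allele, character(1)))
  if (length(alleles) > 1)
    stop("mixed alleles in pattern input: ", paste(alleles, collapse = ", "))
  lens <- vapply(complexes, peptide_length, integer(1))
  if (length(unique(lens)) > 1) {
    warning("mixed peptide lengths (", paste(unique(lens), collapse = ", "),
            "); returning one pattern per length class")
    return(lapply(sort(unique(lens)), function(L)
      extract_pattern(complexes[lens == L], allele = allele)))
  }
  ref <- complexes[[frame]]
  fitted <- lapply(seq_along(complexes), function(i) {
    if (i == frame) complexes[[i]] else
      fit_by_mhc_ca(complexes[[i]], ref)$model
  })
  arrs <- lapply(fitted, function(cpx) backbone_array(cpx$peptide))
  n_pos <- dim(arrs[[1]])[1]
  stack <- array(unlist(arrs), dim = c(n_pos, 4, 3, length(arrs)))
  mean_coords <- apply(stack, c(1, 2, 3), mean)
  dimnames(mean_coords) <- dimnames(arrs[[1]])
  # member deviation at each position: RMS over the 4 backbone atoms of the
  # distance to the mean coordinates
  member_dev <- vapply(seq_along(arrs), function(m) {
    d2 <- (stack[, , , m, drop = FALSE][, , , 1] - mean_coords)^2
    sqrt(rowMeans(apply(d2, c(1, 2), sum)))
  }, numeric(n_pos))
  member_dev <- matrix(member_dev, nrow = n_pos)
  dispersion <- sqrt(rowMeans(member_dev^2))
  out <- list(
    allele = allele, length = n_pos,
    frame = ref, mean_coords = mean_coords,
    dispersion = dispersion, member_dev = member_dev,
    members = vapply(complexes, function(c)
      c$provenance$source %||% c$mhc$id, character(1)))
  class(out) <- "backbone_pattern"
  out
}

#' @export
print.backbone_pattern <- function(x, ...) {
  cat(sprintf("<backbone_pattern> %s, %d-mers, %d member(s)\n",
              x$allele, x$length, length(x$members)))
  cat("  per-position dispersion (A):",
      paste(sprintf("%.2f", x$dispersion), collapse = " "), "\n")
  invisible(x)
}

#' Deviation of one complex from a backbone pattern
#'
#' Fits the complex into the pattern frame by MHC Calpha, then reports the
#' per-position backbone deviation from the pattern mean and an exception
#' flag. The exception rule: overall backbone RMSD above `rmsd_threshold`
#' (default 2.0 Angstrom, under the 2.2 Angstrom reproduction-validity
#' bound) or any per-position deviation above the member mean plus three
#' member dispersions at that position.
#'
#' @param pattern a `backbone_pattern`
#' @param cpx a `pmhc_complex` of the pattern's peptide length
#' @param rmsd_threshold overall backbone RMSD exception threshold (A)
#' @return a `pattern_deviation` list: `overall_backbone_rmsd`,
#'   `per_position`, `exception`, `worst_position`
#' @export
deviation_from_pattern <- function(pattern, cpx, rmsd_threshold = 2.0) {
  if (peptide_length(cpx) != pattern$length)
    stop("peptide length ", peptide_length(cpx),
         " does not match pattern length ", pattern$length)
  fitted <- fit_by_mhc_ca(cpx, pattern$frame)$model
  arr <- backbone_array(fitted$peptide)
  d2 <- (arr - pattern$mean_coords)^2
  per_atom <- apply(d2, c(1, 2), sum)          # squared distance per atom
  per_position <- sqrt(rowMeans(per_atom))
  overall <- sqrt(mean(per_atom))
  pos_mean <- rowMeans(pattern$member_dev)
  pos_thresh <- pos_mean + 3 * pattern$dispersion
  exception <- overall > rmsd_threshold | any(per_position > pos_thresh)
  out <- list(overall_backbone_rmsd = overall,
              per_position = per_position,
              exception = exception,
              worst_position = which.max(per_position))
  class(out) <- "pattern_deviation"
  out
}

#' @export
print.pattern_deviation <- function(x, ...) {
  cat(sprintf("<pattern_deviation> overall %.3f A, worst at p%d%s\n",
              x$overall_backbone_rmsd, x$worst_position,
              if (x$exception) " [EXCEPTION]" else ""))
  invisible(x)
}

# physicochemical classes used for anchor analysis
AA_CLASSES <- list(
  nonpolar = c("A", "V", "L", "I", "M", "F", "W", "P", "G"),
  polar = c("S", "T", "N", "Q", "Y", "C"),
  positive = c("K", "R", "H"),
  negative = c("D", "E")
)
AROMATIC <- c("F", "Y", "W")

#' Physicochemical class of one-letter residue codes
#' @param code1 character vector of one-letter codes
#' @return factor with levels nonpolar/polar/positive/negative
#' @export
aa_class <- function(code1) {
  code1 <- toupper(code1)
  cls <- rep(NA_character_, length(code1))
  for (nm in names(AA_CLASSES)) cls[code1 %in% AA_CLASSES[[nm]]] <- nm
  factor(cls, levels = names(AA_CLASSES))
}

#' Residue and class composition at one peptide position
#'
#' Counts residues and physicochemical classes at an absolute position
#' (from the N terminus) across a set of sequences; sequences shorter than
#' the position are skipped with a warning. The aromatic overlay (F/Y/W)
#' is reported separately from the four-way class partition.
#'
#' @param sequences named character vector (or list) of peptide sequences;
#'   names are the entry identifiers
#' @param position 1-based position from the N terminus
#' @return a `composition_table`: `position`, `counts` (named integer),
#'   `class_counts`, `aromatic_count`, `ids_by_residue`
#' @export
composition_at <- function(sequences, position) {
  sequences <- unlist(sequences)
  if (!length(sequences)) stop("no sequences supplied")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  sequences <- toupper(sequences)
  long_enough <- nchar(sequences) >= position
  if (!all(long_enough)) {
    warning(sum(!long_enough), " sequence(s) shorter than position ",
            position, " skipped")
    sequences <- sequences[long_enough]
    if (!length(sequences)) stop("no sequence reaches position ", position)
  }
  res <- substr(sequences, position, position)
  counts <- table(res)
  cls <- table(aa_class(res))
  out <- list(position = position,
              n = length(sequences),
              counts = counts,
              class_counts = cls,
              aromatic_count = sum(res %in% AROMATIC),
              ids_by_residue = split(names(sequences), res))
  class(out) <- "composition_table"
  out
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition> p%d over %d sequences\n", x$position, x$n))
  print(x$counts)
  print(x$class_counts)
  invisible(x)
}

#' C-terminal (last position) composition across sequences
#' @param sequences named character vector of peptide sequences
#' @return a `composition_table` computed on the final residue of each
#'   sequence (positions may differ across lengths)
#' @export
composition_at_cterm <- function(sequences) {
  sequences <- toupper(unlist(sequences))
  last <- vapply(sequences, function(s)
    substr(s, nchar(s), nchar(s)), character(1))
  names(last) <- names(sequences)
  out <- composition_at(stats::setNames(last, names(sequences)), 1L)
  out$position <- NA_integer_
  out
}

#' Per-position relative side-chain accessibility of the bound peptide
#'
#' Computes the side-chain ASA of each peptide position with the receptor
#' present, divides by the free-residue reference ASA (same residue in an
#' extended Ala-X-Ala tripeptide), and classifies by standard thresholds:
#' buried < 0.1 relative ASA, exposed > 0.4, intermediate otherwise.
#' Glycine uses its CA atom as the side-chain surrogate.
#'
#' @param cpx a `pmhc_complex`
#' @param probe probe radius (Angstrom)
#' @param n_points sphere sample points per atom
#' @param free logical; profile the free peptide (receptor absent)
#' @return data.frame: position, resid, asa (A^2), rel_asa, class
#' @export
burial_profile <- function(cpx, probe = 1.4, n_points = 960, free = FALSE) {
  merged <- if (free) cpx$peptide else merge_pmhc(cpx)
  asa <- shrake_rupley(merged, probe = probe, n_points = n_points)
  atoms <- merged$atoms
  pep_chain <- cpx$peptide$atoms$chain[1]
  res <- residue_table(cpx$peptide)
  out <- lapply(seq_len(nrow(res)), function(i) {
    sel <- atoms$chain == pep_chain & atoms$resno == res$resno[i] &
      atoms$icode == res$icode[i]
    sc <- sel & !(atoms$elety %in% c("N", "CA", "C", "O", "OXT"))
    if (res$resid[i] == "GLY" || !any(sc)) sc <- sel & atoms$elety == "CA"
    a <- sum(asa[sc])
    ref <- reference_sidechain_asa(res$resid[i], probe = probe,
                                   n_points = n_points)
    rel <- if (ref > 0) a / ref else 0
    data.frame(position = i, resid = res$resid[i], asa = a, rel_asa = rel,
               class = if (rel < 0.1) "buried" else
                 if (rel > 0.4) "exposed" else "intermediate",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# reference side-chain ASA of residue X in an extended A-X-A tripeptide
reference_sidechain_asa <- function(code3, probe = 1.4, n_points = 960) {
  key <- paste("refasa", code3, probe, n_points)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  code1 <- aa_three2one(code3)
  if (code1 == "X") stop("no reference ASA for non-canonical residue ", code3)
  tri <- make_ideal_peptide(paste0("A", code1, "A"))
  asa <- shrake_rupley(tri, probe = probe, n_points = n_points)
  sc <- tri$atoms$resno == 2 &
    !(tri$atoms$elety %in% c("N", "CA", "C", "O", "OXT"))
  if (code3 == "GLY" || !any(sc))
    sc <- tri$atoms$resno == 2 & tri$atoms$elety == "CA"
  val <- sum(asa[sc])
  .pkg_cache[[key]] <- val
  val
}

#' Residue identity and peptide hydrogen bonds at a conserved cleft position
#'
#' For each complex, reports the receptor alpha-chain residue at
#' `alpha_position` and all geometric hydrogen bonds between that residue
#' and the peptide. The heavy-atom criterion (no hydrogens): donor-acceptor
#' distance <= 3.5 Angstrom and antecedent-donor-acceptor angle >= 90
#' degrees.
#'
#' @param complexes list of `pmhc_complex` objects
#' @param alpha_position author residue number in the alpha chain
#' @param max_dist donor-acceptor distance cutoff (Angstrom)
#' @param min_angle antecedent-donor-acceptor angle cutoff (degrees)
#' @return data.frame with one row per hydrogen bond (zero-row entries get
#'   a residue-identity row with NA bond fields); columns: complex, resid,
#'   found, donor_atom, acceptor_atom, peptide_position, distance, angle,
#'   direction
#' @export
conserved_contact_report <- function(complexes, alpha_position,
                                     max_dist = 3.5, min_angle = 90) {
  rows <- list()
  for (ci in seq_along(complexes)) {
    cpx <- complexes[[ci]]
    cid <- cpx$provenance$source %||% cpx$mhc$id
    mhc <- cpx$mhc
    alpha <- alpha_ca_coords(mhc)$chain
    sel <- which(mhc$atoms$chain == alpha & mhc$atoms$resno == alpha_position)
    if (!length(sel)) {
      warning("complex ", cid, ": no residue ", alpha_position,
              " in alpha chain ", alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        complex = cid, resid = NA_character_, found = FALSE,
        donor_atom = NA_character_, acceptor_atom = NA_character_,
        peptide_position = NA_integer_, distance = NA_real_,
        angle = NA_real_, direction = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    resid <- mhc$atoms$resid[sel[1]]
    merged <- merge_pmhc(cpx)
    typing <- hbond_typing(merged)
    xyz <- get_coords(merged)
    nm <- nrow(mhc$atoms)
    msel <- which(merged$atoms$chain == alpha &
                    merged$atoms$resno == alpha_position &
                    seq_len(nrow(merged$atoms)) <= nm)
    psel <- nm + seq_len(nrow(cpx$peptide$atoms))
    pep_res <- residue_table(cpx$peptide)
    pep_pos <- match(residue_key(cpx$peptide$atoms),
                     unique(residue_key(cpx$peptide$atoms)))
    found <- FALSE
    check <- function(di, ai, direction) {
      r <- sqrt(sum((xyz[di, ] - xyz[ai, ])^2))
      if (r > max_dist) return(NULL)
      ante <- typing$antecedent[di]
      if (is.na(ante)) return(NULL)
      ang <- bond_angle(xyz[ante, ], xyz[di, ], xyz[ai, ])
      if (ang < min_angle) return(NULL)
      pp <- if (direction == "mhc_donor") pep_pos[ai - nm] else pep_pos[di - nm]
      data.frame(complex = cid, resid = resid, found = TRUE,
                 donor_atom = merged$atoms$elety[di],
                 acceptor_atom = merged$atoms$elety[ai],
                 peptide_position = pp, distance = r, angle = ang,
                 direction = direction, stringsAsFactors = FALSE)
    }
    for (di in msel[typing$donor[msel]]) {
      for (ai in psel[typing$acceptor[psel]]) {
        hit <- check(di, ai, "mhc_donor")
        if (!is.null(hit)) { rows[[length(rows) + 1L]] <- hit; found <- TRUE }
      }
    }
    for (di in psel[typing$donor[psel]]) {
      for (ai in msel[typing$acceptor[msel]]) {
        hit <- check(di, ai, "peptide_donor")
        if (!is.null(hit)) { rows[[length(rows) + 1L]] <- hit; found <- TRUE }
      }
    }
    if (!found) {
      rows[[length(rows) + 1L]] <- data.frame(
        complex = cid, resid = resid, found = FALSE,
        donor_atom = NA_character_, acceptor_atom = NA_character_,
        peptide_position = NA_integer_, distance = NA_real_,
        angle = NA_real_, direction = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
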