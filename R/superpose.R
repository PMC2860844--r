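# Rigid-body superposition (Kabsch/SVD), RMSD conventions, and the
# MHC-Calpha fitting convention used to validate reconstructed complexes.

#' Root-mean-square deviation between two coordinate sets (no fitting)
#'
#' @param A,B n x 3 coordinate matrices in one common frame
#' @return RMSD in Angstrom
#' @export
rmsd_between <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Optimal rigid superposition of Q onto P (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimising the RMSD of
#' R q + t against P, via singular value decomposition of the covariance
#' matrix with reflection correction.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3, non-collinear)
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom) of the fitted selection; apply as
#'   `sweep(Q %*% t(rotation), 2, translation, "+")`
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("point sets differ in size")
  if (nrow(P) < 3) stop("need at least 3 points to superpose")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("non-finite coordinates")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  # degeneracy: collinear (or coincident) point sets leave the rotation
  # underdetermined
  if (min(svd(P0)$d[2], svd(Q0)$d[2]) < 1e-8)
    stop("degenerate (collinear) point set: superposition undetermined")
  H <- t(Q0) %*% P0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- pc - as.vector(R %*% qc)
  Qfit <- sweep(Q %*% t(R), 2, t, "+")
  out <- list(rotation = R, translation = t, rmsd = rmsd_between(P, Qfit))
  class(out) <- "superposition_result"
  out
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A, det(R) = %.6f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Apply a superposition transform to a coordinate matrix or structure
#' @param x n x 3 matrix, `pmhc_structure`, or `pmhc_complex`
#' @param fit a `superposition_result` (or list with rotation/translation)
#' @return object of the same type with transformed coordinates
#' @export
apply_transform <- function(x, fit) {
  if (inherits(x, "pmhc_complex")) {
    x$mhc <- apply_transform(x$mhc, fit)
    x$peptide <- apply_transform(x$peptide, fit)
    return(x)
  }
  if (inherits(x, "pmhc_structure")) {
    return(set_coords(x, apply_transform(get_coords(x), fit)))
  }
  sweep(as.matrix(x) %*% t(fit$rotation), 2, fit$translation, "+")
}

# Matched heavy-atom coordinate pairs of two equal-length peptides
# (intersection by position and atom name, heavy atoms only).
matched_peptide_coords <- function(pep_a, pep_b) {
  ra <- residue_table(pep_a); rb <- residue_table(pep_b)
  if (nrow(ra) != nrow(rb)) stop("peptides differ in length")
  ka <- residue_key(pep_a$atoms); kb <- residue_key(pep_b$atoms)
  keys_a <- unique(ka); keys_b <- unique(kb)
  A <- NULL; B <- NULL
  for (i in seq_len(nrow(ra))) {
    sa <- which(ka == keys_a[i]); sb <- which(kb == keys_b[i])
    common <- intersect(pep_a$atoms$elety[sa], pep_b$atoms$elety[sb])
    if (!length(common)) next
    ia <- sa[match(common, pep_a$atoms$elety[sa])]
    ib <- sb[match(common, pep_b$atoms$elety[sb])]
    A <- rbind(A, get_coords(pep_a, ia))
    B <- rbind(B, get_coords(pep_b, ib))
  }
  if (is.null(A) || !nrow(A)) stop("no matched peptide atoms")
  list(A = A, B = B)
}

# Calpha coordinates of the alpha chain (largest receptor chain), keyed by
# residue number + insertion code.
alpha_ca_coords <- function(mhc) {
  atoms <- mhc$atoms
  ca <- atoms$elety == "CA"
  chains <- table(atoms$chain[ca])
  if (!length(chains)) stop("receptor has no CA atoms")
  alpha <- names(chains)[which.max(chains)]
  sel <- which(ca & atoms$chain == alpha)
  key <- paste(atoms$resno[sel], atoms$icode[sel])
  keep <- !duplicated(key)
  list(chain = alpha, key = key[keep],
       xyz = get_coords(mhc, sel[keep]))
}

#' Validation metric: fit by MHC Calpha, report epitope heavy-atom RMSD
#'
#' Superposes the model complex onto the reference using only the Calpha
#' atoms of the MHC alpha chain (matched by residue number), then reports
#' the all-heavy-atom RMSD of the peptide in that frame, without refitting
#' the peptide. This is the standard validation convention for judging a
#' reconstructed complex against its crystal structure (bound: 2.2 A).
#'
#' @param model,reference `pmhc_complex` objects of the same allele and
#'   peptide length
#' @return list with `model` (transformed into the reference frame),
#'   `epitope_rmsd` (Angstrom), `mhc_ca_rmsd` and the `fit`
#' @export
fit_by_mhc_ca <- function(model, reference) {
  ca_m <- alpha_ca_coords(model$mhc)
  ca_r <- alpha_ca_coords(reference$mhc)
  common <- intersect(ca_m$key, ca_r$key)
  if (length(common) < 3)
    stop("MHC alpha chains share fewer than 3 Calpha residues; unalignable")
  fit <- kabsch(ca_r$xyz[match(common, ca_r$key), , drop = FALSE],
                ca_m$xyz[match(common, ca_m$key), , drop = FALSE])
  model_t <- apply_transform(model, fit)
  mp <- matched_peptide_coords(reference$peptide, model_t$peptide)
  list(model = model_t,
       epitope_rmsd = rmsd_between(mp$A, mp$B),
       mhc_ca_rmsd = fit$rmsd,
       fit = fit)
}

#' Alternative validation metric: fit by epitope Calpha
#'
#' Superposes the peptides directly on their own Calpha atoms and reports
#' the all-heavy-atom RMSD; measures conformational agreement only,
#' ignoring placement in the cleft.
#'
#' @param model,reference `pmhc_complex` objects with equal-length peptides
#' @return list with `epitope_rmsd`, `ca_rmsd` and the `fit`
#' @export
fit_by_epitope_ca <- function(model, reference) {
  ca_m <- get_coords(model$peptide, model$peptide$atoms$elety == "CA")
  ca_r <- get_coords(reference$peptide, reference$peptide$atoms$elety == "CA")
  if (nrow(ca_m) != nrow(ca_r)) stop("peptides differ in length")
  fit <- kabsch(ca_r, ca_m)
  pep_t <- apply_transform(model$peptide, fit)
  mp <- matched_peptide_coords(reference$peptide, pep_t)
  list(epitope_rmsd = rmsd_between(mp$A, mp$B), ca_rmsd = fit$rmsd,
       fit = fit)
}
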