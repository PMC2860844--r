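# Solvent-accessible surface area (Shrake-Rupley sphere sampling with a
# deterministic golden-spiral point set), per-position ASA signatures of
# the bound peptide, and TCR-face topology/electrostatic maps with a
# complex-vs-complex similarity measure.

# Chothia-style heavy-atom radii (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` golden-spiral points on each atom's solvent sphere
#' (van der Waals radius + probe) and counts the fraction not occluded by
#' any neighbour's solvent sphere. Deterministic for a fixed point count.
#'
#' @param structure a `pmhc_structure`
#' @param probe probe radius (Angstrom, default 1.4 = water)
#' @param n_points sphere sample points per atom (>= 100)
#' @return numeric vector of per-atom ASA (Angstrom^2)
#' @export
shrake_rupley <- function(structure, probe = 1.4, n_points = 960) {
  stopifnot(probe > 0, n_points >= 100)
  atoms <- structure$atoms
  n <- nrow(atoms)
  radii <- VDW_RADII[atoms$element]
  if (anyNA(radii))
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$element[is.na(radii)]), collapse = ", "))
  radii <- radii + probe
  xyz <- get_coords(structure)
  sphere <- golden_spiral_points(n_points)
  asa <- numeric(n)
  maxr <- max(radii)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (radii[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (radii[i] + radii[nb])^2]
    pts <- sweep(sphere * radii[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        pd2 <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2)
        free[free] <- pd2 >= radii[j]^2
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    asa[i] <- frac * 4 * pi * radii[i]^2
  }
  asa
}

#' Per-position ASA signature of the bound peptide
#'
#' Whole-residue (backbone + side chain) solvent-accessible surface area of
#' each peptide position computed with the receptor present and occluding.
#'
#' @param cpx a `pmhc_complex`
#' @param probe probe radius (Angstrom)
#' @param n_points sphere sample points per atom
#' @param sidechain_only logical; restrict to side-chain atoms (CA for Gly)
#' @param free logical; compute the free-peptide signature (receptor absent)
#' @return an `asa_signature`: list with `id`, `values` (named p1..pn,
#'   Angstrom^2), `probe`, `n_points`
#' @export
asa_signature <- function(cpx, probe = 1.4, n_points = 960,
                          sidechain_only = FALSE, free = FALSE) {
  merged <- if (free) cpx$peptide else merge_pmhc(cpx)
  asa <- shrake_rupley(merged, probe = probe, n_points = n_points)
  atoms <- merged$atoms
  pep_chain <- cpx$peptide$atoms$chain[1]
  res <- residue_table(cpx$peptide)
  vals <- vapply(seq_len(nrow(res)), function(i) {
    sel <- atoms$chain == pep_chain & atoms$resno == res$resno[i] &
      atoms$icode == res$icode[i]
    if (sidechain_only) {
      sc <- sel & !(atoms$elety %in% c("N", "CA", "C", "O", "OXT"))
      if (res$resid[i] == "GLY" || !any(sc)) sc <- sel & atoms$elety == "CA"
      sel <- sc
    }
    sum(asa[sel])
  }, numeric(1))
  names(vals) <- paste0("p", seq_along(vals))
  out <- list(id = cpx$provenance$source %||% cpx$mhc$id, values = vals,
              probe = probe, n_points = n_points)
  class(out) <- "asa_signature"
  out
}

#' @export
print.asa_signature <- function(x, ...) {
  cat(sprintf("<asa_signature> %s (probe %.1f A, %d pts)\n",
              x$id, x$probe, x$n_points))
  print(round(x$values, 1))
  invisible(x)
}

#' Compare two ASA signatures
#' @param a,b `asa_signature` objects of equal peptide length
#' @return list: `delta` (per-position, a - b), `rms_delta`,
#'   `max_delta_position`
#' @export
compare_signatures <- function(a, b) {
  if (length(a$values) != length(b$values))
    stop("signatures differ in peptide length")
  delta <- a$values - b$values
  list(delta = delta,
       rms_delta = sqrt(mean(delta^2)),
       max_delta_position = unname(which.max(abs(delta))))
}

# Least-squares cleft reference plane: fitted through the receptor Calpha
# atoms, normal oriented toward the peptide centroid.
cleft_plane <- function(cpx) {
  ca <- get_coords(cpx$mhc, cpx$mhc$atoms$elety == "CA")
  if (nrow(ca) < 3) stop("receptor has too few CA atoms for a cleft plane")
  ctr <- colMeans(ca)
  normal <- svd(sweep(ca, 2, ctr))$v[, 3]
  pep_ctr <- colMeans(get_coords(cpx$peptide))
  if (sum((pep_ctr - ctr) * normal) < 0) normal <- -normal
  list(center = ctr, normal = normal)
}

#' Coulomb potential of a set of point charges, in kT/e
#'
#' Evaluates the (unclipped) electrostatic potential at arbitrary points
#' from coarse formal charges, using either the distance-dependent
#' dielectric eps = 4r or a constant dielectric, with the conversion
#' 332.06 kcal A / (mol e^2) and kT = 0.593 kcal/mol.
#'
#' @param points n x 3 evaluation points (Angstrom)
#' @param sources m x 3 charge positions
#' @param q charge vector (e), length m
#' @param dielectric "r4" or "const"
#' @param eps_const constant-dielectric value for `dielectric = "const"`
#' @return numeric vector of potentials (kT/e)
#' @export
coulomb_potential <- function(points, sources, q,
                              dielectric = c("r4", "const"),
                              eps_const = 80) {
  dielectric <- match.arg(dielectric)
  params <- default_scoring_params()
  points <- as.matrix(points); sources <- as.matrix(sources)
  vals <- numeric(nrow(points))
  for (s in which(q != 0)) {
    r <- sqrt(rowSums(sweep(points, 2, sources[s, ])^2))
    r <- pmax(r, 0.5)
    vals <- vals + if (dielectric == "const")
      params$coulomb_k * q[s] / (eps_const * r) else
        params$coulomb_k * q[s] / (4 * r^2)
  }
  vals / params$kT
}

#' Electrostatic potential map of the TCR-facing surface
#'
#' Samples the solvent-accessible surface of the complex around the
#' peptide, keeps points facing "up" relative to the cleft reference plane
#' (the TCR side), and evaluates the Coulomb potential of the coarse formal
#' charges at each point, in kT/e, clipped to [-10, +10]. Point heights are
#' measured from the cleft plane.
#'
#' @param cpx a `pmhc_complex`
#' @param probe probe radius (Angstrom)
#' @param n_points sphere sample points per atom
#' @param region "tcr" (upward-facing, near-peptide) or "all"
#' @param dielectric "r4" (distance-dependent, eps = 4r) or "const"
#' @param eps_const constant-dielectric value when `dielectric = "const"`
#' @param clip clipping bound for the potential (kT/e)
#' @param max_dist_to_peptide region radius around the peptide (Angstrom)
#' @param termini logical; include the +/-1 charges of chain termini
#' @return a `surface_map`: `points` (n x 3), `values` (kT/e, clipped),
#'   `heights` (Angstrom above the cleft plane), `plane`
#' @export
surface_potential <- function(cpx, probe = 1.4, n_points = 240,
                              region = c("tcr", "all"),
                              dielectric = c("r4", "const"), eps_const = 80,
                              clip = 10, max_dist_to_peptide = 12,
                              termini = TRUE) {
  region <- match.arg(region)
  dielectric <- match.arg(dielectric)
  params <- default_scoring_params()
  merged <- merge_pmhc(cpx)
  atoms <- merged$atoms
  xyz <- get_coords(merged)
  radii <- VDW_RADII[atoms$element]
  if (anyNA(radii))
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$element[is.na(radii)]), collapse = ", "))
  radii <- radii + probe
  charges <- c(assign_charges(cpx$mhc, termini = termini),
               assign_charges(cpx$peptide, termini = termini))
  plane <- cleft_plane(cpx)
  pep_xyz <- get_coords(cpx$peptide)
  sphere <- golden_spiral_points(n_points)
  pts <- NULL; normals <- NULL
  near_pep <- vapply(seq_len(nrow(xyz)), function(i) {
    min(rowSums(sweep(pep_xyz, 2, xyz[i, ])^2)) <=
      (max_dist_to_peptide + radii[i])^2
  }, logical(1))
  for (i in which(near_pep | region == "all")) {
    cand <- sweep(sphere * radii[i], 2, xyz[i, ], "+")
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (radii[i] + max(radii))^2 & seq_len(nrow(xyz)) != i)
    nb <- nb[d2[nb] < (radii[i] + radii[nb])^2]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      pd2 <- rowSums(sweep(cand[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- pd2 >= radii[j]^2
    }
    if (!any(free)) next
    pts <- rbind(pts, cand[free, , drop = FALSE])
    normals <- rbind(normals, sphere[free, , drop = FALSE])
  }
  if (is.null(pts) || !nrow(pts)) stop("empty surface region")
  if (region == "tcr") {
    up <- normals %*% plane$normal > 0
    pts <- pts[up[, 1], , drop = FALSE]
    if (!nrow(pts)) stop("empty TCR-face region")
  }
  vals <- coulomb_potential(pts, xyz, charges, dielectric = dielectric,
                            eps_const = eps_const)
  vals <- pmax(-clip, pmin(clip, vals))
  heights <- as.numeric(sweep(pts, 2, plane$center) %*% plane$normal)
  out <- list(points = pts, values = vals, heights = heights, plane = plane,
              id = cpx$provenance$source %||% cpx$mhc$id)
  class(out) <- "surface_map"
  out
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf(
    "<surface_map> %s: %d points, potential %.2f..%.2f kT/e, height %.1f..%.1f A\n",
    x$id, nrow(x$points), min(x$values), max(x$values),
    min(x$heights), max(x$heights)))
  invisible(x)
}

#' Compare two TCR-face surface maps
#'
#' Matches each point of `a` to its nearest point of `b` within a capture
#' radius (maps must be in one common frame, e.g. after fitting the
#' complexes by MHC Calpha) and reports the RMS of height differences
#' (topology), the RMS of potential differences, and the matched fraction.
#'
#' @param a,b `surface_map` objects in a common frame
#' @param capture_radius nearest-point match cutoff (Angstrom)
#' @return list: `topology_rms` (A), `potential_rms` (kT/e),
#'   `matched_fraction`
#' @export
compare_surfaces <- function(a, b, capture_radius = 1.5) {
  A <- a$points; B <- b$points
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  nn <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(A)), nn)], 0))
  ok <- dist <= capture_radius
  if (!any(ok)) stop("no matched surface points within the capture radius")
  dh <- a$heights[ok] - b$heights[nn[ok]]
  dv <- a$values[ok] - b$values[nn[ok]]
  list(topology_rms = sqrt(mean(dh^2)),
       potential_rms = sqrt(mean(dv^2)),
       matched_fraction = mean(ok))
}
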