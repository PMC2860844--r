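# Steepest-descent energy minimisation with backtracking line search on the
# package potential. The pair list is built once at entry (cutoff + margin)
# and the line-search objective evaluates all listed pairs without
# truncation, so the minimised objective is smooth and accepted-step
# energies are guaranteed non-increasing.

prepare_system <- function(structure, params = default_scoring_params(),
                           restraint_ref = NULL, margin = 2) {
  atoms <- structure$atoms
  n <- nrow(atoms)
  xyz <- get_coords(structure)
  lj <- lj_table_for(atoms$element, params)
  charges <- assign_charges(structure)
  typing <- hbond_typing(structure)
  bonds <- bond_graph(structure)
  excl <- exclusion_keys(bonds, n)
  pl <- pairs_within(xyz, seq_len(n), seq_len(n), params$cutoff + margin)
  pl <- pl[pl$i < pl$j, , drop = FALSE]
  pk <- paste(pl$i, pl$j, sep = "|")
  pl <- pl[!(pk %in% excl), , drop = FALSE]
  # restraint pairs: bonded and 1-3 distances toward the reference geometry
  rest <- NULL
  if (!is.null(restraint_ref)) {
    ref_xyz <- get_coords(restraint_ref)
    if (nrow(ref_xyz) != n) stop("restraint reference atom count mismatch")
    adj <- vector("list", n)
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    ri <- integer(0); rj <- integer(0)
    for (k in seq_len(nrow(bonds))) {
      ri <- c(ri, bonds[k, 1]); rj <- c(rj, bonds[k, 2])
    }
    for (i in seq_len(n)) {
      nb <- unique(adj[[i]])
      if (length(nb) > 1) {
        cmb <- utils::combn(nb, 2)
        ri <- c(ri, cmb[1, ]); rj <- c(rj, cmb[2, ])
      }
    }
    keep <- !duplicated(paste(pmin(ri, rj), pmax(ri, rj)))
    ri <- ri[keep]; rj <- rj[keep]
    r0 <- sqrt(rowSums((ref_xyz[ri, , drop = FALSE] -
                          ref_xyz[rj, , drop = FALSE])^2))
    rest <- list(i = ri, j = rj, r0 = r0)
  }
  list(n = n, lj = lj, charges = charges, typing = typing,
       torsions = chi_torsion_list(structure), pairs = pl[, c("i", "j")],
       restraints = rest, params = params)
}

system_energy <- function(sys, xyz, gradient = FALSE, truncate = FALSE) {
  params <- sys$params
  pr <- sys$pairs
  r <- sqrt(rowSums((xyz[pr$i, , drop = FALSE] -
                       xyz[pr$j, , drop = FALSE])^2))
  pairs <- data.frame(i = pr$i, j = pr$j, r = r)
  if (truncate) pairs <- pairs[pairs$r <= params$cutoff, , drop = FALSE]
  nb <- nonbonded_energy(xyz, pairs, sys$lj, sys$charges, sys$typing,
                         params, gradient = gradient)
  tor <- torsion_energy(xyz, sys$torsions, params$torsion_k,
                        gradient = gradient)
  e_rest <- 0
  g <- if (gradient) nb$grad + tor$grad else NULL
  if (!is.null(sys$restraints)) {
    rs <- sys$restraints
    d <- xyz[rs$i, , drop = FALSE] - xyz[rs$j, , drop = FALSE]
    rr <- sqrt(rowSums(d^2))
    e_rest <- params$restraint_k * sum((rr - rs$r0)^2)
    if (gradient) {
      f <- 2 * params$restraint_k * (rr - rs$r0) / rr
      vals <- rbind(f * d, -f * d)
      acc <- rowsum(vals, group = c(rs$i, rs$j))
      rows <- as.integer(rownames(acc))
      g[rows, ] <- g[rows, ] + acc
    }
  }
  list(energy = new_energy_breakdown(steric = nb$steric, hbond = nb$hbond,
                                     electrostatic = nb$electrostatic,
                                     torsion = tor$e, restraint = e_rest),
       grad = g)
}

#' Steepest-descent energy minimisation
#'
#' Relaxes a structure under the package potential (nonbonded terms,
#' chi-staple torsions, and harmonic bonded/1-3 distance restraints toward
#' the input geometry). Atoms in `fixed` never move. Accepted-step energies
#' are non-increasing by construction of the backtracking line search; the
#' run stops at `nsteps`, at the gradient tolerance, or when no decreasing
#' step exists.
#'
#' @param structure a `pmhc_structure`
#' @param nsteps maximum number of accepted steps (>= 1)
#' @param fixed logical vector (one per atom) or integer indices of
#'   immobile atoms; NULL mobilises everything
#' @param params scoring parameters
#' @param tol gradient-infinity-norm convergence tolerance (score units per
#'   Angstrom)
#' @return list with `structure` (relaxed) and `trace` (an `em_trace`:
#'   data.frame of accepted step energies plus `converged`,
#'   `nsteps_requested`)
#' @export
minimize <- function(structure, nsteps = 100, fixed = NULL,
                     params = default_scoring_params(), tol = 1e-3) {
  stopifnot(nsteps >= 1)
  n <- nrow(structure$atoms)
  fx <- logical(n)
  if (!is.null(fixed)) {
    if (is.logical(fixed)) fx <- rep_len(fixed, n) else fx[fixed] <- TRUE
  }
  sys <- prepare_system(structure, params, restraint_ref = structure)
  xyz <- get_coords(structure)
  ev <- system_energy(sys, xyz, gradient = TRUE)
  if (!is.finite(ev$energy$total))
    stop("non-finite energy at minimisation start")
  energies <- ev$energy$total
  steps <- 0L
  converged <- FALSE
  alpha <- 1e-3
  if (!all(fx)) {
    while (steps < nsteps) {
      g <- ev$grad
      g[fx, ] <- 0
      gmax <- max(abs(g))
      if (gmax < tol) { converged <- TRUE; break }
      accepted <- FALSE
      a <- min(alpha * 2, 0.5 / max(gmax, 1))
      gsq <- sum(g^2)
      for (try in 1:40) {
        xyz_new <- xyz - a * g
        ev_new <- system_energy(sys, xyz_new, gradient = TRUE)
        if (is.finite(ev_new$energy$total) &&
            ev_new$energy$total <= energies[length(energies)] - 1e-4 * a * gsq) {
          accepted <- TRUE
          break
        }
        a <- a / 2
      }
      if (!accepted) { converged <- TRUE; break }
      alpha <- a
      xyz <- xyz_new
      ev <- ev_new
      steps <- steps + 1L
      energies <- c(energies, ev$energy$total)
    }
  } else {
    converged <- TRUE
  }
  trace <- list(
    steps = data.frame(step = seq_along(energies) - 1L, total = energies),
    nsteps_requested = nsteps, converged = converged,
    final = ev$energy)
  class(trace) <- "em_trace"
  list(structure = set_coords(structure, xyz), trace = trace)
}

#' @export
print.em_trace <- function(x, ...) {
  cat(sprintf("<em_trace> %d accepted steps (requested %d), %s; E %.4f -> %.4f\n",
              nrow(x$steps) - 1L, x$nsteps_requested,
              if (x$converged) "converged" else "step-limited",
              x$steps$total[1], x$steps$total[nrow(x$steps)]))
  invisible(x)
}
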