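# The dock-minimize-dock (D1-EM-D2) construction protocol: rigid receptor,
# rigid peptide backbone, flexible side chains. Conformers are sampled as
# small rigid-body perturbations of the whole peptide plus chi-staple
# resampling, scored with the package potential, pooled over replicate
# runs, clustered by heavy-atom RMSD, and represented by the most frequent
# conformation (lowest energy within the largest cluster).

#' Protocol configuration for pMHC construction
#'
#' @param n_runs replicate docking runs pooled into one population
#' @param n_out_per_run poses retained per run (best-scoring)
#' @param n_iter sampling iterations (proposals) per run; the
#'   search-effort analog of a docking engine's exhaustiveness
#' @param em_short steps for the post-threading relaxation
#' @param em_long steps for the complex relaxation between D1 and D2
#' @param cluster_rmsd greedy clustering cutoff (Angstrom, heavy atoms)
#' @param trans_amp maximum rigid-body translation per proposal (Angstrom)
#' @param rot_amp maximum rigid-body rotation per proposal (degrees)
#' @param chi_jitter sd of the jitter around chi staples (degrees)
#' @param resample_chi logical; propose side-chain chi moves (disable to
#'   dock with the input side-chain conformations only)
#' @param selection "frequency" (largest cluster wins, energy breaks ties)
#'   or "energy" (global best-energy cluster)
#' @return a `protocol_config`
#' @export
docking_config <- function(n_runs = 20, n_out_per_run = 50, n_iter = 200,
                           em_short = 100, em_long = 1000,
                           cluster_rmsd = 1.0, trans_amp = 1.0,
                           rot_amp = 10, chi_jitter = 20,
                           resample_chi = TRUE,
                           selection = c("frequency", "energy")) {
  stopifnot(n_runs >= 1, n_out_per_run >= 1, n_iter >= 1,
            em_short >= 1, em_long >= 1, cluster_rmsd > 0)
  out <- list(n_runs = n_runs, n_out_per_run = n_out_per_run,
              n_iter = n_iter, em_short = em_short, em_long = em_long,
              cluster_rmsd = cluster_rmsd, trans_amp = trans_amp,
              rot_amp = rot_amp, chi_jitter = chi_jitter,
              resample_chi = resample_chi,
              selection = match.arg(selection))
  class(out) <- "protocol_config"
  out
}

derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + 1000003 * offset) %% 2147483647)
}

# rotate the chi-k torsion of one residue's atoms to `new_chi` (degrees),
# preserving internal geometry: all atoms at/after the first chi-k atom in
# the z-matrix order rotate about the chi bond axis.
set_chi <- function(atoms_res, resid, k, new_chi) {
  quads <- chi_atoms(resid)
  if (k > length(quads)) return(atoms_res)
  quad <- quads[[k]]
  idx <- match(quad, atoms_res$elety)
  if (anyNA(idx)) return(atoms_res)
  xyz <- as.matrix(atoms_res[, c("x", "y", "z")])
  cur <- dihedral_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ],
                        xyz[idx[4], ])
  delta <- new_chi - cur
  tab <- sidechain_topology()
  rows <- tab[tab$resid == toupper(resid), , drop = FALSE]
  first <- which(rows$tortype == paste0("chi", k))[1]
  moving_names <- rows$atom[first:nrow(rows)]
  mv <- which(atoms_res$elety %in% moving_names)
  axis_from <- xyz[idx[3], ]
  R <- rotation_about_axis(xyz[idx[3], ] - xyz[idx[2], ], -delta)
  xyz[mv, ] <- sweep(sweep(xyz[mv, , drop = FALSE], 2, axis_from) %*% t(R),
                     2, axis_from, "+")
  atoms_res[, c("x", "y", "z")] <- xyz
  atoms_res
}

# Deterministic local refinement of a pose under a scorer: cyclic
# rigid-body line searches along the axes plus greedy per-chi staple scans
# (the docking analog of a search engine's local optimisation step).
refine_pose <- function(scorer, atoms, cycles = 2, rigid_range = 0.8,
                        rigid_step = 0.05) {
  key <- residue_key(atoms)
  res_split <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  res_types <- vapply(res_split, function(r) atoms$resid[r[1]], character(1))
  shifts <- seq(-rigid_range, rigid_range, by = rigid_step)
  for (cycle in seq_len(cycles)) {
    # side chains first: a threaded/relaxed pose clashes through its side
    # chains, and resolving that by rigid motion would drag the backbone
    # out of register
    for (ri in seq_along(res_split)) {
      rtype <- res_types[ri]
      if (!is_canonical_aa(rtype) || rtype == "PRO") next
      nchi <- n_chi(rtype)
      if (nchi == 0) next
      rsel <- res_split[[ri]]
      score_res <- function(trial) {
        txyz <- as.matrix(atoms[, c("x", "y", "z")])
        txyz[rsel, ] <- as.matrix(trial[, c("x", "y", "z")])
        scorer(txyz)$total
      }
      ares <- atoms[rsel, , drop = FALSE]
      cur <- measure_chi(rtype, ares)
      # joint scan over the first two torsions (escapes single-flip traps),
      # then sequential scans over any remaining torsions
      c1 <- unique(c(cur[1], chi_staples(rtype, 1)))
      c2 <- if (nchi >= 2) unique(c(cur[2], chi_staples(rtype, 2))) else NA
      best_e <- Inf; best_atoms <- ares
      for (ch1 in c1[!is.na(c1)]) {
        t1 <- set_chi(ares, rtype, 1, ch1)
        for (ch2 in c2[!is.na(c2)] %||% NA) {
          trial <- if (nchi >= 2 && !is.na(ch2))
            set_chi(t1, rtype, 2, ch2) else t1
          e <- score_res(trial)
          if (e < best_e) { best_e <- e; best_atoms <- trial }
        }
      }
      ares <- best_atoms
      if (nchi >= 3) {
        for (k in 3:nchi) {
          cand <- unique(c(measure_chi(rtype, ares)[k],
                           chi_staples(rtype, k)))
          best_e <- Inf; best_atoms <- ares
          for (ch in cand[!is.na(cand)]) {
            trial <- set_chi(ares, rtype, k, ch)
            e <- score_res(trial)
            if (e < best_e) { best_e <- e; best_atoms <- trial }
          }
          ares <- best_atoms
        }
      }
      atoms[rsel, ] <- ares
    }
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    for (ax in 1:3) {
      vals <- vapply(shifts, function(sh) {
        xs <- xyz; xs[, ax] <- xs[, ax] + sh
        scorer(xs)$total
      }, numeric(1))
      xyz[, ax] <- xyz[, ax] + shifts[which.min(vals)]
    }
    atoms[, c("x", "y", "z")] <- xyz
  }
  list(atoms = atoms,
       energy = scorer(as.matrix(atoms[, c("x", "y", "z")])))
}

# fast rescoring closure: atom metadata precomputed once, poses differ only
# in peptide coordinates
make_pose_scorer <- function(receptor, peptide,
                             params = default_scoring_params()) {
  merged <- new_structure("scored", rbind(receptor$atoms, peptide$atoms))
  nr <- nrow(receptor$atoms)
  np <- nrow(peptide$atoms)
  lj <- lj_table_for(merged$atoms$element, params)
  charges <- c(assign_charges(receptor), assign_charges(peptide))
  typing <- hbond_typing(merged)
  rec_xyz <- get_coords(receptor)
  function(pose_xyz) {
    xyz <- rbind(rec_xyz, pose_xyz)
    pairs <- pairs_within(xyz, seq_len(nr), nr + seq_len(np), params$cutoff)
    nb <- nonbonded_energy(xyz, pairs, lj, charges, typing, params)
    new_energy_breakdown(steric = nb$steric, hbond = nb$hbond,
                         electrostatic = nb$electrostatic)
  }
}

#' Sample a docked-conformer population
#'
#' Runs `n_runs` replicate stochastic local searches from the input pose.
#' Each iteration proposes a move from the run's current best pose: a
#' random rigid-body perturbation of the whole peptide (translation up to
#' `trans_amp`, rotation up to `rot_amp` about the peptide centroid)
#' and/or a chi-staple resampling of one or two randomly chosen side
#' chains (geometry-preserving bond rotations with Gaussian jitter);
#' improving proposals become the new current pose. Backbone internal
#' geometry is untouched and the receptor never moves. Every proposal is a
#' population candidate; the best `n_out_per_run` poses of each run (by
#' total interaction energy) are pooled. Deterministic for a fixed seed.
#'
#' @param receptor `pmhc_structure` receptor (held rigid)
#' @param peptide `pmhc_structure` peptide start pose (backbone already in
#'   a cleft-compatible, pattern-threaded conformation)
#' @param config a `protocol_config`
#' @param seed master seed; per-run streams are derived by fixed offsets
#' @param seed_offset stream offset base (distinguishes D1 from D2)
#' @param params scoring parameters
#' @return a `conformer_population` (unclustered)
#' @export
sample_conformers <- function(receptor, peptide, config = docking_config(),
                              seed = 1, seed_offset = 0,
                              params = default_scoring_params()) {
  scorer <- make_pose_scorer(receptor, peptide, params)
  atoms <- peptide$atoms
  key <- residue_key(atoms)
  res_split <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  res_types <- vapply(res_split, function(r) atoms$resid[r[1]], character(1))
  # proline ring torsions are not resampled (the ring is kept closed)
  chi_counts <- vapply(res_types, function(t)
    if (is_canonical_aa(t) && t != "PRO") n_chi(t) else 0L, integer(1))
  chi_res <- which(chi_counts > 0)
  # deterministic local refinement of the input pose; every run starts its
  # stochastic search from this common refined pose
  start <- refine_pose(scorer, atoms)
  atoms <- start$atoms
  conformers <- list()
  for (run in seq_len(config$n_runs)) {
    run_conf <- with_seed(derive_seed(seed, seed_offset + run), {
      current <- atoms
      current_e <- scorer(as.matrix(current[, c("x", "y", "z")]))
      out <- vector("list", config$n_iter + 1L)
      out[[1]] <- list(xyz = as.matrix(current[, c("x", "y", "z")]),
                       energy = current_e)
      for (it in seq_len(config$n_iter)) {
        pose <- current
        if (config$resample_chi && length(chi_res)) {
          nres <- min(length(chi_res), sample(1:2, 1))
          for (ri in sample(chi_res, nres)) {
            rsel <- res_split[[ri]]
            ares <- pose[rsel, , drop = FALSE]
            for (k in seq_len(chi_counts[ri])) {
              staples <- chi_staples(res_types[ri], k)
              target <- staples[sample.int(length(staples), 1)] +
                stats::rnorm(1, sd = config$chi_jitter)
              ares <- set_chi(ares, res_types[ri], k, target)
            }
            pose[rsel, ] <- ares
          }
        }
        # rigid-body perturbation about the centroid
        xyz <- as.matrix(pose[, c("x", "y", "z")])
        if (config$rot_amp > 0) {
          ax <- stats::rnorm(3)
          R <- rotation_about_axis(ax, stats::runif(1, -config$rot_amp,
                                                    config$rot_amp))
          ctr <- colMeans(xyz)
          xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
        }
        if (config$trans_amp > 0) {
          tr <- stats::runif(3, -1, 1)
          nrm <- vnorm(tr)
          if (nrm > 1e-9) {
            tr <- tr / nrm * stats::runif(1, 0, config$trans_amp)
            xyz <- sweep(xyz, 2, tr, "+")
          }
        }
        e <- scorer(xyz)
        out[[it + 1L]] <- list(xyz = xyz, energy = e)
        if (e$total < current_e$total) {
          current[, c("x", "y", "z")] <- xyz
          current_e <- e
        }
      }
      # local optimisation of the run's best pose (deterministic)
      ref <- refine_pose(scorer, current)
      out[[length(out) + 1L]] <- list(
        xyz = as.matrix(ref$atoms[, c("x", "y", "z")]), energy = ref$energy,
        refined = TRUE)
      out
    })
    for (q in seq_along(run_conf)) {
      run_conf[[q]]$run <- run
      if (is.null(run_conf[[q]]$refined)) run_conf[[q]]$refined <- FALSE
    }
    totals <- vapply(run_conf, function(cf) cf$energy$total, numeric(1))
    keep <- order(totals)[seq_len(min(config$n_out_per_run,
                                      length(run_conf)))]
    conformers <- c(conformers, run_conf[keep])
  }
  out <- list(conformers = conformers, template = peptide,
              clusters = NULL, representative = NA_integer_,
              config = config)
  class(out) <- "conformer_population"
  out
}

#' @export
print.conformer_population <- function(x, ...) {
  totals <- vapply(x$conformers, function(cf) cf$energy$total, numeric(1))
  cat(sprintf("<conformer_population> %d poses, E %.3f..%.3f",
              length(totals), min(totals), max(totals)))
  if (!is.null(x$clusters))
    cat(sprintf(", %d clusters, representative #%d",
                length(x$clusters), x$representative))
  cat("\n")
  invisible(x)
}

#' Cluster a conformer population and pick its representative
#'
#' Greedy clustering by all-heavy-atom peptide RMSD: conformers are visited
#' in order of increasing energy; each joins the first cluster whose
#' founder pose lies within `cluster_rmsd`, otherwise founds a new cluster.
#' The representative is chosen frequency-first: the largest cluster wins
#' (ties to the cluster holding the lower-energy member) and its
#' lowest-energy member (ties to the lower index) represents the
#' population. With `selection = "energy"` the cluster of the global
#' best-energy pose wins instead.
#'
#' @param population a `conformer_population`
#' @param cluster_rmsd clustering cutoff (Angstrom)
#' @param selection "frequency" or "energy"
#' @return the population with `clusters` and `representative` filled
#' @export
cluster_conformers <- function(population,
                               cluster_rmsd = population$config$cluster_rmsd,
                               selection = population$config$selection) {
  confs <- population$conformers
  n <- length(confs)
  stopifnot(n >= 1)
  totals <- vapply(confs, function(cf) cf$energy$total, numeric(1))
  visit <- order(totals, seq_len(n))
  medoids <- integer(0)
  membership <- integer(n)
  for (ci in visit) {
    placed <- FALSE
    for (m in seq_along(medoids)) {
      if (rmsd_between(confs[[ci]]$xyz, confs[[medoids[m]]]$xyz) <=
          cluster_rmsd) {
        membership[ci] <- m
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      medoids <- c(medoids, ci)
      membership[ci] <- length(medoids)
    }
  }
  clusters <- lapply(seq_along(medoids), function(m)
    list(members = which(membership == m), medoid = medoids[m]))
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  best_in <- vapply(clusters, function(cl) min(totals[cl$members]),
                    numeric(1))
  win <- if (identical(selection, "energy")) {
    which.min(best_in)
  } else {
    cand <- which(sizes == max(sizes))
    cand[which.min(best_in[cand])]
  }
  members <- clusters[[win]]$members
  rep_idx <- members[order(totals[members], members)][1]
  population$clusters <- clusters
  population$representative <- rep_idx
  population
}

#' Representative conformer index of a population
#' @inheritParams cluster_conformers
#' @return integer index into `population$conformers`
#' @export
select_representative <- function(population,
                                  cluster_rmsd =
                                    population$config$cluster_rmsd,
                                  selection = population$config$selection) {
  cluster_conformers(population, cluster_rmsd, selection)$representative
}

# Frequency analysis over the best conformation of each run: the run-best
# (locally refined) poses are clustered and the winning cluster's
# lowest-energy member is returned as a global conformer index.
select_from_run_bests <- function(population,
                                  cluster_rmsd =
                                    population$config$cluster_rmsd,
                                  selection = population$config$selection) {
  refined <- which(vapply(population$conformers,
                          function(cf) isTRUE(cf$refined), logical(1)))
  if (!length(refined)) return(select_representative(population,
                                                     cluster_rmsd, selection))
  sub <- population
  sub$conformers <- population$conformers[refined]
  sub <- cluster_conformers(sub, cluster_rmsd, selection)
  refined[sub$representative]
}

population_pose <- function(population, index) {
  set_coords(population$template, population$conformers[[index]]$xyz)
}

backbone_atom_selection <- function(structure) {
  structure$atoms$elety %in% c("N", "CA", "C", "O", "OXT")
}

#' Build a pMHC complex by threading plus dock-minimize-dock
#'
#' Executes the full construction protocol for a target sequence: thread
#' the sequence onto the template peptide backbone, relax the threaded
#' side chains (short EM, backbone fixed), dock into the donor receptor
#' (D1: `n_runs` x `n_out_per_run` population, frequency-first
#' representative), relax the selected complex (long EM; all backbones
#' fixed, side chains of both molecules free), separate the partners and
#' dock again (D2). The receptor coordinates are modified only during the
#' complex relaxation, never by docking.
#'
#' @param target_seq one-letter peptide sequence to build
#' @param mhc_donor `pmhc_complex` donating the receptor (its own peptide
#'   is ignored); may equal `template`
#' @param template `pmhc_complex` whose peptide backbone is the
#'   allele/length pattern template (same length as `target_seq`)
#' @param config a `protocol_config`
#' @param seed master seed for the whole protocol
#' @param params scoring parameters
#' @return a `docking_result`: `complex` (final `pmhc_complex`),
#'   `d1_energy`, `d2_energy`, `population_d1`, `population_d2`,
#'   `em_traces`, `seed`, `config`
#' @export
run_d1_em_d2 <- function(target_seq, mhc_donor, template,
                         config = docking_config(), seed = 1,
                         params = default_scoring_params()) {
  target_seq <- toupper(target_seq)
  if (nchar(target_seq) != peptide_length(template))
    stop("target length ", nchar(target_seq), " != template peptide length ",
         peptide_length(template),
         "; the template must present an epitope of the same length")
  al_d <- mhc_donor$provenance$allele
  al_t <- template$provenance$allele
  if (!is.null(al_d) && !is.null(al_t) && !identical(al_d, al_t))
    stop("MHC donor allele ", al_d, " != template allele ", al_t)
  # thread and relax the new side chains against the template backbone
  pep0 <- thread_sequence(target_seq, template$peptide)
  em1 <- minimize(pep0, nsteps = config$em_short,
                  fixed = backbone_atom_selection(pep0), params = params)
  pep_em <- em1$structure
  # D1 into the donor receptor
  pop1 <- sample_conformers(mhc_donor$mhc, pep_em, config, seed = seed,
                            seed_offset = 0, params = params)
  pop1 <- cluster_conformers(pop1)
  rep1 <- select_from_run_bests(pop1)
  pose1 <- population_pose(pop1, rep1)
  d1_energy <- pop1$conformers[[rep1]]$energy
  # long EM of the selected complex, backbones fixed
  merged <- new_structure("d1_complex", rbind(mhc_donor$mhc$atoms,
                                              pose1$atoms))
  fixed <- c(backbone_atom_selection(mhc_donor$mhc),
             backbone_atom_selection(pose1))
  em2 <- minimize(merged, nsteps = config$em_long, fixed = fixed,
                  params = params)
  nr <- nrow(mhc_donor$mhc$atoms)
  mhc_min <- subset_structure(em2$structure, seq_len(nr),
                              id = mhc_donor$mhc$id)
  pep_min <- subset_structure(em2$structure,
                              nr + seq_len(nrow(pose1$atoms)),
                              id = pose1$id)
  # D2: dock the relaxed partners again
  pop2 <- sample_conformers(mhc_min, pep_min, config, seed = seed,
                            seed_offset = config$n_runs + 1, params = params)
  pop2 <- cluster_conformers(pop2)
  rep2 <- select_from_run_bests(pop2)
  pose2 <- population_pose(pop2, rep2)
  d2_energy <- pop2$conformers[[rep2]]$energy
  final <- new_pmhc(
    mhc_min, pose2,
    provenance = list(
      target_seq = target_seq,
      template = template$provenance$source %||% template$mhc$id,
      donor = mhc_donor$provenance$source %||% mhc_donor$mhc$id,
      allele = al_d %||% al_t,
      seed = seed, stage = "D2", protocol = "D1-EM-D2"),
    energy = d2_energy)
  out <- list(complex = final, d1_energy = d1_energy,
              d2_energy = d2_energy, population_d1 = pop1,
              population_d2 = pop2,
              em_traces = list(thread = em1$trace, complex = em2$trace),
              seed = seed, config = config)
  class(out) <- "docking_result"
  out
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result> %s via template %s, donor %s (seed %d)\n",
              x$complex$provenance$target_seq,
              x$complex$provenance$template, x$complex$provenance$donor,
              x$seed))
  cat(sprintf("  D1 total %.3f -> D2 total %.3f\n",
              x$d1_energy$total, x$d2_energy$total))
  invisible(x)
}
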