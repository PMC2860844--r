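# Deterministic synthetic-structure generator: ideal-geometry peptides,
# toy MHC-like clefts (two walls over a floor, optional anchor pockets,
# mid-cleft bulge blockers and a planted hydrogen-bond donor), and noisy
# peptide populations for pattern extraction. These scaffolds exercise the
# geometry/occlusion/energetics contracts of the pipeline without any
# external structure files.

#' Evaluate an expression under a temporary RNG state
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Build a full heavy-atom peptide from ideal internal geometry
#'
#' Constructs the backbone by NeRF chain propagation from per-residue
#' phi/psi torsions (omega fixed at 180) and places side chains from the
#' packaged z-matrix at all-trans chi staples. Deterministic.
#'
#' @param seq one-letter peptide sequence (canonical residues)
#' @param phi,psi backbone torsions in degrees, recycled along the
#'   sequence; the default (-140, 135) is an extended beta conformation
#' @param chain chain identifier
#' @param id structure label
#' @return a `pmhc_structure`
#' @export
make_ideal_peptide <- function(seq, phi = -140, psi = 135, chain = "P",
                               id = paste0("ideal_", seq)) {
  codes <- strsplit(toupper(seq), "")[[1]]
  n <- length(codes)
  if (n < 1) stop("empty sequence")
  res3 <- aa_one2three(codes)   # errors on non-canonical codes
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  if (any(phi <= -180 | phi > 180 | psi <= -180 | psi > 180))
    stop("phi/psi must lie in (-180, 180]")
  bb <- BB_GEOM
  Npos <- CApos <- Cpos <- Opos <- vector("list", n)
  Npos[[1]] <- c(0, 0, 0)
  CApos[[1]] <- c(bb$n_ca, 0, 0)
  Cpos[[1]] <- place_atom(c(0, 1, 0), Npos[[1]], CApos[[1]],
                          bb$ca_c, bb$ang_n_ca_c, 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Npos[[i]] <- place_atom(Npos[[i - 1]], CApos[[i - 1]], Cpos[[i - 1]],
                              bb$c_n, bb$ang_ca_c_n, psi[i - 1])
      CApos[[i]] <- place_atom(CApos[[i - 1]], Cpos[[i - 1]], Npos[[i]],
                               bb$n_ca, bb$ang_c_n_ca, bb$omega)
      Cpos[[i]] <- place_atom(Cpos[[i - 1]], Npos[[i]], CApos[[i]],
                              bb$ca_c, bb$ang_n_ca_c, phi[i])
    }
    Opos[[i]] <- place_atom(Npos[[i]], CApos[[i]], Cpos[[i]],
                            bb$c_o, bb$ang_ca_c_o,
                            if (psi[i] + 180 > 180) psi[i] - 180 else psi[i] + 180)
  }
  rows <- list()
  for (i in seq_len(n)) {
    bbmat <- rbind(N = Npos[[i]], CA = CApos[[i]], C = Cpos[[i]],
                   O = Opos[[i]])
    bb_df <- data.frame(elety = rownames(bbmat),
                        element = c("N", "C", "C", "O"),
                        x = bbmat[, 1], y = bbmat[, 2], z = bbmat[, 3],
                        stringsAsFactors = FALSE)
    sc_df <- build_sidechain(res3[i],
                             list(N = Npos[[i]], CA = CApos[[i]],
                                  C = Cpos[[i]]))
    df <- rbind(bb_df, sc_df)
    df$record <- "ATOM"; df$resid <- res3[i]; df$chain <- chain
    df$resno <- i; df$icode <- ""; df$occ <- 1
    rows[[i]] <- df
  }
  atoms <- do.call(rbind, rows)
  new_structure(id, atoms[, c("record", "elety", "element", "resid",
                              "chain", "resno", "icode", "x", "y", "z",
                              "occ")])
}

# one pseudo-residue of the toy receptor: a GLY-like N/CA/C triplet lying
# along `axis` (unit vector), centred at `center`
pseudo_residue <- function(center, resno, chain = "A",
                           axis = c(1, 0, 0), resid = "GLY") {
  offs <- 1.3 * unit(axis)
  pos <- rbind(N = center - offs, CA = center, C = center + offs)
  data.frame(record = "ATOM", elety = rownames(pos),
             element = c("N", "C", "C"), resid = resid, chain = chain,
             resno = resno, icode = "",
             x = pos[, 1], y = pos[, 2], z = pos[, 3], occ = 1,
             stringsAsFactors = FALSE)
}

#' Build a synthetic MHC-like cleft around an ideal peptide
#'
#' The receptor is a rigid scaffold of GLY-like pseudo-residues: a floor
#' below the peptide and two parallel walls flanking it, emulating the
#' beta-sheet floor and alpha-helix walls of the class I groove. Options
#' plant anchor pockets (an occluding cage around a side chain), a pair of
#' mid-cleft bulge blockers over which the peptide must arc (the
#' Trp73/Trp147-like constriction), and a serine-like hydrogen-bond donor
#' adjacent to a chosen peptide position (numbered residue 73 of the
#' receptor chain).
#'
#' @param peptide_seq one-letter peptide sequence (8-12 canonical residues)
#' @param wall_spacing distance between the two wall planes (Angstrom)
#' @param pocket_positions integer peptide positions receiving an anchor
#'   pocket cage; the default plants the allele-like anchors at p5 and the
#'   C-terminal position (use `integer(0)` for a pocketless groove)
#' @param pocket_depth cage centre distance from CA along the side chain
#'   direction (Angstrom)
#' @param bulge_blockers logical; add mid-cleft blockers and arc the
#'   peptide over them
#' @param donor_position optional peptide position next to which a
#'   serine-like donor (residue 73) is planted
#' @param relax logical; settle the planted peptide into the scaffold's
#'   ground state (a generous fixed-seed conformer search plus local
#'   refinement), so the planted truth is self-consistent the way a
#'   crystal structure sits in the minimum of the true potential
#' @param id complex label
#' @return a `pmhc_complex` with provenance recording the generator settings
#' @export
make_toy_cleft <- function(peptide_seq, wall_spacing = 11,
                           pocket_positions = NULL, pocket_depth = 3,
                           bulge_blockers = FALSE, donor_position = NULL,
                           relax = TRUE, id = "toy_cleft") {
  wall_height <- 8
  if (is.null(pocket_positions))
    pocket_positions <- c(5L, nchar(peptide_seq))
  if (pocket_depth > wall_height)
    stop("pocket depth ", pocket_depth, " exceeds the wall height ",
         wall_height)
  pep <- make_ideal_peptide(peptide_seq, id = paste0(id, "_pep"))
  # orient the peptide along x (principal axis of its CA trace), centred
  ca_sel <- pep$atoms$elety == "CA"
  ca <- get_coords(pep, ca_sel)
  ctr <- colMeans(ca)
  pc <- svd(sweep(ca, 2, ctr))$v
  if (det(pc) < 0) pc[, 3] <- -pc[, 3]
  pep <- set_coords(pep, sweep(get_coords(pep), 2, ctr) %*% pc)
  xyz <- get_coords(pep)
  if (bulge_blockers) {
    # arc the mid-section (around p6-p8) upward, as over cleft blockers
    ca <- get_coords(pep, ca_sel)
    n <- nrow(ca)
    x0 <- mean(ca[pmin(n, 6:8), 1])
    bump <- 1.8 * exp(-((xyz[, 1] - x0)^2) / (2 * 3.5^2))
    xyz[, 3] <- xyz[, 3] + bump
    pep <- set_coords(pep, xyz)
  }
  res <- list()
  resno <- 100L
  add_res <- function(center, axis = c(1, 0, 0), resid = "GLY",
                      resno_force = NULL) {
    resno <<- resno + 1L
    res[[length(res) + 1L]] <<- pseudo_residue(
      center, resno_force %||% resno, axis = axis, resid = resid)
  }
  xr <- range(xyz[, 1]) + c(-4.5, 4.5)
  z_floor <- min(xyz[, 3]) - 3.6
  for (x in seq(xr[1], xr[2], by = 3.5)) {
    for (y in c(-3.5, 0, 3.5)) add_res(c(x, y, z_floor))
  }
  for (x in seq(xr[1], xr[2], by = 3.5)) {
    for (z in seq(z_floor + 3.5, z_floor + wall_height, by = 3.5)) {
      add_res(c(x, -wall_spacing / 2, z))
      add_res(c(x, wall_spacing / 2, z))
    }
  }
  # the class I groove is closed at both ends (A/F pockets): end columns
  for (xe in xr) {
    for (y in c(-2, 2)) {
      for (z in seq(z_floor + 3.5, z_floor + wall_height, by = 3.5)) {
        add_res(c(xe, y, z), axis = c(0, 1, 0))
      }
    }
  }
  # conserved terminal anchors: a carboxylate coordinating the charged
  # peptide N terminus and an ammonium donor coordinating the C-terminal
  # carboxylate, the toy analog of the conserved A/F-pocket hydrogen-bond
  # network that fixes the bound register
  pep_at <- pep$atoms
  n1 <- as.numeric(pep_at[pep_at$resno == 1 & pep_at$elety == "N",
                          c("x", "y", "z")][1, ])
  o_last <- as.numeric(pep_at[pep_at$resno == max(pep_at$resno) &
                                pep_at$elety == "O", c("x", "y", "z")][1, ])
  ctr_x <- mean(range(pep_at$x))
  d_n <- unit(c(sign(n1[1] - ctr_x), 0, 0.25))
  asp <- pseudo_residue(n1 + 2.9 * d_n + 1.5 * d_n, 90, resid = "ASP",
                        axis = c(0, 1, 0))
  base <- n1 + 2.9 * d_n
  asp <- rbind(asp, data.frame(
    record = "ATOM", elety = c("OD1", "OD2"), element = "O", resid = "ASP",
    chain = "A", resno = 90, icode = "",
    x = c(base[1], base[1]), y = c(base[2] - 1.1, base[2] + 1.1),
    z = c(base[3], base[3]), occ = 1, stringsAsFactors = FALSE))
  res[[length(res) + 1L]] <- asp
  d_c <- unit(c(sign(o_last[1] - ctr_x), 0, 0.25))
  nz <- o_last + 2.9 * d_c
  lys <- pseudo_residue(nz + 1.6 * d_c, 91, resid = "LYS",
                        axis = c(0, 1, 0))
  lys <- rbind(lys, data.frame(
    record = "ATOM", elety = "NZ", element = "N", resid = "LYS",
    chain = "A", resno = 91, icode = "",
    x = nz[1], y = nz[2], z = nz[3], occ = 1, stringsAsFactors = FALSE))
  res[[length(res) + 1L]] <- lys
  res_tab <- residue_table(pep)
  sidechain_dir <- function(p) {
    sel <- pep$atoms$resno == p
    at <- pep$atoms[sel, , drop = FALSE]
    ca <- as.numeric(at[at$elety == "CA", c("x", "y", "z")])
    sc <- at[!(at$elety %in% c("N", "CA", "C", "O")), , drop = FALSE]
    tip <- if (nrow(sc)) colMeans(as.matrix(sc[, c("x", "y", "z")])) else
      ca + c(0, 0, -1)   # glycine: point into the cleft
    list(ca = ca, u = unit(tip - ca))
  }
  for (p in pocket_positions) {
    if (p < 1 || p > nrow(res_tab)) stop("pocket position out of range: ", p)
    sd <- sidechain_dir(p)
    q <- sd$ca + pocket_depth * sd$u
    dirs <- golden_spiral_points(48)
    keep <- dirs %*% sd$u > -0.35   # cage open back toward the backbone
    dirs <- dirs[keep[, 1], , drop = FALSE]
    pep_xyz <- get_coords(pep)
    for (k in seq_len(nrow(dirs))) {
      d <- dirs[k, ]
      helper <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      axis <- unit(vcross(d, helper))
      center <- q + 5.2 * d
      triplet <- rbind(center - 1.3 * axis, center, center + 1.3 * axis)
      dmin <- min(sqrt(outer(rowSums(triplet^2), rowSums(pep_xyz^2), "+") -
                         2 * triplet %*% t(pep_xyz)))
      if (dmin < 3.3) next   # never carve into the peptide itself
      add_res(center, axis = axis)
    }
  }
  if (bulge_blockers) {
    ca <- get_coords(pep, ca_sel)
    n <- nrow(ca)
    x0 <- mean(ca[pmin(n, 6:8), 1])
    add_res(c(x0, -2.2, z_floor + 2.8))
    add_res(c(x0, 2.2, z_floor + 2.8))
  }
  mhc_pre <- new_structure(paste0(id, "_mhc"), do.call(rbind, res))
  if (relax) {
    # settle the peptide into the scaffold ground state: a generous
    # fixed-seed stochastic conformer search (the same machinery the
    # docking protocol uses), keeping the best refined pose found
    params <- default_scoring_params()
    scorer <- make_pose_scorer(mhc_pre, pep, params)
    ref <- refine_pose(scorer, pep$atoms, cycles = 2, rigid_range = 1.2)
    pep$atoms <- ref$atoms
    cfg <- docking_config(n_runs = 6, n_out_per_run = 1, n_iter = 150,
                          em_short = 1, em_long = 1)
    pop <- sample_conformers(mhc_pre, pep, cfg, seed = 20100426L)
    totals <- vapply(pop$conformers, function(cf) cf$energy$total,
                     numeric(1))
    best <- pop$conformers[[which.min(totals)]]
    if (best$energy$total < ref$energy$total) pep <- set_coords(pep, best$xyz)
  }
  if (!is.null(donor_position)) {
    p <- donor_position
    sel <- pep$atoms$resno == p & pep$atoms$elety == "O"
    if (!any(sel)) stop("no backbone O at donor_position ", p)
    a_pos <- as.numeric(pep$atoms[sel, c("x", "y", "z")][1, ])
    u <- c(0, 1, 0)                     # approach from the wall side
    og <- a_pos + 2.9 * u
    m <- c(0, 0, 1)
    w <- cos(deg2rad(160)) * (-u) + sin(deg2rad(160)) * m
    cb <- og + 1.43 * unit(w)
    don <- pseudo_residue(cb + c(0, 1.6, 0), 73, resid = "SER")
    don <- rbind(don, data.frame(
      record = "ATOM", elety = "OG", element = "O", resid = "SER",
      chain = "A", resno = 73, icode = "",
      x = og[1], y = og[2], z = og[3], occ = 1, stringsAsFactors = FALSE))
    # keep CB as the donor antecedent
    don$x[don$elety == "CA"] <- cb[1]
    don$y[don$elety == "CA"] <- cb[2]
    don$z[don$elety == "CA"] <- cb[3]
    res[[length(res) + 1L]] <- don
  }
  mhc <- new_structure(paste0(id, "_mhc"), do.call(rbind, res))
  new_pmhc(mhc, pep,
           provenance = list(
             fixture = "toy_cleft", peptide_seq = toupper(peptide_seq),
             wall_spacing = wall_spacing,
             pocket_positions = pocket_positions,
             pocket_depth = pocket_depth,
             bulge_blockers = bulge_blockers,
             donor_position = donor_position))
}

#' Noisy copies of a complex's peptide for pattern extraction
#'
#' Adds independent Gaussian noise (sd `noise_sigma` per coordinate) to
#' every peptide atom; the receptor is untouched. Deterministic per seed.
#'
#' @param base a `pmhc_complex`
#' @param n_copies number of copies (>= 1)
#' @param noise_sigma coordinate noise sd (Angstrom)
#' @param seed integer seed
#' @return list of `pmhc_complex` objects
#' @export
make_pattern_population <- function(base, n_copies, noise_sigma, seed = 1) {
  stopifnot(n_copies >= 1, noise_sigma >= 0)
  xyz <- get_coords(base$peptide)
  with_seed(seed, lapply(seq_len(n_copies), function(k) {
    noise <- matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                    nrow = nrow(xyz))
    out <- base
    out$peptide <- set_coords(base$peptide, xyz + noise)
    out$provenance$copy <- k
    out
  }))
}
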