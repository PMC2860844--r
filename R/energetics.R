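# Lightweight empirical potential for pose scoring and minimisation:
# 12-6 Lennard-Jones sterics, Coulomb electrostatics with a
# distance-dependent dielectric (eps = 4r), a 10-4 angular-weighted
# hydrogen-bond well between donor/acceptor heavy atoms, and a chi-staple
# torsion penalty. Scores are in arbitrary "score units"; the functional
# form is simple enough to verify against a brute-force pair enumeration.

#' Scoring parameters packaged with the tool
#'
#' Reads the packaged JSON parameter file: per-element Lennard-Jones
#' sigma/epsilon (Angstrom, score units), Coulomb constant, dielectric
#' model ("r4" for eps = 4r or "const"), hydrogen-bond well (depth, optimum
#' distance, evaluation cutoff), torsion and restraint force constants, and
#' the nonbonded cutoff (8 Angstrom, unsmoothed).
#'
#' @return a `scoring_params` list
#' @export
default_scoring_params <- function() {
  if (is.null(.pkg_cache$params)) {
    path <- system.file("extdata", "scoring_params.json",
                        package = "pmhcbuild", mustWork = TRUE)
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    class(p) <- "scoring_params"
    .pkg_cache$params <- p
  }
  .pkg_cache$params
}

lj_table_for <- function(elements, params) {
  i <- match(elements, params$lj$element)
  if (anyNA(i)) {
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  }
  list(sigma = params$lj$sigma[i], eps = params$lj$eps[i])
}

#' Coarse formal charges for a structure
#'
#' Assigns formal charges to charged side-chain groups (Lys +1 on NZ,
#' Arg +0.5 on NH1/NH2, Asp/Glu -0.5 on each carboxylate oxygen, His +0.05
#' on each ring nitrogen) and, optionally, +1 to each chain's N-terminal
#' nitrogen and -1 spread over the C-terminal carboxylate.
#'
#' @param structure a `pmhc_structure`
#' @param termini logical; charge the chain termini
#' @return numeric vector of per-atom charges (e)
#' @export
assign_charges <- function(structure, termini = TRUE) {
  atoms <- structure$atoms
  q <- numeric(nrow(atoms))
  rule <- function(resid, elety, val) {
    sel <- atoms$resid == resid & atoms$elety %in% elety
    q[sel] <<- q[sel] + val
  }
  rule("LYS", "NZ", 1)
  rule("ARG", c("NH1", "NH2"), 0.5)
  rule("ASP", c("OD1", "OD2"), -0.5)
  rule("GLU", c("OE1", "OE2"), -0.5)
  rule("HIS", c("ND1", "NE2"), 0.05)
  if (termini && nrow(atoms)) {
    for (ch in unique(atoms$chain)) {
      rows <- which(atoms$chain == ch)
      key <- residue_key(atoms)[rows]
      first_res <- rows[key == key[1]]
      last_res <- rows[key == key[length(key)]]
      nterm <- first_res[atoms$elety[first_res] == "N"]
      if (length(nterm)) q[nterm[1]] <- q[nterm[1]] + 1
      oxt <- last_res[atoms$elety[last_res] == "OXT"]
      oo <- last_res[atoms$elety[last_res] == "O"]
      if (length(oxt) && length(oo)) {
        q[oxt[1]] <- q[oxt[1]] - 0.5
        q[oo[1]] <- q[oo[1]] - 0.5
      } else if (length(oo)) {
        q[oo[1]] <- q[oo[1]] - 1
      }
    }
  }
  q
}

# Hydrogen-bond donor/acceptor typing on heavy atoms (crystal structures
# carry no hydrogens). Returns per-atom logical donor/acceptor flags and,
# for donors, the index of the antecedent heavy atom used for the
# C-donor-acceptor angle.
DONOR_ANTECEDENT <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  HIS = c(ND1 = "CG", NE2 = "CE1"),
  LYS = c(NZ = "CE"), ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  TRP = c(NE1 = "CD1")
)
SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2")
)

hbond_typing <- function(structure) {
  atoms <- structure$atoms
  n <- nrow(atoms)
  donor <- logical(n); acceptor <- logical(n)
  antecedent <- rep(NA_integer_, n)
  key <- residue_key(atoms)
  res_split <- split(seq_len(n), factor(key, levels = unique(key)))
  for (rows in res_split) {
    resid <- atoms$resid[rows[1]]
    ety <- atoms$elety[rows]
    # backbone
    bb_n <- rows[ety == "N"]
    if (length(bb_n) && resid != "PRO") {
      donor[bb_n] <- TRUE
      ca <- rows[ety == "CA"]
      antecedent[bb_n] <- if (length(ca)) ca[1] else NA_integer_
    }
    acceptor[rows[ety %in% c("O", "OXT")]] <- TRUE
    acc <- SIDECHAIN_ACCEPTORS[[resid]]
    if (!is.null(acc)) acceptor[rows[ety %in% acc]] <- TRUE
    don <- DONOR_ANTECEDENT[[resid]]
    if (!is.null(don)) {
      for (dn in names(don)) {
        di <- rows[ety == dn]
        if (!length(di)) next
        donor[di] <- TRUE
        ai <- rows[ety == don[[dn]]]
        antecedent[di] <- if (length(ai)) ai[1] else NA_integer_
      }
    }
  }
  # fallback antecedent: nearest heavy atom in the same residue
  need <- which(donor & is.na(antecedent))
  if (length(need)) {
    xyz <- get_coords(structure)
    for (di in need) {
      rows <- res_split[[match(key[di], unique(key))]]
      others <- setdiff(rows, di)
      if (!length(others)) { donor[di] <- FALSE; next }
      d2 <- rowSums((xyz[others, , drop = FALSE] -
                       matrix(xyz[di, ], length(others), 3, byrow = TRUE))^2)
      antecedent[di] <- others[which.min(d2)]
    }
  }
  list(donor = donor, acceptor = acceptor, antecedent = antecedent)
}

new_energy_breakdown <- function(steric = 0, hbond = 0, electrostatic = 0,
                                 torsion = 0, restraint = 0) {
  out <- list(steric = steric, hbond = hbond, electrostatic = electrostatic,
              torsion = torsion, restraint = restraint,
              total = steric + hbond + electrostatic + torsion + restraint)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy> total %.4f (steric %.4f, elec %.4f, hbond %.4f, torsion %.4f, restraint %.4f)\n",
    x$total, x$steric, x$electrostatic, x$hbond, x$torsion, x$restraint))
  invisible(x)
}

# --- pairwise terms (vectorised over pair vectors) -----------------------

lj_pair <- function(r, sigma, eps) {
  sr6 <- (sigma / r)^6
  e <- 4 * eps * (sr6^2 - sr6)
  dedr <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r
  list(e = e, dedr = dedr)
}

coulomb_pair <- function(r, qq, params) {
  k <- params$coulomb_k
  if (identical(params$dielectric, "const")) {
    e <- k * qq / (params$eps_const * r)
    dedr <- -e / r
  } else {                      # eps = 4r
    e <- k * qq / (4 * r^2)
    dedr <- -2 * e / r
  }
  list(e = e, dedr = dedr)
}

hbond_radial <- function(r, params) {
  x <- params$hbond$r0 / r
  e <- params$hbond$eps / 3 * (2 * x^10 - 5 * x^4)
  dedr <- params$hbond$eps / 3 * (-20 * x^10 + 20 * x^4) / r
  list(e = e, dedr = dedr)
}

# Candidate pairs (i from set_a, j from set_b) within `cut` of each other.
pairs_within <- function(xyz, set_a, set_b, cut) {
  if (!length(set_a) || !length(set_b)) {
    return(data.frame(i = integer(), j = integer(), r = numeric()))
  }
  A <- xyz[set_a, , drop = FALSE]
  B <- xyz[set_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- which(d2 <= cut^2, arr.ind = TRUE)
  data.frame(i = set_a[hit[, 1]], j = set_b[hit[, 2]],
             r = sqrt(pmax(d2[hit], 1e-12)))
}

# Nonbonded energy over an explicit pair list. `typing`/`charges`/`lj` are
# per-atom vectors for the merged coordinate set.
nonbonded_energy <- function(xyz, pairs, lj, charges, typing, params,
                             gradient = FALSE) {
  n <- nrow(xyz)
  g <- if (gradient) matrix(0, n, 3) else NULL
  if (!nrow(pairs)) {
    return(list(steric = 0, electrostatic = 0, hbond = 0, grad = g))
  }
  i <- pairs$i; j <- pairs$j; r <- pairs$r
  sig <- (lj$sigma[i] + lj$sigma[j]) / 2
  eps <- sqrt(lj$eps[i] * lj$eps[j])
  ljv <- lj_pair(r, sig, eps)
  qq <- charges[i] * charges[j]
  elv <- coulomb_pair(r, qq, params)
  elv$e[qq == 0] <- 0; elv$dedr[qq == 0] <- 0
  dedr <- ljv$dedr + elv$dedr
  e_st <- sum(ljv$e); e_el <- sum(elv$e)

  e_hb <- 0
  hb <- which((typing$donor[i] & typing$acceptor[j]) |
                (typing$donor[j] & typing$acceptor[i]))
  hb <- hb[r[hb] <= params$hbond$rcut]
  hb_terms <- NULL
  if (length(hb)) {
    # orient so that `d` is the donor, `a` the acceptor; pairs qualifying
    # in both directions contribute twice (symmetric O-H...O case)
    d1 <- hb[typing$donor[i[hb]] & typing$acceptor[j[hb]]]
    d2 <- hb[typing$donor[j[hb]] & typing$acceptor[i[hb]]]
    hd <- c(i[d1], j[d2]); ha <- c(j[d1], i[d2]); hr <- c(r[d1], r[d2])
    hc <- typing$antecedent[hd]
    ok <- !is.na(hc)
    hd <- hd[ok]; ha <- ha[ok]; hr <- hr[ok]; hc <- hc[ok]
    if (length(hd)) {
      u <- xyz[hc, , drop = FALSE] - xyz[hd, , drop = FALSE]
      v <- xyz[ha, , drop = FALSE] - xyz[hd, , drop = FALSE]
      nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
      ct <- rowSums(u * v) / (nu * nv)
      w <- pmax(0, -ct)^2          # 1 when C-D...A is linear, 0 below 90 deg
      rad <- hbond_radial(hr, params)
      e_hb <- sum(w * rad$e)
      hb_terms <- list(hd = hd, ha = ha, hc = hc, hr = hr, u = u, v = v,
                       nu = nu, nv = nv, ct = ct, w = w, rad = rad)
    }
  }

  if (gradient) {
    d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    f <- dedr / r
    contrib <- f * d
    idx <- c(i, j)
    vals <- rbind(contrib, -contrib)
    acc <- rowsum(vals, group = idx)
    rows <- as.integer(rownames(acc))
    g[rows, ] <- g[rows, ] + acc
    if (!is.null(hb_terms)) {
      ht <- hb_terms
      # radial part: dE = w * rad$dedr along the donor-acceptor axis
      fr <- (ht$w * ht$rad$dedr) / ht$hr
      cr <- fr * (-ht$v)                   # gradient on the donor side
      # angular part: dE = rad$e * dw/dcos * dcos/dx with w = max(0,-ct)^2
      dwdc <- ifelse(ht$ct < 0, 2 * ht$ct, 0)
      fa <- ht$rad$e * dwdc
      dcd_c <- (ht$v / (ht$nu * ht$nv)) - ht$ct * ht$u / ht$nu^2
      dcd_a <- (ht$u / (ht$nu * ht$nv)) - ht$ct * ht$v / ht$nv^2
      dcd_d <- -(dcd_c + dcd_a)
      vals2 <- rbind(cr + fa * dcd_d, -cr + fa * dcd_a, fa * dcd_c)
      idx2 <- c(ht$hd, ht$ha, ht$hc)
      acc2 <- rowsum(vals2, group = idx2)
      rows2 <- as.integer(rownames(acc2))
      g[rows2, ] <- g[rows2, ] + acc2
    }
  }
  list(steric = e_st, electrostatic = e_el, hbond = e_hb, grad = g)
}

# --- torsion staple term -------------------------------------------------

# List of chi torsions (atom index quadruples + multiplicity/phase) for the
# canonical residues of a structure, restricted to `residue_sel` rows of
# residue_table if given.
chi_torsion_list <- function(structure) {
  atoms <- structure$atoms
  key <- residue_key(atoms)
  res_split <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  out <- list()
  for (rows in res_split) {
    resid <- atoms$resid[rows[1]]
    if (!is_canonical_aa(resid) || resid == "PRO") next
    quads <- chi_atoms(resid)
    for (k in seq_along(quads)) {
      idx <- rows[match(quads[[k]], atoms$elety[rows])]
      if (anyNA(idx)) next
      aromatic_flip <- k == 2 && resid %in% c("PHE", "TYR", "TRP", "HIS")
      out[[length(out) + 1L]] <- list(
        idx = idx,
        mult = if (aromatic_flip) 2 else 3,
        phase = if (aromatic_flip) 180 else 0)
    }
  }
  out
}

# E = k * (1 + cos(mult * chi - phase)); analytic gradient via the standard
# four-point dihedral derivative.
torsion_energy <- function(xyz, torsions, k, gradient = FALSE) {
  n <- nrow(xyz)
  g <- if (gradient) matrix(0, n, 3) else NULL
  e <- 0
  for (tor in torsions) {
    p <- xyz[tor$idx, , drop = FALSE]
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
    nb2 <- vnorm(b2)
    if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) next
    m1 <- vcross(n1, b2 / nb2)
    chi <- atan2(sum(m1 * n2), sum(n1 * n2))
    arg <- tor$mult * chi - deg2rad(tor$phase)
    e <- e + k * (1 + cos(arg))
    if (gradient) {
      dEdchi <- -k * tor$mult * sin(arg)
      dphi1 <- nb2 / sum(n1 * n1) * n1
      dphi4 <- -nb2 / sum(n2 * n2) * n2
      c12 <- sum(b1 * b2) / nb2^2
      c32 <- sum(b3 * b2) / nb2^2
      dphi2 <- (-1 - c12) * dphi1 + c32 * dphi4
      dphi3 <- c12 * dphi1 + (-1 - c32) * dphi4
      g[tor$idx[1], ] <- g[tor$idx[1], ] + dEdchi * dphi1
      g[tor$idx[2], ] <- g[tor$idx[2], ] + dEdchi * dphi2
      g[tor$idx[3], ] <- g[tor$idx[3], ] + dEdchi * dphi3
      g[tor$idx[4], ] <- g[tor$idx[4], ] + dEdchi * dphi4
    }
  }
  list(e = e, grad = g)
}

# --- bond graph and exclusions -------------------------------------------

#' Heavy-atom bond list of a structure
#'
#' Canonical residues use the packaged topology (including ring closures
#' and the peptide C-N link between consecutive residues of a chain, joined
#' only when the C-N distance is bondable); other residues are bonded by a
#' 1.9 Angstrom distance heuristic.
#'
#' @param structure a `pmhc_structure`
#' @return two-column integer matrix of atom index pairs
#' @export
bond_graph <- function(structure) {
  atoms <- structure$atoms
  xyz <- get_coords(structure)
  key <- residue_key(atoms)
  ukey <- unique(key)
  res_split <- split(seq_len(nrow(atoms)), factor(key, levels = ukey))
  bonds <- list()
  add <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)
  for (rows in res_split) {
    resid <- atoms$resid[rows[1]]
    ety <- atoms$elety[rows]
    if (is_canonical_aa(resid)) {
      for (b in residue_bonds(resid)) {
        i <- rows[match(b[1], ety)]; j <- rows[match(b[2], ety)]
        if (!is.na(i) && !is.na(j)) add(i, j)
      }
      # extra atoms not covered by the ideal topology (e.g. OXT)
      covered <- unique(unlist(residue_bonds(resid)))
      extra <- rows[!(ety %in% covered)]
      for (i in extra) {
        d2 <- rowSums((xyz[rows, , drop = FALSE] -
                         matrix(xyz[i, ], length(rows), 3, byrow = TRUE))^2)
        d2[rows == i] <- Inf
        j <- rows[which.min(d2)]
        if (min(d2) < 1.9^2) add(i, j)
      }
    } else {
      if (length(rows) > 1) {
        pr <- pairs_within(xyz, rows, rows, 1.9)
        pr <- pr[pr$i < pr$j, , drop = FALSE]
        for (q in seq_len(nrow(pr))) add(pr$i[q], pr$j[q])
      }
    }
  }
  # peptide bonds between consecutive residues of the same chain
  for (k in seq_len(length(res_split) - 1)) {
    a <- res_split[[k]]; b <- res_split[[k + 1]]
    if (atoms$chain[a[1]] != atoms$chain[b[1]]) next
    ci <- a[match("C", atoms$elety[a])]
    ni <- b[match("N", atoms$elety[b])]
    if (!is.na(ci) && !is.na(ni) &&
        sum((xyz[ci, ] - xyz[ni, ])^2) < 2.0^2) add(ci, ni)
  }
  if (!length(bonds)) return(matrix(integer(), 0, 2))
  do.call(rbind, bonds)
}

# Set of excluded pairs (graph distance <= 2) as a character key "i|j", i<j.
exclusion_keys <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  keys <- character(0)
  pk <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")
  for (k in seq_len(nrow(bonds))) keys <- c(keys, pk(bonds[k, 1], bonds[k, 2]))
  for (i in seq_len(n)) {
    nb <- unique(adj[[i]])
    if (length(nb) > 1) {
      cmb <- utils::combn(nb, 2)
      keys <- c(keys, pk(cmb[1, ], cmb[2, ]))
    }
  }
  unique(keys)
}

#' Interaction energy between a receptor and a peptide pose
#'
#' Pairwise-additive intermolecular energy over all receptor/peptide atom
#' pairs within the cutoff: Lennard-Jones sterics, Coulomb electrostatics
#' on coarse formal charges, and the angular-weighted hydrogen-bond well.
#' Deterministic; no intramolecular terms.
#'
#' @param receptor,peptide `pmhc_structure` objects with no shared atoms
#' @param params scoring parameters (default: packaged set)
#' @return an `energy_breakdown`
#' @export
score_pose <- function(receptor, peptide, params = default_scoring_params()) {
  merged <- new_structure("scored", rbind(receptor$atoms, peptide$atoms))
  xyz <- get_coords(merged)
  nr <- nrow(receptor$atoms)
  lj <- lj_table_for(merged$atoms$element, params)
  charges <- c(assign_charges(receptor), assign_charges(peptide))
  typing <- hbond_typing(merged)
  pairs <- pairs_within(xyz, seq_len(nr), nr + seq_len(nrow(peptide$atoms)),
                        params$cutoff)
  nb <- nonbonded_energy(xyz, pairs, lj, charges, typing, params)
  new_energy_breakdown(steric = nb$steric, hbond = nb$hbond,
                       electrostatic = nb$electrostatic)
}

#' Intramolecular energy of a structure
#'
#' Nonbonded terms over intra-structure atom pairs within the cutoff,
#' excluding 1-2 and 1-3 bonded pairs, plus the chi-staple torsion penalty
#' and (optionally) harmonic distance restraints toward a reference
#' geometry over bonded and 1-3 pairs.
#'
#' @param structure a `pmhc_structure`
#' @param params scoring parameters
#' @param restraint_ref optional `pmhc_structure` with identical atoms whose
#'   bonded/1-3 distances serve as restraint targets
#' @return an `energy_breakdown`
#' @export
internal_energy <- function(structure, params = default_scoring_params(),
                            restraint_ref = NULL) {
  sys <- prepare_system(structure, params, restraint_ref = restraint_ref)
  ev <- system_energy(sys, get_coords(structure), gradient = FALSE,
                      truncate = TRUE)
  ev$energy
}
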