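# The empirical potential: brute-force verification, invariances, and
# analytic gradients.

# independent brute-force oracle: naive double loop over every atom pair,
# recomputing each term from the published functional forms
brute_force_score <- function(receptor, peptide,
                              params = default_scoring_params()) {
  merged <- pmhcbuild:::new_structure("bf", rbind(receptor$atoms,
                                                  peptide$atoms))
  xyz <- get_coords(merged)
  nr <- nrow(receptor$atoms)
  lj <- pmhcbuild:::lj_table_for(merged$atoms$element, params)
  q <- c(assign_charges(receptor), assign_charges(peptide))
  typing <- pmhcbuild:::hbond_typing(merged)
  e_st <- e_el <- e_hb <- 0
  for (i in seq_len(nr)) {
    for (j in (nr + 1):nrow(xyz)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > params$cutoff) next
      sig <- (lj$sigma[i] + lj$sigma[j]) / 2
      eps <- sqrt(lj$eps[i] * lj$eps[j])
      e_st <- e_st + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      e_el <- e_el + params$coulomb_k * q[i] * q[j] / (4 * r^2)
      for (dir in list(c(i, j), c(j, i))) {
        d <- dir[1]; a <- dir[2]
        if (!typing$donor[d] || !typing$acceptor[a]) next
        if (r > params$hbond$rcut) next
        ante <- typing$antecedent[d]
        if (is.na(ante)) next
        u <- xyz[ante, ] - xyz[d, ]
        v <- xyz[a, ] - xyz[d, ]
        ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
        w <- max(0, -ct)^2
        x <- params$hbond$r0 / r
        e_hb <- e_hb + w * params$hbond$eps / 3 * (2 * x^10 - 5 * x^4)
      }
    }
  }
  list(steric = e_st, electrostatic = e_el, hbond = e_hb)
}

test_that("pose scoring equals the brute-force pair enumeration", {
  cpx <- toy_deep_p5()
  fast <- score_pose(cpx$mhc, cpx$peptide)
  slow <- brute_force_score(cpx$mhc, cpx$peptide)
  expect_equal(fast$steric, slow$steric, tolerance = 1e-9)
  expect_equal(fast$electrostatic, slow$electrostatic, tolerance = 1e-9)
  expect_equal(fast$hbond, slow$hbond, tolerance = 1e-9)
  expect_equal(fast$total, fast$steric + fast$hbond + fast$electrostatic +
                 fast$torsion + fast$restraint, tolerance = 1e-9)
})

test_that("a peptide translated far beyond the cutoff scores exactly zero", {
  cpx <- toy_complex()
  far <- set_coords(cpx$peptide,
                    sweep(get_coords(cpx$peptide), 2, c(500, 0, 0), "+"))
  e <- score_pose(cpx$mhc, far)
  expect_identical(e$total, 0)
  expect_identical(e$steric, 0)
  expect_identical(e$hbond, 0)
  expect_identical(e$electrostatic, 0)
})

test_that("an interatomic clash is dominated by the repulsive wall", {
  a <- structure_of(atom_row("C1", 0, 0, 0))
  b <- structure_of(atom_row("C1", 0.5, 0, 0))
  b$atoms$chain <- "B"
  e <- score_pose(a, b)
  expect_gt(e$steric, 1e4)
  expect_gt(e$total, 1e4)
})

test_that("scoring is symmetric and invariant under joint rigid motion", {
  cpx <- toy_complex()
  e_ab <- score_pose(cpx$mhc, cpx$peptide)
  e_ba <- score_pose(cpx$peptide, cpx$mhc)
  expect_equal(e_ab$total, e_ba$total, tolerance = 1e-9)
  fit <- list(rotation = rotation_about_axis(c(2, 1, 5), 33),
              translation = c(7, -3, 11))
  moved <- apply_transform(cpx, fit)
  e_mv <- score_pose(moved$mhc, moved$peptide)
  for (term in c("steric", "electrostatic", "hbond", "total")) {
    expect_equal(e_mv[[term]], e_ab[[term]], tolerance = 1e-9)
  }
})

test_that("the steric term decreases with distance below the LJ minimum", {
  sig <- default_scoring_params()$lj$sigma[1]
  rs <- seq(2.0, 2^(1 / 6) * sig - 0.05, length.out = 12)
  es <- vapply(rs, function(r) {
    a <- structure_of(atom_row("C1", 0, 0, 0))
    b <- structure_of(atom_row("C1", r, 0, 0))
    b$atoms$chain <- "B"
    score_pose(a, b)$steric
  }, numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("unknown elements are reported by name", {
  a <- structure_of(atom_row("XX", 0, 0, 0, element = "X"))
  b <- structure_of(atom_row("C1", 3, 0, 0))
  b$atoms$chain <- "B"
  expect_error(score_pose(a, b), "X")
})

test_that("internal energy: single atom is zero, runs are reproducible", {
  one <- structure_of(atom_row("C1", 0, 0, 0))
  expect_equal(internal_energy(one)$total, 0)
  pep <- make_ideal_peptide("NK")
  e1 <- internal_energy(pep)
  e2 <- internal_energy(pep)
  expect_identical(e1$total, e2$total)
  expect_true(is.finite(e1$total))
  expect_equal(e1$total, e1$steric + e1$hbond + e1$electrostatic +
                 e1$torsion + e1$restraint, tolerance = 1e-12)
})

test_that("internal energy excludes 1-2 and 1-3 pairs", {
  # a three-atom bonded chain at short distances contributes nothing
  s <- structure_of(atom_row("N", 0, 0, 0, element = "N"),
                    atom_row("CA", 1.458, 0, 0, element = "C"),
                    atom_row("C", 2.0, 1.4, 0, element = "C"))
  s$atoms$resid <- "GLY"
  expect_equal(internal_energy(s)$steric, 0)
})

test_that("the analytic gradient matches numeric differentiation", {
  pep <- make_ideal_peptide("SNKF")
  sys <- pmhcbuild:::prepare_system(pep, restraint_ref = pep)
  xyz <- get_coords(pep) +
    with_seed(5, matrix(stats::rnorm(3 * nrow(pep$atoms), sd = 0.05),
                        ncol = 3))
  ev <- pmhcbuild:::system_energy(sys, xyz, gradient = TRUE)
  h <- 1e-6
  idx <- with_seed(6, sample(nrow(xyz), 8))
  for (i in idx) {
    for (d in 1:3) {
      xp <- xyz; xp[i, d] <- xp[i, d] + h
      xm <- xyz; xm[i, d] <- xm[i, d] - h
      num <- (pmhcbuild:::system_energy(sys, xp)$energy$total -
                pmhcbuild:::system_energy(sys, xm)$energy$total) / (2 * h)
      expect_equal(ev$grad[i, d], num, tolerance = 1e-4)
    }
  }
})

test_that("coarse formal charges sum to the expected net charge", {
  pep <- make_ideal_peptide("KDEAR")
  q <- assign_charges(pep)
  # +1 Lys, -1 Asp, -1 Glu, +1 Arg, +1 N-term, -1 C-term
  expect_equal(sum(q), 0)
  expect_equal(sum(q[pep$atoms$elety == "NZ"]), 1)
  expect_equal(sum(q[pep$atoms$resid == "ASP" &
                       grepl("^OD", pep$atoms$elety)]), -1)
  q0 <- assign_charges(pep, termini = FALSE)
  expect_equal(sum(q0), 0)  # K + R - D - E
  expect_equal(sum(assign_charges(make_ideal_peptide("AAAA"),
                                  termini = FALSE)), 0)
})
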