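# Shrake-Rupley ASA, per-position signatures, and TCR-face surface maps.

test_that("an isolated carbon atom matches the analytic sphere area", {
  s <- structure_of(atom_row("C1", 0, 0, 0))
  asa <- shrake_rupley(s, probe = 1.4, n_points = 960)
  expect_equal(asa, 4 * pi * 3.1^2, tolerance = 0.01)
  # point-count refinement changes the analytic case by well under 0.5%
  asa4k <- shrake_rupley(s, probe = 1.4, n_points = 4000)
  expect_lt(abs(asa4k - asa) / asa, 0.005)
})

test_that("an atom fully enclosed by a neighbour shell has zero area", {
  shell <- golden_spiral_points(60) * 2.5
  rows <- lapply(seq_len(60), function(i)
    atom_row("C1", shell[i, 1], shell[i, 2], shell[i, 3],
             resno = i + 1L))
  s <- structure_of(atom_row("C1", 0, 0, 0), do.call(rbind, rows))
  expect_equal(shrake_rupley(s, n_points = 480)[1], 0)
})

test_that("two-sphere overlap matches the analytic oracle across a sweep", {
  R_C <- 1.7 + 1.4
  R_O <- 1.52 + 1.4
  for (d in c(1.5, 2.2, 3.0, 4.5, 5.5)) {
    s <- structure_of(atom_row("C1", 0, 0, 0),
                      atom_row("O1", d, 0, 0, element = "O", resno = 2L))
    asa <- shrake_rupley(s, n_points = 960)
    truth <- two_sphere_exposed(R_C, R_O, d)
    expect_equal(asa[1], truth[1], tolerance = 0.01)
    expect_equal(asa[2], truth[2], tolerance = 0.01)
  }
})

test_that("ASA is invariant under rigid motion within sampling tolerance", {
  pep <- make_ideal_peptide("NKFA")
  base <- shrake_rupley(pep, n_points = 960)
  fit <- list(rotation = rotation_about_axis(c(3, 1, 2), 51),
              translation = c(4, -7, 2))
  moved <- set_coords(pep, apply_transform(get_coords(pep), fit))
  expect_equal(shrake_rupley(moved, n_points = 960), base,
               tolerance = 0.02)
})

test_that("unknown elements are rejected by name", {
  s <- structure_of(atom_row("Q1", 0, 0, 0, element = "Q"))
  expect_error(shrake_rupley(s), "Q")
})

test_that("identical complexes give identical signatures; occlusion only removes area", {
  cpx <- toy_complex()
  s1 <- asa_signature(cpx, n_points = 480)
  s2 <- asa_signature(cpx, n_points = 480)
  expect_identical(s1$values, s2$values)
  free <- asa_signature(cpx, n_points = 480, free = TRUE)
  expect_true(all(free$values >= s1$values - 1e-9))
})

test_that("an alanine substitution shrinks the ASA at an exposed position", {
  cpx <- toy_complex()   # p6 = TYR, exposed on the TCR face
  sub <- cpx
  sub$peptide <- thread_sequence("FAPGNAPAL", cpx$peptide)
  a_nat <- asa_signature(cpx, n_points = 480)
  a_sub <- asa_signature(sub, n_points = 480)
  expect_lt(a_sub$values[6], a_nat$values[6])
})

test_that("signature comparison follows its arithmetic", {
  a <- list(values = c(p1 = 10, p2 = 20, p3 = 30))
  b <- list(values = c(p1 = 10, p2 = 26, p3 = 30))
  cmp <- compare_signatures(a, b)
  expect_equal(cmp$rms_delta, 6 / sqrt(3), tolerance = 1e-12)
  expect_equal(cmp$max_delta_position, 2L)
  expect_equal(compare_signatures(b, a)$rms_delta, cmp$rms_delta)
  expect_equal(compare_signatures(a, a)$rms_delta, 0)
  expect_error(compare_signatures(a, list(values = c(1, 2))), "length")
})

test_that("the Coulomb potential matches its closed forms and clips at ten", {
  p <- matrix(c(7, 0, 0), 1, 3)
  src <- matrix(0, 1, 3)
  expect_equal(coulomb_potential(p, src, 1, dielectric = "const",
                                 eps_const = 80),
               332.06 / (80 * 7) / 0.593, tolerance = 1e-9)
  expect_equal(coulomb_potential(matrix(c(2, 0, 0), 1, 3), src, 1),
               332.06 / (4 * 4) / 0.593, tolerance = 1e-9)
  # raw values beyond the display scale are clipped to +/-10
  raw <- coulomb_potential(matrix(c(1.2, 0, 0), 1, 3), src, 1)
  expect_gt(raw, 10)
  expect_equal(min(10, raw), 10)
})

test_that("an all-neutral complex has an identically zero potential map", {
  cpx <- make_toy_cleft("AAGAAGAAG", relax = FALSE)
  # strip the receptor's charged terminal anchors; with uncharged termini
  # the polyalanine/glycine system carries no charge at all
  neutral <- cpx
  sel <- neutral$mhc$atoms$resid %in% c("ASP", "LYS")
  neutral$mhc$atoms$resid[sel] <- "GLY"
  m0 <- surface_potential(neutral, n_points = 180, termini = FALSE)
  expect_true(all(m0$values == 0))
  # the same complex with charged termini is not flat
  m1 <- surface_potential(cpx, n_points = 180)
  expect_true(any(m1$values != 0))
})

test_that("map values respect the clipping bound and heights the plane", {
  cpx <- toy_complex()
  m <- surface_potential(cpx, n_points = 180)
  expect_true(all(abs(m$values) <= 10))
  expect_equal(nrow(m$points), length(m$values))
  expect_equal(nrow(m$points), length(m$heights))
  # TCR-face points sit mostly above the cleft plane
  expect_gt(mean(m$heights > 0), 0.8)
})

test_that("surface comparison: identity, symmetry and a planted potential change", {
  cpx <- toy_complex()
  m1 <- surface_potential(cpx, n_points = 180)
  self <- compare_surfaces(m1, m1)
  expect_equal(self$topology_rms, 0)
  expect_equal(self$potential_rms, 0)
  expect_equal(self$matched_fraction, 1)
  # same geometry, planted potential difference: topology silent, charge loud
  m2 <- m1
  m2$values <- pmax(-10, pmin(10, m1$values + 2))
  cmp <- compare_surfaces(m1, m2)
  expect_equal(cmp$topology_rms, 0)
  expect_gt(cmp$potential_rms, 1)
  # near-symmetry under swapping
  cpx2 <- make_toy_cleft("FAPSNYPAL", id = "toy_s4")
  fitted <- fit_by_mhc_ca(cpx2, cpx)$model
  ma <- surface_potential(cpx, n_points = 180)
  mb <- surface_potential(fitted, n_points = 180)
  ab <- compare_surfaces(ma, mb)
  ba <- compare_surfaces(mb, ma)
  expect_equal(ab$topology_rms, ba$topology_rms, tolerance = 0.35)
  expect_equal(ab$potential_rms, ba$potential_rms, tolerance = 0.6)
  expect_error(compare_surfaces(m1, list(points = m1$points + 1e3,
                                         values = m1$values,
                                         heights = m1$heights)),
               "no matched")
})
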