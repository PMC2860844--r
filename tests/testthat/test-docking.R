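# Conformer sampling, frequency-first representative selection, and the
# D1-EM-D2 protocol contracts.

fake_population <- function(energies, centers) {
  conformers <- lapply(seq_along(energies), function(i) {
    list(xyz = matrix(centers[i], 4, 3), energy = list(total = energies[i]))
  })
  pop <- list(conformers = conformers, template = NULL, clusters = NULL,
              representative = NA_integer_, config = docking_config())
  class(pop) <- "conformer_population"
  pop
}

test_that("frequency beats energy: the most populous cluster wins", {
  # 8 poses near 0 (worst energies), 2 poses near 100 holding the global
  # best energy
  energies <- c(-1, -2, -3, -1.5, -2.5, -1.2, -2.2, -3.2, -50, -49)
  centers <- c(rep(0, 8) + seq(0, 0.07, length.out = 8), 100, 100.05)
  pop <- cluster_conformers(fake_population(energies, centers),
                            cluster_rmsd = 1)
  expect_equal(length(pop$clusters), 2L)
  expect_true(pop$representative %in% 1:8)
  expect_equal(pop$representative, 8L)   # lowest energy inside the big cluster
  # energy-first switch picks the global best instead
  pop_e <- cluster_conformers(fake_population(energies, centers),
                              cluster_rmsd = 1, selection = "energy")
  expect_equal(pop_e$representative, 9L)
})

test_that("a single conformer represents itself", {
  pop <- cluster_conformers(fake_population(-5, 0), cluster_rmsd = 1)
  expect_equal(pop$representative, 1L)
})

test_that("equal-size clusters tie-break to the lower-energy cluster", {
  energies <- c(-1, -2, -9, -3)
  centers <- c(0, 0.05, 50, 50.05)
  pop <- cluster_conformers(fake_population(energies, centers),
                            cluster_rmsd = 1)
  expect_equal(pop$representative, 3L)
})

test_that("a zero-amplitude sampler with fixed side chains degenerates", {
  cpx <- toy_complex()
  cfg <- docking_config(n_runs = 2, n_out_per_run = 4, n_iter = 5,
                        trans_amp = 0, rot_amp = 0, resample_chi = FALSE,
                        em_short = 1, em_long = 1)
  pop <- sample_conformers(cpx$mhc, cpx$peptide, cfg, seed = 3)
  ref <- pop$conformers[[1]]
  for (cf in pop$conformers) {
    expect_equal(rmsd_between(cf$xyz, ref$xyz), 0, tolerance = 1e-9)
    expect_equal(cf$energy$total, ref$energy$total, tolerance = 1e-9)
  }
})

test_that("sampling is bit-reproducible for a fixed seed", {
  cpx <- toy_complex()
  cfg <- docking_config(n_runs = 2, n_out_per_run = 3, n_iter = 10,
                        em_short = 1, em_long = 1)
  p1 <- sample_conformers(cpx$mhc, cpx$peptide, cfg, seed = 11)
  p2 <- sample_conformers(cpx$mhc, cpx$peptide, cfg, seed = 11)
  for (i in seq_along(p1$conformers)) {
    expect_identical(p1$conformers[[i]]$xyz, p2$conformers[[i]]$xyz)
  }
  p3 <- sample_conformers(cpx$mhc, cpx$peptide, cfg, seed = 12)
  expect_false(identical(lapply(p1$conformers, `[[`, "xyz"),
                         lapply(p3$conformers, `[[`, "xyz")))
})

test_that("sampling preserves the peptide backbone internal geometry", {
  cpx <- toy_complex()
  cfg <- docking_config(n_runs = 1, n_out_per_run = 3, n_iter = 10,
                        em_short = 1, em_long = 1)
  pop <- sample_conformers(cpx$mhc, cpx$peptide, cfg, seed = 2)
  bb <- which(pmhcbuild:::backbone_atom_selection(cpx$peptide))
  ref <- get_coords(cpx$peptide)[bb, ]
  ref_d <- as.matrix(dist(ref))
  for (cf in pop$conformers[1:3]) {
    expect_equal(as.matrix(dist(cf$xyz[bb, ])), ref_d, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("the full protocol is deterministic and leaves the receptor rigid", {
  cpx <- toy_complex()
  cfg <- docking_config(n_runs = 2, n_out_per_run = 5, n_iter = 15,
                        em_short = 10, em_long = 20)
  r1 <- run_d1_em_d2("FAPSNYPAL", cpx, cpx, config = cfg, seed = 4)
  r2 <- run_d1_em_d2("FAPSNYPAL", cpx, cpx, config = cfg, seed = 4)
  expect_identical(get_coords(r1$complex$peptide),
                   get_coords(r2$complex$peptide))
  expect_identical(r1$d2_energy$total, r2$d2_energy$total)
  # docking never touches the receptor; only the complex relaxation may
  # adjust receptor side chains (here the terminal-anchor OD/NZ atoms), so
  # every receptor backbone atom must match the donor exactly
  bb <- r1$complex$mhc$atoms$elety %in% c("N", "CA", "C", "O")
  expect_identical(get_coords(r1$complex$mhc)[bb, ],
                   get_coords(cpx$mhc)[bb, ])
})

test_that("peptide backbone bonds drift less than 0.05 A through D1-EM-D2", {
  cpx <- toy_complex()
  cfg <- docking_config(n_runs = 2, n_out_per_run = 5, n_iter = 15,
                        em_short = 10, em_long = 20)
  res <- run_d1_em_d2("FAPSNYPAL", cpx, cpx, config = cfg, seed = 4)
  tpl <- cpx$peptide
  out <- res$complex$peptide
  bb_t <- get_coords(tpl, tpl$atoms$elety %in% c("N", "CA", "C", "O"))
  bb_o <- get_coords(out, out$atoms$elety %in% c("N", "CA", "C", "O"))
  d_t <- as.matrix(dist(bb_t)); d_o <- as.matrix(dist(bb_o))
  near <- d_t < 2.0 & d_t > 0
  expect_lt(max(abs(d_o[near] - d_t[near])), 0.05)
})

test_that("protocol input validation refuses bad targets", {
  cpx <- toy_complex()
  expect_error(run_d1_em_d2("FAPGNYPA", cpx, cpx), "length")
  expect_error(run_d1_em_d2("FAPGNYPAB", cpx, cpx,
                            config = test_config()), "non-canonical")
  donor <- cpx; donor$provenance$allele <- "H-2Db"
  tmpl <- cpx; tmpl$provenance$allele <- "H-2Kb"
  expect_error(run_d1_em_d2("FAPGNYPAL", donor, tmpl), "allele")
})

test_that("provenance records template, donor and seed", {
  cpx <- toy_complex()
  cfg <- docking_config(n_runs = 1, n_out_per_run = 2, n_iter = 5,
                        em_short = 2, em_long = 2)
  res <- run_d1_em_d2("FAPGNYPAL", cpx, cpx, config = cfg, seed = 99)
  pv <- res$complex$provenance
  expect_equal(pv$seed, 99)
  expect_equal(pv$target_seq, "FAPGNYPAL")
  expect_true(nzchar(pv$template))
  expect_true(nzchar(pv$donor))
})
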