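# Backbone pattern extraction, deviation flagging, anchor composition,
# burial classification and conserved-contact reporting.

test_that("identical copies give zero dispersion and the input backbone", {
  cpx <- toy_complex()
  members <- make_pattern_population(cpx, 5, 0, seed = 1)
  pat <- extract_pattern(members, allele = "toy")
  expect_true(all(pat$dispersion < 1e-9))
  ref_bb <- pmhcbuild:::backbone_array(cpx$peptide)
  expect_equal(pat$mean_coords, ref_bb, tolerance = 1e-9)
})

test_that("a single complex is its own pattern", {
  cpx <- toy_complex()
  pat <- extract_pattern(list(cpx), allele = "toy")
  expect_equal(length(pat$members), 1L)
  expect_true(all(pat$dispersion == 0))
  dev <- deviation_from_pattern(pat, cpx)
  expect_equal(dev$overall_backbone_rmsd, 0, tolerance = 1e-9)
})

test_that("Gaussian-noise populations show the chi-distribution dispersion", {
  cpx <- toy_complex()
  members <- make_pattern_population(cpx, 400, 0.3, seed = 11)
  pat <- extract_pattern(members, allele = "toy")
  expect_equal(mean(pat$dispersion), 0.3 * sqrt(3), tolerance = 0.04)
})

test_that("pattern extraction is permutation-invariant given a fixed frame", {
  cpx <- toy_complex()
  members <- make_pattern_population(cpx, 6, 0.2, seed = 4)
  pat_a <- extract_pattern(members, allele = "toy", frame = 1)
  perm <- members[c(3, 1, 6, 2, 5, 4)]
  pat_b <- extract_pattern(perm, allele = "toy", frame = 2)  # same complex
  expect_equal(pat_a$mean_coords, pat_b$mean_coords, tolerance = 1e-6)
  expect_equal(pat_a$dispersion, pat_b$dispersion, tolerance = 1e-6)
})

test_that("mixed lengths split into per-length patterns with a warning", {
  a <- make_toy_cleft("FAPGNYPAL", relax = FALSE)
  b <- make_toy_cleft("SQLKNNAKEI", relax = FALSE)
  expect_warning(pats <- extract_pattern(list(a, b), allele = "toy"),
                 "mixed peptide lengths")
  expect_equal(length(pats), 2L)
  expect_equal(vapply(pats, function(p) p$length, integer(1)), c(9L, 10L))
})

test_that("pattern members are not exceptions; planted outliers are", {
  cpx <- toy_complex()
  members <- make_pattern_population(cpx, 20, 0.25, seed = 8)
  pat <- extract_pattern(members, allele = "toy")
  devs <- vapply(members[1:5], function(m)
    deviation_from_pattern(pat, m)$exception, logical(1))
  expect_false(any(devs))
  # p5 backbone displaced 4 A, rising out of the cleft
  out <- cpx
  sel <- out$peptide$atoms$resno == 5
  xyz <- get_coords(out$peptide)
  xyz[sel, 3] <- xyz[sel, 3] + 4
  out$peptide <- set_coords(out$peptide, xyz)
  dev <- deviation_from_pattern(pat, out)
  expect_true(dev$exception)
  expect_equal(dev$worst_position, 5L)
  expect_error(deviation_from_pattern(pat,
                                      make_toy_cleft("SQLKNNAKEI",
                                                     relax = FALSE)),
               "length")
})

test_that("position-5 composition of the curated ligand table matches the record", {
  seqs <- h2db_sequences()
  expect_equal(length(seqs), 28L)
  p5 <- composition_at(seqs, 5)
  expect_equal(unname(p5$counts[["N"]]), 25L)
  non_asn <- sort(unlist(p5$ids_by_residue[names(p5$ids_by_residue) != "N"]))
  expect_identical(unname(non_asn), c("1BZ9", "1INQ", "1JUF"))
  expect_true(all(aa_class(names(p5$ids_by_residue)[
    names(p5$ids_by_residue) != "N"]) == "nonpolar"))
})

test_that("the C terminus is nonpolar except for one cysteine", {
  seqs <- h2db_sequences()
  ct <- composition_at_cterm(seqs)
  expect_equal(unname(ct$class_counts[["nonpolar"]]), 27L)
  expect_equal(unname(ct$class_counts[["polar"]]), 1L)
  expect_identical(unname(unlist(ct$ids_by_residue[["C"]])), "1FG2")
})

test_that("composition counting follows its contracts", {
  one <- composition_at(c(s1 = "AAAA"), 2)
  expect_equal(unname(one$counts[["A"]]), 1L)
  expect_error(composition_at(character(0), 1), "no sequences")
  expect_warning(mixed <- composition_at(c(a = "AAAA", b = "AA"), 3),
                 "skipped")
  expect_equal(mixed$n, 1L)
  # class counts partition the residue counts
  seqs <- h2db_sequences()
  for (pos in c(1, 5)) {
    ct <- composition_at(seqs, pos)
    expect_equal(sum(ct$class_counts), sum(ct$counts))
  }
})

test_that("burial classification: anchors buried in pockets, free peptide exposed", {
  cpx <- toy_deep_p5()
  bp <- burial_profile(cpx, n_points = 480)
  expect_equal(bp$class[bp$position == 5], "buried")
  free <- burial_profile(cpx, n_points = 480, free = TRUE)
  expect_true(all(free$class == "exposed"))
  expect_true(all(free$rel_asa >= bp$rel_asa - 1e-9))
  # glycine surrogate: exposed in the free peptide
  gly <- make_toy_cleft("FAPGNYPAL", relax = FALSE)
  fr <- burial_profile(gly, n_points = 480, free = TRUE)
  expect_equal(fr$class[fr$resid == "GLY"], "exposed")
})

test_that("a planted serine-like donor hydrogen-bonds the peptide at p5", {
  cpx <- make_toy_cleft("FAPGNYPAL", donor_position = 5)
  rep <- conserved_contact_report(list(cpx), 73)
  expect_true(any(rep$found))
  hit <- rep[rep$found, ][1, ]
  expect_equal(hit$resid, "SER")
  expect_equal(hit$peptide_position, 5L)
  expect_equal(hit$distance, 2.9, tolerance = 0.01)
  expect_gte(hit$angle, 90)
})

test_that("contacts beyond 3.5 A are not reported; missing residues warn", {
  cpx <- make_toy_cleft("FAPGNYPAL", donor_position = 5)
  moved <- cpx
  sel <- moved$mhc$atoms$resno == 73
  moved$mhc$atoms$y[sel] <- moved$mhc$atoms$y[sel] + 1.5
  rep <- conserved_contact_report(list(moved), 73)
  expect_false(any(rep$found))
  expect_warning(rep2 <- conserved_contact_report(list(cpx), 999),
                 "no residue 999")
  expect_false(any(rep2$found))
})
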