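# PDB parsing, writing, and peptide/receptor splitting.

test_that("a single ATOM record parses into one chain, residue and atom", {
  txt <- paste0(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "           C\nEND\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 1L)
  res <- residue_table(s)
  expect_equal(nrow(res), 1L)
  expect_equal(res$resid, "ALA")
  expect_equal(as.numeric(s$atoms[1, c("x", "y", "z")]), c(1, 2, 3))
})

test_that("write/read round trip preserves the structure field by field", {
  pep <- make_ideal_peptide("FAPGNYPAL")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pep, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(pep$atoms))
  expect_identical(back$atoms$elety, pep$atoms$elety)
  expect_identical(back$atoms$resid, pep$atoms$resid)
  expect_identical(back$atoms$resno, pep$atoms$resno)
  expect_identical(back$atoms$chain, pep$atoms$chain)
  expect_equal(get_coords(back), round(get_coords(pep), 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("coordinates are written at three decimals in columns 31-54", {
  s <- structure_of(atom_row("C1", 1.23456, 0, 0, element = "C"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  line <- readLines(f)[1]
  expect_equal(substr(line, 31, 38), "   1.235")
})

test_that("an empty structure writes a file containing only END", {
  s <- pmhcbuild:::new_structure("empty", structure_of(atom_row("C1", 0, 0, 0))$atoms[0, ])
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  expect_identical(readLines(f), "END")
})

test_that("over-long atom names and malformed/empty inputs are rejected", {
  s <- structure_of(atom_row("CABCD", 0, 0, 0, element = "C"))
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_pdb(s, f), "too long")
  bad <- paste0(
    "ATOM      1  CA  ALA A   1       1.0x0   2.000   3.000  1.00  0.00",
    "           C\nEND\n")
  expect_error(read_pdb(bad), "line 1")
  expect_error(read_pdb("END\n"), "empty|record-free")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f2)
  expect_error(read_pdb(f2), "empty|record-free")
})

test_that("hydrogens are dropped and altloc B discarded at parse", {
  txt <- paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.50  0.00           C",
    "ATOM      4  HA  ALA A   1       1.458   1.000   0.000  1.00  0.00           H",
    "END", sep = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 2L)
  expect_false(any(s$atoms$element == "H"))
  expect_equal(s$atoms$x[s$atoms$elety == "CA"], 1.458)
})

test_that("split_pmhc selects the unique 8-12mer chain and drops waters", {
  cpx <- toy_complex()
  merged <- merge_pmhc(cpx)
  water <- atom_row("O", 50, 50, 50, element = "O", resid = "HOH",
                    chain = "W", resno = 999L, record = "HETATM")
  merged$atoms <- rbind(merged$atoms, water)
  out <- split_pmhc(merged)
  expect_equal(peptide_sequence(out), "FAPGNYPAL")
  expect_false(any(out$mhc$atoms$resid == "HOH"))
  expect_equal(nrow(out$mhc$atoms), nrow(cpx$mhc$atoms))
})

test_that("a water-only file parses but yields no peptide candidate", {
  txt <- paste(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END", sep = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 2L)
  expect_error(split_pmhc(s), "no candidate peptide")
})

test_that("two same-length peptide chains produce an ambiguity error", {
  cpx <- toy_complex()
  second <- cpx$peptide$atoms
  second$chain <- "Q"
  second$z <- second$z + 30
  merged <- merge_pmhc(cpx)
  merged$atoms <- rbind(merged$atoms, second)
  expect_error(split_pmhc(merged), "ambiguous.*P.*Q|ambiguous.*Q.*P")
})

test_that("an incomplete peptide backbone is excluded with an error", {
  cpx <- toy_complex()
  merged <- merge_pmhc(cpx)
  drop <- which(merged$atoms$chain == "P" & merged$atoms$resno == 4 &
                  merged$atoms$elety == "O")
  merged$atoms <- merged$atoms[-drop, ]
  expect_error(split_pmhc(merged), "incomplete backbone")
})

test_that("split_pmhc is idempotent on its own re-serialized output", {
  cpx <- toy_complex()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(merge_pmhc(cpx), f)
  once <- split_pmhc(read_pdb(f))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(merge_pmhc(once), f2)
  twice <- split_pmhc(read_pdb(f2))
  expect_identical(peptide_sequence(once), peptide_sequence(twice))
  expect_equal(get_coords(twice$peptide), get_coords(once$peptide))
  expect_equal(get_coords(twice$mhc), get_coords(once$mhc))
})

test_that("the FASTA reader returns named upper-case peptide sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">epi1 some description", "FAPGNYPAL",
               ">epi2", "asnen", "metm"), f)
  seqs <- read_peptide_fasta(f)
  expect_identical(unname(seqs), c("FAPGNYPAL", "ASNENMETM"))
  expect_identical(names(seqs), c("epi1", "epi2"))
})
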