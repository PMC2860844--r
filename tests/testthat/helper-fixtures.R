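# Shared fixtures, memoised for the whole test session. All structures are
# generated in code; nothing is read from disk except the packaged tables.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the standard toy complex: a real H-2Db nonamer epitope in the synthetic
# cleft with default anchor pockets (p5 and C terminus)
toy_complex <- function() memo("toy9", make_toy_cleft("FAPGNYPAL"))

# variant with a deep p5 pocket only
toy_deep_p5 <- function() memo("deep5", make_toy_cleft(
  "FAPGNYPAL", pocket_positions = 5, pocket_depth = 3, id = "toy_deep"))

# variant with mid-cleft bulge blockers
toy_blockers <- function() memo("blk", make_toy_cleft(
  "FAPGNYPAL", bulge_blockers = TRUE, id = "toy_blk"))

# small scaled protocol used throughout the tests (the package defaults,
# 20 runs x 50 poses, are desk-scale for production use; the tests use a
# reduced search with the same structure)
test_config <- function() docking_config(n_runs = 3, n_out_per_run = 10,
                                         n_iter = 60, em_short = 50,
                                         em_long = 100)

# D1-EM-D2 self-reconstruction over ten seeds, shared between the
# planted-truth recovery and energy-improvement checks
recovery_runs <- function() memo("recovery", {
  cpx <- toy_complex()
  lapply(1:10, function(sd) {
    res <- run_d1_em_d2("FAPGNYPAL", cpx, cpx, config = test_config(),
                        seed = sd)
    list(rmsd = fit_by_mhc_ca(res$complex, cpx)$epitope_rmsd,
         d1 = res$d1_energy$total, d2 = res$d2_energy$total)
  })
})

# a bare structure from an atom table fragment
atom_row <- function(elety, x, y, z, element = substr(elety, 1, 1),
                     resid = "UNK", chain = "A", resno = 1L,
                     record = "ATOM") {
  data.frame(record = record, elety = elety, element = element,
             resid = resid, chain = chain, resno = resno, icode = "",
             x = x, y = y, z = z, occ = 1, stringsAsFactors = FALSE)
}

structure_of <- function(...) {
  pmhcbuild:::new_structure("test", do.call(rbind, list(...)))
}
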