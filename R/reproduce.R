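# Crystal-structure reproduction benchmark: rebuild a deposited pMHC from
# its sequence and an independent template, then validate against the
# crystal at the standard 2.2 Angstrom bound.

#' Reproduce a crystallised pMHC complex from local PDB files
#'
#' Rebuilds the target complex's peptide from its own sequence using the
#' template complex's peptide backbone (same allele and length) and the
#' donor complex's receptor, via the full threading + dock-minimize-dock
#' protocol, then reports the epitope heavy-atom RMSD against the target
#' crystal after fitting the receptors by alpha-chain Calpha (the standard
#' validation metric) and the fit-by-epitope-Calpha variant.
#'
#' Typical use: `reproduce_crystal("2V2W.pdb", "2V2W.pdb", "1T1Z.pdb")`
#' rebuilds the 2V2W epitope on the 1T1Z template with 2V2W as receptor
#' donor. The PDB files must be provided locally (this package performs no
#' downloads).
#'
#' @param target_path PDB file of the crystal to reproduce
#' @param donor_path PDB file donating the receptor (often the target)
#' @param template_path PDB file providing the template peptide backbone
#' @param config a `protocol_config`
#' @param seed master seed
#' @param bound validity bound in Angstrom (2.2 by convention)
#' @return list: `result` (the `docking_result`), `rmsd_mhc_ca`,
#'   `rmsd_epitope_ca`, `bound`, `valid`
#' @export
reproduce_crystal <- function(target_path, donor_path, template_path,
                              config = docking_config(), seed = 1,
                              bound = 2.2) {
  target <- split_pmhc(read_pdb(target_path))
  donor <- if (identical(donor_path, target_path)) target else
    split_pmhc(read_pdb(donor_path))
  template <- if (identical(template_path, target_path)) target else
    split_pmhc(read_pdb(template_path))
  result <- run_d1_em_d2(peptide_sequence(target), donor, template,
                         config = config, seed = seed)
  by_mhc <- fit_by_mhc_ca(result$complex, target)
  by_epi <- fit_by_epitope_ca(result$complex, target)
  list(result = result,
       rmsd_mhc_ca = by_mhc$epitope_rmsd,
       rmsd_epitope_ca = by_epi$epitope_rmsd,
       bound = bound,
       valid = by_mhc$epitope_rmsd < bound)
}
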