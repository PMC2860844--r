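Package: pmhcbuild
Title: Construction and Structural Analysis of MHC Class I Peptide Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structural immunoinformatics of MHC class I peptide
    (pMHC-I) complexes. Extracts allele-specific peptide backbone
    conformational patterns from sets of crystal structures, flags
    structural outliers, and analyses anchor-position composition and
    burial. Builds new pMHC-I complexes for arbitrary peptide sequences by
    template threading followed by a dock-minimize-dock protocol with a
    rigid receptor and flexible peptide side chains. Provides
    solvent-accessible surface area signatures (Shrake-Rupley) and
    TCR-face topology and electrostatic comparisons for cross-reactivity
    screening, plus a deterministic synthetic fixture generator (ideal
    geometry peptides and toy binding clefts) so the full pipeline can be
    exercised without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
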