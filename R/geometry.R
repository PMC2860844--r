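# Ideal-geometry machinery: amino-acid code tables, the packaged side-chain
# z-matrix, internal-to-Cartesian construction (NeRF), torsion measurement,
# rotamer staples and per-residue bond topology.

.pkg_cache <- new.env(parent = emptyenv())

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Convert three-letter residue names to one-letter codes ('X' if unknown)
#' @param code3 character vector of three-letter residue names
#' @return character vector of one-letter codes
#' @export
aa_three2one <- function(code3) {
  i <- match(toupper(code3), AA3)
  out <- AA1[i]
  out[is.na(i)] <- "X"
  out
}

#' Convert one-letter codes to three-letter residue names
#' @param code1 character vector of one-letter residue codes
#' @return character vector of three-letter names
#' @export
aa_one2three <- function(code1) {
  i <- match(toupper(code1), AA1)
  if (anyNA(i)) {
    stop("non-canonical residue code(s): ",
         paste(unique(code1[is.na(i)]), collapse = ", "))
  }
  AA3[i]
}

is_canonical_aa <- function(code3) toupper(code3) %in% AA3

# Backbone ideal internal coordinates (Engh-Huber-like)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_o = 1.231, c_n = 1.329,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

#' Side-chain z-matrix table packaged with the tool
#' @return data.frame with one row per side-chain atom placement rule
#' @export
sidechain_topology <- function() {
  if (is.null(.pkg_cache$scbuild)) {
    path <- system.file("extdata", "sidechain_topology.tsv",
                        package = "pmhcbuild", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .pkg_cache$scbuild <- tab
  }
  .pkg_cache$scbuild
}

#' Number of rotatable chi torsions per canonical residue type
#' @param code3 three-letter residue name
#' @return integer count of chi angles
#' @export
n_chi <- function(code3) {
  tab <- sidechain_topology()
  rows <- tab[tab$resid == toupper(code3), , drop = FALSE]
  ch <- grep("^chi", rows$tortype, value = TRUE)
  if (!length(ch)) return(0L)
  max(as.integer(sub("chi", "", ch)))
}

#' Canonical chi staple values (degrees) used as the rotamer library
#'
#' A deliberately minimal backbone-independent library: gauche-/gauche+/trans
#' staples for aliphatic torsions, +/-90 for the aromatic ring flip torsion,
#' and a narrow pucker pair for proline.
#' @param code3 three-letter residue name
#' @param chi chi index (1-based)
#' @return numeric vector of staple torsions in degrees
#' @export
chi_staples <- function(code3, chi) {
  code3 <- toupper(code3)
  if (code3 == "PRO") return(if (chi == 1) c(-34, 34) else c(22, -22))
  if (chi == 2 && code3 %in% c("PHE", "TYR", "TRP", "HIS")) return(c(90, -90))
  c(-60, 60, 180)
}

# Chi torsion atom-name quadruples, read off the packaged z-matrix
chi_atoms <- function(code3) {
  tab <- sidechain_topology()
  rows <- tab[tab$resid == toupper(code3) & grepl("^chi", tab$tortype) &
                tab$offset == 0, , drop = FALSE]
  if (!nrow(rows)) return(list())
  rows <- rows[order(rows$tortype), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    with(rows[i, ], c(ref1, ref2, ref3, atom))
  })
}

element_from_name <- function(name) {
  # heavy-atom PDB names start with the element letter (C, N, O, S)
  first <- substr(gsub("[0-9]", "", name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P"), first, first)
}

#' Build side-chain atoms from ideal internal geometry
#'
#' Places the side chain of one residue from its backbone frame and a vector
#' of chi torsions using the packaged z-matrix.
#'
#' @param code3 three-letter residue name (canonical)
#' @param backbone named list or matrix with rows/entries `N`, `CA`, `C`
#'   giving 3-vectors in Angstrom
#' @param chi numeric vector of chi torsions (degrees); recycled/truncated to
#'   the residue's chi count, defaults to all-trans (180)
#' @return data.frame with columns `elety`, `element`, `x`, `y`, `z`
#'   (empty for glycine)
#' @export
build_sidechain <- function(code3, backbone, chi = NULL) {
  code3 <- toupper(code3)
  if (!is_canonical_aa(code3)) stop("non-canonical residue type: ", code3)
  if (is.matrix(backbone)) {
    backbone <- list(N = backbone["N", ], CA = backbone["CA", ],
                     C = backbone["C", ])
  }
  for (nm in c("N", "CA", "C")) {
    if (is.null(backbone[[nm]]) || !all(is.finite(backbone[[nm]]))) {
      stop("backbone frame must provide finite N, CA, C coordinates")
    }
  }
  if (vnorm(vcross(backbone$N - backbone$CA, backbone$C - backbone$CA)) < 1e-6) {
    stop("degenerate backbone frame (collinear N, CA, C)")
  }
  nchi <- n_chi(code3)
  # proline's default chi close the pyrrolidine ring (one pucker state)
  if (is.null(chi)) chi <- if (code3 == "PRO") c(-34, 22) else rep(180, nchi)
  chi <- rep_len(as.numeric(chi), max(nchi, 1L))
  tab <- sidechain_topology()
  rows <- tab[tab$resid == code3, , drop = FALSE]
  pos <- backbone
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tor <- if (r$tortype == "fixed") r$offset else
      chi[as.integer(sub("chi", "", r$tortype))] + r$offset
    p <- place_atom(pos[[r$ref1]], pos[[r$ref2]], pos[[r$ref3]],
                    r$bond, r$angle, tor)
    pos[[r$atom]] <- p
    out[[i]] <- data.frame(elety = r$atom,
                           element = element_from_name(r$atom),
                           x = p[1], y = p[2], z = p[3],
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(elety = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Measure the chi torsions of a residue's atoms
#' @param code3 three-letter residue name
#' @param atoms data.frame with `elety`, `x`, `y`, `z` for one residue
#' @return numeric vector of chi torsions (degrees), NA where atoms missing
#' @export
measure_chi <- function(code3, atoms) {
  quads <- chi_atoms(code3)
  vapply(quads, function(q) {
    idx <- match(q, atoms$elety)
    if (anyNA(idx)) return(NA_real_)
    p <- as.matrix(atoms[idx, c("x", "y", "z")])
    dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  }, numeric(1))
}

# Intra-residue heavy-atom bond list for a canonical residue: backbone bonds
# plus z-matrix parent bonds plus ring closures.
RING_CLOSURES <- list(
  PHE = list(c("CE2", "CZ")), TYR = list(c("CE2", "CZ")),
  TRP = list(c("CE2", "CD2"), c("CZ3", "CH2")),
  HIS = list(c("CE1", "NE2")), PRO = list(c("CD", "N"))
)

residue_bonds <- function(code3) {
  code3 <- toupper(code3)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (is_canonical_aa(code3)) {
    tab <- sidechain_topology()
    rows <- tab[tab$resid == code3, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      bonds[[length(bonds) + 1L]] <- c(rows$ref3[i], rows$atom[i])
    }
    for (cl in RING_CLOSURES[[code3]] %||% list()) {
      bonds[[length(bonds) + 1L]] <- cl
    }
  }
  bonds
}
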