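# Template-based threading: copy the template peptide backbone verbatim and
# rebuild side chains for the target sequence from ideal internal geometry.

#' Thread a target sequence onto a template peptide backbone
#'
#' The backbone (N, CA, C, O) is copied bit-exactly from the template.
#' Positions where the target residue equals the template residue keep the
#' template side-chain atoms; substituted positions get side chains rebuilt
#' from ideal geometry in the template backbone frame, inheriting the
#' template's chi torsions where a torsion of the same index exists
#' (all-trans otherwise).
#'
#' @param target_seq one-letter peptide sequence, same length as the
#'   template peptide, canonical residues only
#' @param template `pmhc_structure` holding a single peptide chain with
#'   complete backbones (e.g. the `peptide` of a `pmhc_complex`)
#' @return a `pmhc_structure` with residues renumbered 1..n
#' @export
thread_sequence <- function(target_seq, template) {
  codes <- strsplit(toupper(target_seq), "")[[1]]
  res <- residue_table(template)
  if (length(codes) != nrow(res))
    stop("target length ", length(codes), " != template length ", nrow(res),
         "; threading requires a template with the same number of residues")
  target3 <- aa_one2three(codes)   # errors on non-canonical targets
  if (!all(res$canonical))
    stop("template contains non-canonical residue(s) at position(s): ",
         paste(which(!res$canonical), collapse = ", "),
         "; refusing to thread")
  if (!all(res$backbone))
    stop("template backbone incomplete at position(s): ",
         paste(which(!res$backbone), collapse = ", "))
  atoms <- template$atoms
  key <- residue_key(atoms)
  ukey <- unique(key)
  chain <- res$chain[1]
  rows <- list()
  for (i in seq_len(nrow(res))) {
    sel <- which(key == ukey[i])
    at <- atoms[sel, , drop = FALSE]
    bbsel <- match(c("N", "CA", "C", "O"), at$elety)
    bb <- at[bbsel, , drop = FALSE]
    if (target3[i] == res$resid[i]) {
      df <- rbind(bb, at[-bbsel, , drop = FALSE])
    } else {
      frame <- list(N = as.numeric(bb[1, c("x", "y", "z")]),
                    CA = as.numeric(bb[2, c("x", "y", "z")]),
                    C = as.numeric(bb[3, c("x", "y", "z")]))
      tmpl_chi <- measure_chi(res$resid[i], at)
      nchi <- n_chi(target3[i])
      chi <- rep(180, max(nchi, 1L))
      if (nchi > 0 && length(tmpl_chi)) {
        m <- seq_len(min(nchi, length(tmpl_chi)))
        inherit <- tmpl_chi[m]
        chi[m][!is.na(inherit)] <- inherit[!is.na(inherit)]
      }
      sc <- build_sidechain(target3[i], frame, chi = chi)
      if (nrow(sc)) {
        sc$record <- "ATOM"; sc$resid <- target3[i]; sc$chain <- chain
        sc$resno <- i; sc$icode <- ""; sc$occ <- 1
        sc <- sc[, names(atoms)]
      }
      df <- rbind(bb, if (nrow(sc)) sc else NULL)
    }
    df$record <- "ATOM"
    df$resid <- target3[i]
    df$chain <- chain
    df$resno <- i
    df$icode <- ""
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  new_structure(paste0("thread_", target_seq), out)
}
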