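# Ensembles on disk: multi-MODEL PDB, one MODEL per conformer, with the
# conformer weight written into the B-factor column of the nitroxide atoms.

#' Write a label ensemble as a multi-MODEL PDB file
#'
#' @param ens a `label_ensemble`.
#' @param path output path.
#' @param chain chain identifier for the written R1A residue.
#' @param resno residue number (defaults to the ensemble's site).
#' @export
write_ensemble_pdb <- function(ens, path, chain = NULL, resno = NULL) {
  if (!length(ens$conformers)) stop("cannot write an empty ensemble")
  chain <- chain %||% substr(as.character(ens$site[[1L]]), 1L, 1L)
  resno <- resno %||% as.integer(ens$site[[2L]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 SPINLABELR ENSEMBLE METHOD %s N %d PF %.6g",
                     toupper(ens$method), length(ens$conformers),
                     ens$partition_function), con)
  for (m in seq_along(ens$conformers)) {
    cf <- ens$conformers[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    a <- cf$atoms
    nm <- rownames(a)
    bfac <- ifelse(nm %in% c("N1", "O1"), cf$weight, 0)
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(nm) >= 4L, nm, paste0(" ", nm)),
      "R1A", chain, resno, a[, 1L], a[, 2L], a[, 3L], 1, bfac,
      substr(nm, 1L, 1L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Measure chi angles of every MODEL in an ensemble PDB file
#'
#' @param path a multi-MODEL PDB file written by [write_ensemble_pdb()] (or
#'   any file whose MODELs each contain one full R1A residue).
#' @param topo label topology.
#' @return matrix, one row of chi1-chi5 per MODEL.
#' @export
read_ensemble_chi <- function(path, topo = r1_topology()) {
  ln <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", ln)
  ends <- grep("^ENDMDL", ln)
  if (length(starts) == 0L) { starts <- 1L; ends <- length(ln) }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records")
  out <- matrix(NA_real_, length(starts), 5L,
                dimnames = list(NULL, paste0("chi", 1:5)))
  for (m in seq_along(starts)) {
    blk <- ln[starts[m]:ends[m]]
    at <- blk[grepl("^(ATOM  |HETATM)", blk)]
    nm <- trimws(substr(at, 13, 16))
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54)))
    rownames(xyz) <- nm
    out[m, ] <- measure_chi(xyz, topo)
  }
  out
}
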