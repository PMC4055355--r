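# Structure-level checks against deposited spin-labelled azurin crystal
# structures.  These need the deposited coordinate files on disk (they are
# not shipped with the package); everything else in the package runs on
# synthetic fixtures.

protein_chains <- function(model, min_res = 50L) {
  at <- model$atoms[model$atoms$record == "ATOM", , drop = FALSE]
  n_per <- tapply(at$resno, at$chain, function(r) length(unique(r)))
  names(n_per)[n_per >= min_res]
}

ca_coords <- function(model, chain) {
  at <- model$atoms
  sel <- at$chain == chain & at$name == "CA" & at$record == "ATOM"
  m <- as.matrix(at[sel, c("x", "y", "z")])
  rownames(m) <- at$resno[sel]
  m
}

# CA RMSD between two chains over their common residue numbers
chain_ca_rmsd <- function(model_a, chain_a, model_b, chain_b) {
  ca <- ca_coords(model_a, chain_a)
  cb <- ca_coords(model_b, chain_b)
  common <- intersect(rownames(ca), rownames(cb))
  if (length(common) < 3L) stop("too few common CA atoms")
  superpose_rmsd(ca[common, ], cb[common, ])$rmsd
}

#' Benchmark a spin-labelled azurin crystal structure
#'
#' Given the deposited coordinates of the spin-labelled azurin crystal form
#' (four monomers in P1) and optionally a reference azurin structure, this
#' computes: the number of protein chains in the asymmetric unit, the mean
#' pairwise C-alpha RMSD among the monomers, the C-alpha RMSD of the first
#' monomer against the reference, and — in the packing-expanded assembly —
#' the total and buried solvent-accessible surface area of every R1 side
#' chain found.
#'
#' @param path path to the spin-labelled structure (PDB format).
#' @param reference_path optional path to a reference azurin structure.
#' @param packing_cutoff Angstrom for the packing expansion used as SASA
#'   context.
#' @param n_points SASA quadrature points per atom.
#' @return list with `n_chains`, `mean_pairwise_ca_rmsd`,
#'   `reference_ca_rmsd` (or NA), and a data.frame `r1_surface` with one
#'   row per R1 site (chain, resno, total_asa, buried_asa).
#' @export
benchmark_azurin <- function(path, reference_path = NULL,
                             packing_cutoff = 5, n_points = 960) {
  model <- read_pdb(path)
  chains <- protein_chains(model)
  rmsds <- c()
  if (length(chains) >= 2L)
    for (i in seq_len(length(chains) - 1L))
      for (j in (i + 1L):length(chains))
        rmsds <- c(rmsds, chain_ca_rmsd(model, chains[i], model, chains[j]))
  ref_rmsd <- NA_real_
  if (!is.null(reference_path)) {
    ref <- read_pdb(reference_path)
    ref_rmsd <- chain_ca_rmsd(model, chains[1L], ref,
                              protein_chains(ref)[1L])
  }

  r1 <- unique(model$atoms[toupper(model$atoms$resname) == "R1A",
                           c("chain", "resno")])
  surf <- NULL
  if (nrow(r1)) {
    sites <- lapply(seq_len(nrow(r1)),
                    function(i) list(chain = r1$chain[i],
                                     resno = r1$resno[i]))
    asm <- build_benchmark_assembly(model, sites, packing_cutoff)$model
    side <- .r1_sidechain_atoms
    rows <- lapply(sites, function(s) {
      sel <- asm$atoms$chain == s$chain & asm$atoms$resno == s$resno &
        asm$atoms$name %in% side
      sr <- sasa(asm, sel, n_points = n_points)
      data.frame(chain = s$chain, resno = s$resno,
                 total_asa = sr$total_asa, buried_asa = sr$buried_asa)
    })
    surf <- do.call(rbind, rows)
  }
  list(n_chains = length(chains),
       mean_pairwise_ca_rmsd = if (length(rmsds)) mean(rmsds) else NA_real_,
       reference_ca_rmsd = ref_rmsd,
       r1_surface = surf)
}
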