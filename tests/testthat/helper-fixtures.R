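# shared fixture builders

# minimal ensembles whose conformers only need N1/O1 coordinates
fake_ensemble <- function(centers, weights = NULL) {
  n <- nrow(centers)
  if (is.null(weights)) weights <- rep(1 / n, n)
  confs <- lapply(seq_len(n), function(i) {
    at <- rbind(N1 = centers[i, ], O1 = centers[i, ] + c(0, 0, 1.27))
    structure(list(chi = rep(0, 5), atoms = at, weight = weights[i]),
              class = "conformer")
  })
  structure(list(site = list("A", 1), method = "test", conformers = confs,
                 partition_function = 1, n_trials = n, params = list()),
            class = "label_ensemble")
}

one_atom_model <- function(xyz, element = "C", vdw = 1.7, chain = "A") {
  n <- nrow(xyz)
  at <- data.frame(record = "ATOM", serial = seq_len(n), name = element,
                   altloc = "", resname = "UNK", chain = chain,
                   resno = seq_len(n), icode = "", x = xyz[, 1],
                   y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
                   element = element, vdw = vdw, stringsAsFactors = FALSE)
  spinlabelr:::new_structure_model(at)
}
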