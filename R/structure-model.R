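# Coordinate data model: a structure_model is a flat atom table plus an
# optional crystal cell and a list of fractional symmetry operators.
# Chains/residues are columns of the table, the natural R idiom for
# whole-structure vectorised work (cf. bio3d's pdb$atom).

# Bondi-style van der Waals radii (Angstrom) used for clash detection and
# surface areas; overridable wherever radii enter a computation.
.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                  CU = 1.40, ZN = 1.39, P = 1.80)

vdw_radius <- function(element, table = .default_vdw) {
  r <- table[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct a crystal cell
#'
#' @param a,b,c axis lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return an object of class `crystal_cell`.
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  class(cell) <- "crystal_cell"
  if (cell_discriminant(cell) <= 0)
    stop("degenerate cell: volume discriminant is not positive")
  cell
}

cell_discriminant <- function(cell) {
  ca <- cos(deg2rad(cell$alpha))
  cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma))
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Triclinic cell volume
#'
#' `V = abc * sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'   + 2 cos(alpha) cos(beta) cos(gamma))`, valid for every crystal system.
#'
#' @param cell a [crystal_cell()].
#' @return volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  disc <- cell_discriminant(cell)
  if (disc <= 0) stop("degenerate cell: volume discriminant is not positive")
  cell$a * cell$b * cell$c * sqrt(disc)
}

# orthogonalisation matrix: columns are the cell vectors in Cartesian frame,
# so cart = M %*% frac.
orth_matrix <- function(cell) {
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma)); sg <- sin(deg2rad(cell$gamma))
  v <- sqrt(cell_discriminant(cell))
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3L, byrow = TRUE)
}

#' Solvent content from the Matthews coefficient
#'
#' The standard Matthews relation: solvent fraction = 1 - 1.23 / Vm, where
#' 1.23 A^3/Da is the reciprocal density of a typical protein.
#'
#' @param vm Matthews coefficient in Angstrom^3 per Dalton; must be >= 1.23.
#' @return solvent content in percent.
#' @examples
#' matthews_solvent(2.41)  # 49.0 percent
#' @export
matthews_solvent <- function(vm) {
  if (any(vm < 1.23))
    stop("Matthews coefficient below 1.23 A^3/Da implies a physically ",
         "impossible protein density")
  100 * (1 - 1.23 / vm)
}

new_structure_model <- function(atoms, cell = NULL, symmetry = NULL) {
  if (is.null(symmetry))
    symmetry <- list(list(R = diag(3), t = c(0, 0, 0)))
  structure(list(atoms = atoms, cell = cell, symmetry = symmetry),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(ch), "chain(s):", paste(ch, collapse = " "), "\n")
  if (!is.null(x$cell))
    cat(sprintf("  cell: %.1f %.1f %.1f A, %.1f %.1f %.1f deg\n",
                x$cell$a, x$cell$b, x$cell$c,
                x$cell$alpha, x$cell$beta, x$cell$gamma))
  invisible(x)
}

# fixed-column numeric fields of an ATOM/HETATM record; returns NULL if ok,
# else a description of the defect
.check_atom_record <- function(line) {
  for (f in list(c(31, 38, "x"), c(39, 46, "y"), c(47, 54, "z"))) {
    v <- suppressWarnings(as.numeric(substr(line, as.integer(f[1L]),
                                            as.integer(f[2L]))))
    if (is.na(v)) return(paste("non-numeric", f[3L], "coordinate"))
  }
  NULL
}

#' Read a PDB file into a structure_model
#'
#' Parsing of the fixed-column records is delegated to
#' \code{bio3d::read.pdb}; on top of that the CRYST1 record is parsed into a
#' [crystal_cell()], alternate locations are reduced to the highest-occupancy
#' conformer (ties broken towards altloc 'A'), and van der Waals radii are
#' attached per element.  HETATM residues (metal ions, the R1 label, solvent)
#' are kept and flagged.
#'
#' @param path path to a PDB file.
#' @param vdw_table named vector of per-element radii overriding the built-in
#'   Bondi-style table.
#' @return a `structure_model`.
#' @export
read_pdb <- function(path, vdw_table = .default_vdw) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_at <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_at)) stop("no ATOM/HETATM records in ", path)
  for (i in which(is_at)) {
    bad <- .check_atom_record(lines[i])
    if (!is.null(bad))
      stop("malformed ATOM/HETATM record at line ", i, ": ", bad)
  }

  cell <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) >= 1L) {
    f <- suppressWarnings(as.numeric(c(
      substr(cl[1L], 7, 15), substr(cl[1L], 16, 24), substr(cl[1L], 25, 33),
      substr(cl[1L], 34, 40), substr(cl[1L], 41, 47), substr(cl[1L], 48, 54))))
    if (!anyNA(f) && all(f[1:3] > 0))
      cell <- crystal_cell(f[1L], f[2L], f[3L], f[4L], f[5L], f[6L])
  }

  p <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom
  el <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1L, 1L))
  el[is.na(el) | el == ""] <- guess[is.na(el) | el == ""]
  occ <- at$o
  occ[is.na(occ)] <- 1
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- " "
  atoms <- data.frame(
    record = at$type, serial = at$eleno, name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid), chain = chain, resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = occ, b = ifelse(is.na(at$b), 0, at$b),
    element = el, stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius(atoms$element, vdw_table)

  # altloc reduction: keep the highest-occupancy location of each atom,
  # preferring 'A' (then alphabetical) on ties
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "|")
    ord <- order(key, -atoms$occ, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                     atoms$name, sep = "|")), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  new_structure_model(atoms, cell = cell)
}

# deterministic remap of long internal chain ids to single PDB characters
.chain_letters <- c(LETTERS, letters, 0:9)

#' Write a structure_model as a PDB file
#'
#' Emits standard fixed-column ATOM/HETATM records (and a CRYST1 header when
#' a cell is present).  Internal chain identifiers longer than one character
#' (packing images carry suffixes) are remapped deterministically onto
#' single characters.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return invisibly, the chain-id mapping used.
#' @export
write_pdb <- function(model, path) {
  at <- model$atoms
  if (is.null(at) || nrow(at) == 0L) stop("cannot write an empty model")
  if (any(nchar(at$name) > 4L)) stop("atom name longer than 4 characters")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$cell))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       model$cell$a, model$cell$b, model$cell$c,
                       model$cell$alpha, model$cell$beta, model$cell$gamma),
               con)
  ch <- unique(at$chain)
  map <- if (all(nchar(ch) == 1L)) stats::setNames(ch, ch) else
    stats::setNames(.chain_letters[seq_along(ch)], ch)
  nm <- ifelse(nchar(at$name) >= 4L | nchar(at$element) >= 2L,
               at$name, paste0(" ", at$name))
  rec <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 at$record, seq_len(nrow(at)) %% 100000L, nm, "",
                 at$resname, map[at$chain], at$resno,
                 ifelse(at$icode == "", " ", at$icode),
                 at$x, at$y, at$z, at$occ, at$b, at$element)
  # TER between chains
  out <- character(0)
  for (c1 in ch) {
    out <- c(out, rec[at$chain == c1], "TER")
  }
  writeLines(c(out, "END"), con)
  invisible(map)
}

# coordinates of one residue as a matrix with atom-name rownames
residue_coords <- function(model, chain, resno) {
  sel <- model$atoms$chain == chain & model$atoms$resno == resno
  if (!any(sel)) stop("residue ", resno, " in chain '", chain, "' not found")
  at <- model$atoms[sel, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$name
  m
}

#' Expand crystal packing around a chain
#'
#' Adds every symmetry/lattice image of the model that has at least one atom
#' within `cutoff` Angstrom of the centre chain.  For space group P1 (the
#' only group required here) the operators are the identity plus integer
#' lattice translations; image chains receive suffixed identifiers such as
#' `"A+101"` (operator index and lattice shift).
#'
#' @param model a `structure_model` with a crystal cell.
#' @param center_chain chain identifier to expand around.
#' @param cutoff contact distance in Angstrom; `cutoff <= 0` returns the
#'   model unchanged.
#' @return a `structure_model` containing the original chains plus contact
#'   images.
#' @export
expand_packing <- function(model, center_chain, cutoff) {
  if (cutoff <= 0) return(model)
  if (is.null(model$cell))
    stop("packing expansion needs a crystal cell: supply a CRYST1 record")
  M <- orth_matrix(model$cell)
  Minv <- solve(M)
  at <- model$atoms
  xyz <- t(as.matrix(at[, c("x", "y", "z")]))   # 3 x n
  frac <- Minv %*% xyz
  csel <- at$chain == center_chain
  if (!any(csel)) stop("centre chain '", center_chain, "' not found")
  cxyz <- t(xyz[, csel, drop = FALSE])          # m x 3

  # conservative integer translation ranges from the cell heights
  V <- cell_volume(model$cell)
  ax <- M[, 1L]; bx <- M[, 2L]; cx <- M[, 3L]
  heights <- c(V / vnorm(vcross(bx, cx)),
               V / vnorm(vcross(ax, cx)),
               V / vnorm(vcross(ax, bx)))
  rng <- pmin(3L, ceiling(cutoff / heights) + 1L)

  pieces <- list(model$atoms)
  for (k in seq_along(model$symmetry)) {
    op <- model$symmetry[[k]]
    base <- op$R %*% frac + op$t
    for (n1 in -rng[1L]:rng[1L]) for (n2 in -rng[2L]:rng[2L])
      for (n3 in -rng[3L]:rng[3L]) {
        if (k == 1L && n1 == 0L && n2 == 0L && n3 == 0L) next
        img <- M %*% (base + c(n1, n2, n3))
        # bounding-box prefilter then exact minimum distance
        lo <- apply(cxyz, 2L, min) - cutoff
        hi <- apply(cxyz, 2L, max) + cutoff
        inbox <- img[1L, ] >= lo[1L] & img[1L, ] <= hi[1L] &
                 img[2L, ] >= lo[2L] & img[2L, ] <= hi[2L] &
                 img[3L, ] >= lo[3L] & img[3L, ] <= hi[3L]
        if (!any(inbox)) next
        # exact check, atom by atom, for the prefiltered subset
        near <- logical(ncol(img))
        idx <- which(inbox)
        near[idx] <- vapply(idx, function(j)
          min(rowSums(sweep(cxyz, 2L, img[, j])^2)) <= cutoff^2, logical(1L))
        if (!any(near)) next
        # keep only those chains of the image that actually touch the centre
        keep_ch <- unique(at$chain[near])
        csub <- at$chain %in% keep_ch
        piece <- at[csub, , drop = FALSE]
        piece$x <- img[1L, csub]; piece$y <- img[2L, csub]
        piece$z <- img[3L, csub]
        tag <- sprintf("+%d%d%d", n1 + 1L, n2 + 1L, n3 + 1L)
        if (k > 1L) tag <- sprintf("s%d%s", k, tag)
        piece$chain <- paste0(piece$chain, tag)
        pieces[[length(pieces) + 1L]] <- piece
      }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  new_structure_model(out, cell = model$cell, symmetry = model$symmetry)
}
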