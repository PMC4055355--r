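# The R1 side-chain model: internal-coordinate template, Cartesian
# construction from chi1-chi5, and chi measurement from coordinates.

.r1_sidechain_atoms <- c("CB", "SG", "SD", "CE", "C3", "C4", "C5",
                         "C6", "C7", "C8", "C9", "N1", "O1")

#' The R1 side-chain internal-coordinate topology
#'
#' Loads the plain-text template shipped with the package: every side-chain
#' atom beyond CB with its reference triplet, bond length, bond angle and
#' dihedral (either a frozen value or one of the five rotatable torsions
#' chi1-chi5).  Bond lengths and angles are ideal values; only the dihedrals
#' vary, mirroring the rigid-geometry treatment both prediction paradigms
#' use.
#'
#' The fourth atom of chi5 is convention-dependent across programs and
#' libraries, so it is configurable; every report downstream names the
#' convention in use.
#'
#' @param chi5_atom fourth atom of the chi5 torsion (default `"C4"`,
#'   i.e. chi5 = SD-CE-C3-C4).
#' @param path optional alternative template file.
#' @return an object of class `label_topology`.
#' @export
r1_topology <- function(chi5_atom = "C4", path = NULL) {
  if (is.null(path)) {
    key <- paste0("default|", chi5_atom)
    if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
    path <- system.file("extdata", "r1a_topology.txt", package = "spinlabelr",
                        mustWork = TRUE)
    on.exit(.topo_cache[[key]] <- out, add = TRUE)
  }
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  f <- strsplit(trimws(ln), "\\s+")
  if (any(lengths(f) != 7L)) stop("malformed topology line in ", path)
  tab <- data.frame(atom = vapply(f, `[`, "", 1L),
                    p1 = vapply(f, `[`, "", 2L),
                    p2 = vapply(f, `[`, "", 3L),
                    p3 = vapply(f, `[`, "", 4L),
                    bond = as.numeric(vapply(f, `[`, "", 5L)),
                    angle = as.numeric(vapply(f, `[`, "", 6L)),
                    dihedral = vapply(f, `[`, "", 7L),
                    stringsAsFactors = FALSE)
  if (any(tab$bond <= 1.0 | tab$bond >= 2.2))
    stop("template bond length outside the physical window (1.0, 2.2) A")
  chi <- list(chi1 = c("N", "CA", "CB", "SG"),
              chi2 = c("CA", "CB", "SG", "SD"),
              chi3 = c("CB", "SG", "SD", "CE"),
              chi4 = c("SG", "SD", "CE", "C3"),
              chi5 = c("SD", "CE", "C3", chi5_atom))
  known <- c("N", "CA", .r1_sidechain_atoms)
  if (!all(unlist(chi) %in% known))
    stop("chi definition names an atom absent from the topology")
  out <- structure(list(atoms = tab, chi_definitions = chi,
                        chi5_convention = paste0("SD-CE-C3-", chi5_atom),
                        spin_center = "N1"),
                   class = "label_topology")
  out
}

.topo_cache <- new.env(parent = emptyenv())

#' @export
print.label_topology <- function(x, ...) {
  cat("R1 label topology:", nrow(x$atoms), "buildable atoms;",
      "chi5 convention", x$chi5_convention, "\n")
  invisible(x)
}

# idealized CB from backbone N, CA, C (mutate-to-CYS geometry)
build_cb <- function(n, ca, c) {
  place_atom(n, c, ca, 1.530, 110.5, 122.5)
}

#' Build one R1 conformer from chi angles
#'
#' Places every template atom by the standard internal-to-Cartesian (NERF)
#' construction off the residue's N/CA/CB backbone.  The construction and
#' [measure_chi()] share one sign convention, so measuring a built conformer
#' returns the input angles.
#'
#' @param backbone 3 x 3 matrix with rownames `N`, `CA`, `CB` (Angstrom).
#'   A `C` row may replace `CB`; CB is then built with ideal geometry.
#' @param chi numeric length 5, degrees.
#' @param topo a [r1_topology()].
#' @param weight occupancy fraction stored on the conformer.
#' @return an object of class `conformer`: list with `chi`, `atoms`
#'   (coordinate matrix with rownames N, CA, CB, SG, ..., O1) and `weight`.
#' @export
build_label <- function(backbone, chi, topo = r1_topology(), weight = 1) {
  backbone <- as.matrix(backbone)
  for (nm in c("N", "CA"))
    if (!nm %in% rownames(backbone))
      stop("missing backbone atom: ", nm)
  if (!"CB" %in% rownames(backbone)) {
    if (!"C" %in% rownames(backbone))
      stop("missing backbone atom: CB (and no C to rebuild it from)")
    backbone <- rbind(backbone,
                      CB = build_cb(backbone["N", ], backbone["CA", ],
                                    backbone["C", ]))
  }
  if (length(chi) != 5L || anyNA(chi)) stop("chi must be 5 finite angles")
  pos <- list(N = backbone["N", ], CA = backbone["CA", ],
              CB = backbone["CB", ])
  chi_names <- paste0("chi", 1:5)
  for (i in seq_len(nrow(topo$atoms))) {
    r <- topo$atoms[i, ]
    tors <- if (r$dihedral %in% chi_names)
      chi[match(r$dihedral, chi_names)] else as.numeric(r$dihedral)
    pos[[r$atom]] <- place_atom(pos[[r$p3]], pos[[r$p2]], pos[[r$p1]],
                                r$bond, r$angle, tors)
  }
  atoms <- do.call(rbind, pos)
  structure(list(chi = stats::setNames(wrap_angle(chi), chi_names),
                 atoms = atoms, weight = weight),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("R1 conformer: chi = (%s), weight %.3f\n",
              paste(sprintf("%.1f", x$chi), collapse = ", "), x$weight))
  invisible(x)
}

#' Measure chi1-chi5 from coordinates
#'
#' Applies [dihedral_angle()] to the five 4-atom tuples of the topology's
#' chi definitions.
#'
#' @param coords named coordinate matrix (rownames are atom names, must
#'   include N, CA, CB and all label atoms named by the chi definitions),
#'   or a `conformer`.
#' @param topo a [r1_topology()].
#' @return named numeric length 5, degrees in (-180, 180].
#' @export
measure_chi <- function(coords, topo = r1_topology()) {
  if (inherits(coords, "conformer")) coords <- coords$atoms
  coords <- as.matrix(coords)
  need <- unique(unlist(topo$chi_definitions))
  miss <- setdiff(need, rownames(coords))
  if (length(miss))
    stop("missing atoms for chi measurement: ", paste(miss, collapse = ", "))
  vapply(topo$chi_definitions, function(tt)
    dihedral_angle(coords[tt[1L], ], coords[tt[2L], ],
                   coords[tt[3L], ], coords[tt[4L], ]),
    numeric(1L))
}

# recompute internal coordinates (bond, angle, torsion to the template's
# reference triplet) of a built conformer; used by tests as the template
# round-trip oracle and exported for completeness.

#' Internal coordinates of a conformer relative to its template
#' @param conf a `conformer`.
#' @param topo a [r1_topology()].
#' @return data.frame with measured bond, angle and dihedral per atom.
#' @export
internal_coords <- function(conf, topo = r1_topology()) {
  a <- conf$atoms
  out <- topo$atoms[, c("atom", "p1", "p2", "p3")]
  out$bond <- out$angle <- out$dihedral <- NA_real_
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    out$bond[i] <- vnorm(a[r$atom, ] - a[r$p1, ])
    out$angle[i] <- bond_angle(a[r$p2, ], a[r$p1, ], a[r$atom, ])
    out$dihedral[i] <- dihedral_angle(a[r$p3, ], a[r$p2, ], a[r$p1, ],
                                      a[r$atom, ])
  }
  out
}
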