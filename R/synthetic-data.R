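# Generator of fully specified test systems: an idealized helical fragment
# with a surface R1 site ("open"), the same site occluded by a neighbouring
# chain ("tight"), and synthetic rotamer libraries — all with planted ground
# truth so every pipeline stage can be tested without external downloads.

.bb_geom <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ca_cb = 1.530,
                 ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                 ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5)

#' Idealized poly-alanine helix
#'
#' Builds a single chain with ideal backbone geometry at fixed (phi, psi)
#' (default alpha-helical -57/-47, omega 180) and an ideal CB on every
#' residue.  The fragment stands in for a real protein fold in synthetic
#' labelling-site fixtures.
#'
#' @param n_res number of residues (>= 5).
#' @param phi,psi backbone dihedrals, degrees.
#' @param chain chain identifier.
#' @return a `structure_model` (no crystal cell).
#' @export
make_helix <- function(n_res, phi = -57, psi = -47, chain = "A") {
  if (n_res < 5L) stop("a helix fragment needs at least 5 residues")
  g <- .bb_geom
  pos <- vector("list", n_res)
  # residue 1 in a canonical frame
  n1 <- c(0, 0, 0)
  ca1 <- c(g$n_ca, 0, 0)
  th <- deg2rad(180 - g$ang_n_ca_c)
  c1 <- ca1 + g$ca_c * c(cos(th), sin(th), 0)
  pos[[1L]] <- list(N = n1, CA = ca1, C = c1)
  for (i in 2:n_res) {
    pr <- pos[[i - 1L]]
    n <- place_atom(pr$N, pr$CA, pr$C, g$c_n, g$ang_ca_c_n, psi)
    ca <- place_atom(pr$CA, pr$C, n, g$n_ca, g$ang_c_n_ca, 180)  # omega
    c <- place_atom(pr$C, n, ca, g$ca_c, g$ang_n_ca_c, phi)
    pos[[i]] <- list(N = n, CA = ca, C = c)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    p <- pos[[i]]
    o <- place_atom(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o, psi + 180)
    cb <- build_cb(p$N, p$CA, p$C)
    xyz <- rbind(N = p$N, CA = p$CA, C = p$C, O = o, CB = cb)
    rows[[i]] <- data.frame(
      record = "ATOM", serial = 0L, name = rownames(xyz), altloc = "",
      resname = "ALA", chain = chain, resno = i, icode = "",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occ = 1, b = 0,
      element = substr(rownames(xyz), 1L, 1L), stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$vdw <- vdw_radius(at$element)
  rownames(at) <- NULL
  new_structure_model(at)
}

# replace a residue of `model` with an R1A residue realizing `chi`
attach_r1 <- function(model, chain, resno, chi, topo = r1_topology()) {
  bb <- site_backbone(model, list(chain, resno))
  conf <- build_label(bb, chi, topo)
  at <- model$atoms
  own <- at$chain == chain & at$resno == resno
  keep_bb <- own & at$name %in% c("N", "CA", "C", "O", "CB")
  at <- at[!own | keep_bb, , drop = FALSE]
  at$resname[at$chain == chain & at$resno == resno] <- "R1A"
  at$record[at$chain == chain & at$resno == resno] <- "HETATM"
  side <- conf$atoms[setdiff(rownames(conf$atoms), c("N", "CA", "CB")), ,
                     drop = FALSE]
  add <- data.frame(
    record = "HETATM", serial = 0L, name = rownames(side), altloc = "",
    resname = "R1A", chain = chain, resno = resno, icode = "",
    x = side[, 1L], y = side[, 2L], z = side[, 3L], occ = 1, b = 0,
    element = substr(rownames(side), 1L, 1L), stringsAsFactors = FALSE)
  add$vdw <- vdw_radius(add$element)
  at <- rbind(at, add)
  ord <- order(match(at$chain, unique(at$chain)), at$resno)
  at <- at[ord, , drop = FALSE]
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  m <- new_structure_model(at, cell = model$cell, symmetry = model$symmetry)
  list(model = m, conformer = conf)
}

new_synthetic_site <- function(model, site, planted_chi, regime,
                               occluder = NULL, conformer = NULL) {
  structure(list(model = model, site = site, planted_chi = planted_chi,
                 regime = regime, occluder = occluder,
                 planted_conformer = conformer),
            class = "synthetic_site")
}

#' @export
print.synthetic_site <- function(x, ...) {
  cat(sprintf("synthetic %s site: chain %s residue %s", x$regime,
              x$site[[1L]], x$site[[2L]]))
  if (!is.null(x$planted_chi))
    cat(sprintf(", planted chi (%s)",
                paste(sprintf("%.0f", x$planted_chi), collapse = ", ")))
  if (!is.null(x$occluder)) cat(", occluder chain", x$occluder)
  cat("\n")
  invisible(x)
}

#' Synthetic solvent-exposed ("open") labelling site
#'
#' A helical fragment with an R1 side chain planted at an interior residue
#' in a known chi1-chi5 conformation.  The planted conformer is guaranteed
#' clash-free against the rest of the model at vdW scale 0.9; nothing
#' occludes the label.
#'
#' @param n_res helix length.
#' @param site_index labelled residue (interior: not first/last two).
#' @param planted_chi the ground-truth chi tuple, degrees.
#' @param seed recorded for provenance (construction is deterministic).
#' @return a `synthetic_site` with regime `"open"`.
#' @export
make_open_site <- function(n_res = 18, site_index = 9,
                           planted_chi = c(-60, 180, -60, 180, -90),
                           seed = 1) {
  if (site_index < 3L || site_index > n_res - 2L)
    stop("site_index must be interior to the chain")
  helix <- make_helix(n_res)
  res <- attach_r1(helix, "A", site_index, planted_chi)
  site <- list(chain = "A", resno = site_index)
  env <- clash_environment(res$model, site)
  cc <- clash_count(res$conformer, env, scale = 0.9)
  if (cc > 0)
    stop("planted chi clashes with the fragment (", cc,
         " clashes at scale 0.9); choose a different chi tuple")
  new_synthetic_site(res$model, site, wrap_angle(planted_chi), "open",
                     conformer = res$conformer)
}

# unit helix axis from CA positions (first-half to second-half centroid)
helix_axis <- function(model, chain) {
  ca <- model$atoms[model$atoms$chain == chain &
                      model$atoms$name == "CA", c("x", "y", "z")]
  ca <- as.matrix(ca)
  h <- nrow(ca) %/% 2L
  v <- colMeans(ca[(h + 1L):nrow(ca), , drop = FALSE]) -
    colMeans(ca[1:h, , drop = FALSE])
  v / vnorm(v)
}

#' Synthetic crystal-contact ("tight") labelling site
#'
#' The open-site model plus a second helix placed by a deterministic grid
#' search so that it approaches the planted label to within `occluder_gap`
#' on one side.  The planted conformer remains clash-free (scale 0.9) while
#' a large part of chi space is now sterically blocked, emulating a label at
#' the heart of a crystal contact.
#'
#' @param n_res helix length (both chains).
#' @param site_index labelled residue on chain A.
#' @param planted_chi ground-truth chi tuple, degrees.
#' @param occluder_gap closest allowed occluder-to-label approach,
#'   Angstrom (>= 3.5 so the planted conformer survives).
#' @param seed recorded for provenance (construction is deterministic).
#' @return a `synthetic_site` with regime `"tight"` and occluder chain "B".
#' @export
make_tight_site <- function(n_res = 18, site_index = 9,
                            planted_chi = c(-60, 180, -60, 180, -90),
                            occluder_gap = 3.5, seed = 1) {
  if (occluder_gap < 3.5)
    stop("occluder_gap below 3.5 A would clash with the planted conformer")
  open <- make_open_site(n_res, site_index, planted_chi, seed)
  lab <- clash_atoms(open$planted_conformer)
  lcen <- colMeans(lab)

  u <- helix_axis(open$model, "A")
  ca <- as.matrix(open$model$atoms[open$model$atoms$chain == "A" &
                                     open$model$atoms$name == "CA",
                                   c("x", "y", "z")])
  axis_pt <- colMeans(ca)
  radial <- lcen - axis_pt
  radial <- radial - sum(radial * u) * u
  e1 <- radial / vnorm(radial)
  e3 <- vcross(u, e1)

  occ0 <- make_helix(n_res, chain = "B")
  oat <- occ0$atoms
  oxyz <- as.matrix(oat[, c("x", "y", "z")])
  oxyz <- sweep(oxyz, 2L, colMeans(oxyz))   # centred copy, axis parallel to A

  a_at <- open$model$atoms
  a_xyz <- as.matrix(a_at[a_at$chain == "A", c("x", "y", "z")])
  bb <- site_backbone(open$model, open$site)
  cb <- bb["CB", ]
  topo <- r1_topology()
  # conformers on the canonical chi grid that are allowed at the open site:
  # the occluder placement is scored by how many of them it blocks, a
  # deterministic proxy for "occludes half of chi space"
  grid <- as.matrix(expand.grid(c(-60, 60, 180), c(-60, 60, 180),
                                c(-60, 60, 180), c(-75, 75, 180),
                                c(-90, 90)))
  open_env <- clash_environment(open$model, open$site)
  grid_confs <- lapply(seq_len(nrow(grid)), function(i)
    build_label(bb, grid[i, ], topo))
  grid_free <- vapply(grid_confs, function(cf)
    clash_count(cf, open_env, 0.9) == 0L, logical(1L))
  grid_confs <- grid_confs[grid_free]

  # deterministic search: occluder axis (parallel or crossing), slide
  # direction, and outward anchor offset; the best-scoring valid placement
  # wins (ties resolved by grid order)
  best <- NULL
  best_score <- -1L
  for (ax in list(u, e3)) for (d in list(u, -u, e3, -e3))
    for (r_out in c(4, 6, 8)) {
      ox <- rotate_axis(oxyz, u, ax)
      anchor <- cb + r_out * e1
      placed <- NULL
      for (t in seq(30, 2, by = -0.25)) {
        cand <- sweep(ox, 2L, anchor + t * d, `+`)
        gap_lab <- sqrt(min_d2(cand, lab))
        if (gap_lab < occluder_gap) break   # slid too close to the label
        if (gap_lab > occluder_gap + 0.5) next
        if (sqrt(min_d2(cand, a_xyz)) < 3.0) next  # hits chain A itself
        placed <- cand
        break
      }
      if (is.null(placed)) next
      env_b <- data.frame(x = placed[, 1L], y = placed[, 2L],
                          z = placed[, 3L], vdw = oat$vdw)
      score <- sum(vapply(grid_confs, function(cf)
        clash_count(cf, env_b, 0.9) > 0L, logical(1L)))
      if (score > best_score) { best <- placed; best_score <- score }
    }
  placed <- best
  if (is.null(placed))
    stop("could not place an occluder satisfying the gap constraints")
  oat$x <- placed[, 1L]; oat$y <- placed[, 2L]; oat$z <- placed[, 3L]
  at <- rbind(open$model$atoms, oat)
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  model <- new_structure_model(at)
  env <- clash_environment(model, open$site)
  cc <- clash_count(open$planted_conformer, env, scale = 0.9)
  if (cc > 0)
    stop("internal error: occluder placement broke the planted conformer (",
         cc, " clashes)")
  new_synthetic_site(model, open$site, open$planted_chi, "tight",
                     occluder = "B", conformer = open$planted_conformer)
}

# rotate a coordinate set so that direction `from` maps onto `to`
# (Rodrigues formula)
rotate_axis <- function(xyz, from, to) {
  v <- vcross(from, to)
  s <- vnorm(v)
  cc <- sum(from * to)
  if (s < 1e-9) return(if (cc > 0) xyz else -xyz)
  vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
               3L, 3L, byrow = TRUE)
  xyz %*% t(diag(3) + vx + vx %*% vx * ((1 - cc) / s^2))
}

# squared minimum distance between two coordinate matrices
min_d2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  min(pmax(d2, 0))
}

# von Mises sampler (Best & Fisher rejection scheme); mu, output in radians
rvonmises <- function(n, mu, kappa) {
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3L)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3L] - 0.5) * acos(max(-1, min(1, f)))
    }
  }
  out
}

.synlib_spec <- list(
  chi1 = list(centers = c(-60, 60, 180), kappa_scale = 1),
  chi2 = list(centers = c(-60, 60, 180), kappa_scale = 1),
  chi3 = list(centers = c(-60, 60, 180), kappa_scale = 1),
  chi4 = list(centers = c(-75, 75, 180), kappa_scale = 1 / 4),
  chi5 = list(centers = c(-90, 90), kappa_scale = 1 / 8))

#' Synthetic rotamer library
#'
#' Emulates the shape of an MD-derived R1 rotamer library: chi1-chi3 are
#' drawn from von Mises mixtures at the canonical minima (-60, 60, 180)
#' with concentration `concentration`; chi4 and chi5, which are genuinely
#' broader for the free label, use wider mixtures (centers -75/75/180 at a
#' quarter, and -90/90 at an eighth, of the concentration).  Priors are
#' Dirichlet-uniform.  The generating parameters are recorded in the
#' metadata so tests can use them as ground truth.
#'
#' @param n_entries number of rotamers (>= 3).
#' @param concentration von Mises concentration for chi1-chi3
#'   (dimensionless; `Inf` collapses every angle onto a mixture centre).
#' @param seed integer seed (private RNG stream).
#' @return a `rotamer_library` with generation metadata.
#' @export
make_synthetic_library <- function(n_entries = 200, concentration = 20,
                                   seed = 1) {
  if (n_entries < 3L) stop("a library needs at least 3 entries")
  spec <- .synlib_spec
  with_private_rng(seed, function() {
    chi <- matrix(NA_real_, n_entries, 5L)
    for (k in 1:5) {
      s <- spec[[k]]
      comp <- sample.int(length(s$centers), n_entries, replace = TRUE)
      kap <- concentration * s$kappa_scale
      for (j in seq_along(s$centers)) {
        idx <- which(comp == j)
        if (length(idx))
          chi[idx, k] <- wrap_angle(rad2deg(
            rvonmises(length(idx), deg2rad(s$centers[j]), kap)))
      }
    }
    w <- stats::rgamma(n_entries, shape = 1)
    entries <- as.data.frame(chi)
    names(entries) <- paste0("chi", 1:5)
    entries$weight <- w
    new_rotamer_library(entries, name = sprintf("synthetic-vM-%d", n_entries),
                        chi5_convention = "SD-CE-C3-C4",
                        generation = list(spec = spec,
                                          concentration = concentration,
                                          seed = seed))
  })
}
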