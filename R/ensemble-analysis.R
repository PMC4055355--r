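# Comparison metrics: spin centers and occupancy-weighted means, inter-label
# distance distributions, distance-vector angles, Shrake-Rupley surface
# areas, chi deviations from a library, and residue contact listings.

#' Spin-center of a conformer
#'
#' The point standing in for the unpaired electron: the nitroxide N1 atom or
#' the midpoint of the N1-O1 bond.  The rule in use is carried through every
#' downstream report.
#'
#' @param conf a `conformer` (or any named coordinate matrix with N1/O1).
#' @param rule `"N1"` or `"NO_midpoint"`.
#' @return numeric length-3 Cartesian point.
#' @export
spin_center <- function(conf, rule = c("NO_midpoint", "N1")) {
  rule <- match.arg(rule)
  a <- if (inherits(conf, "conformer")) conf$atoms else as.matrix(conf)
  if (!"N1" %in% rownames(a)) stop("missing nitroxide atom N1")
  if (rule == "N1") return(a["N1", ])
  if (!"O1" %in% rownames(a)) stop("missing nitroxide atom O1")
  (a["N1", ] + a["O1", ]) / 2
}

ensemble_centers <- function(ens, rule = "NO_midpoint") {
  if (!length(ens$conformers)) stop("empty ensemble")
  t(vapply(ens$conformers, function(cf) spin_center(cf, rule), numeric(3L)))
}

#' Occupancy-weighted mean spin position of an ensemble
#'
#' `sum_i w_i * center_i`; for equal weights (the accessible-volume case)
#' this is the plain centroid of the spin centers.
#'
#' @param ens a `label_ensemble`.
#' @param rule spin-center rule, see [spin_center()].
#' @return numeric length-3 point.
#' @export
mean_spin_position <- function(ens, rule = "NO_midpoint") {
  ctr <- ensemble_centers(ens, rule)
  w <- ensemble_weights(ens)
  as.numeric(t(ctr) %*% w)
}

#' Distance between two label ensembles
#'
#' Returns the distance between the occupancy-weighted mean spin positions
#' together with the full weighted pair-distance distribution (the
#' PELDOR-like histogram over all conformer pairs, pair weight `w_i * w_j`).
#'
#' @param a,b `label_ensemble` objects.
#' @param rule spin-center rule.
#' @param breaks histogram bin width in Angstrom.
#' @return list with `mean_position_distance`, `distribution` (data.frame
#'   distance/probability), `pair_mean`, `pair_sd` and the rule used.
#' @export
ensemble_distance <- function(a, b, rule = "NO_midpoint", breaks = 0.5) {
  ca <- ensemble_centers(a, rule); cb <- ensemble_centers(b, rule)
  wa <- ensemble_weights(a); wb <- ensemble_weights(b)
  mpd <- vnorm(as.numeric(t(ca) %*% wa) - as.numeric(t(cb) %*% wb))
  # all pairwise center distances, weights outer(wa, wb)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * ca %*% t(cb)
  d <- sqrt(pmax(d2, 0))
  w <- outer(wa, wb)
  pm <- sum(w * d)
  psd <- sqrt(max(0, sum(w * d^2) - pm^2))
  bin <- floor(d / breaks)
  agg <- tapply(as.numeric(w), as.numeric(bin), sum)
  dist_tab <- data.frame(
    distance = (as.numeric(names(agg)) + 0.5) * breaks,
    probability = as.numeric(agg))
  dist_tab <- dist_tab[order(dist_tab$distance), , drop = FALSE]
  rownames(dist_tab) <- NULL
  list(mean_position_distance = mpd, distribution = dist_tab,
       pair_mean = pm, pair_sd = psd, rule = rule)
}

#' Angle between an experimental and a predicted distance vector
#'
#' @param experimental,predicted 2 x 3 matrices (rows: the two site points).
#' @return angle in degrees in `[0, 180]`.
#' @export
vector_angle_deviation <- function(experimental, predicted) {
  ve <- as.numeric(experimental[2L, ] - experimental[1L, ])
  vp <- as.numeric(predicted[2L, ] - predicted[1L, ])
  if (vnorm(ve) < 1e-9 || vnorm(vp) < 1e-9)
    stop("zero-length distance vector")
  rad2deg(acos(max(-1, min(1, sum(ve * vp) / (vnorm(ve) * vnorm(vp))))))
}

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible and buried surface area (Shrake-Rupley)
#'
#' Numeric SASA with deterministic golden-spiral quadrature points on each
#' atom's solvent-expanded sphere.  The buried area of the selection is the
#' area it exposes with only its own chain(s) as context minus the area in
#' the full model context, the usual interface bookkeeping.
#'
#' @param model a `structure_model` providing the context (hydrogens and, by
#'   default, solvent are ignored).
#' @param select logical or integer index into `model$atoms`, or a list with
#'   `chain` and `resno` naming one residue.
#' @param probe probe radius, Angstrom.
#' @param n_points quadrature points per atom (>= 100).
#' @param include_solvent keep solvent molecules in the context.
#' @return a `surface_report`: list with `total_asa`, `buried_asa`,
#'   `per_atom` (named areas, full context), `probe`, `n_points`.
#' @export
sasa <- function(model, select, probe = 1.4, n_points = 960,
                 include_solvent = FALSE) {
  stopifnot(probe > 0, n_points >= 100)
  at <- model$atoms
  ctx <- at$element != "H"
  if (!include_solvent)
    ctx <- ctx & (at$record != "HETATM" |
                    toupper(at$resname) %in% c(.metal_resnames, "R1A"))
  if (is.list(select) && !is.null(select$chain))
    sel <- at$chain == select$chain & at$resno == as.integer(select$resno)
  else if (is.logical(select)) sel <- select
  else sel <- seq_len(nrow(at)) %in% select
  sel <- sel & at$element != "H"
  if (!any(sel)) stop("empty atom selection")
  own_chains <- unique(at$chain[sel])

  full <- .sr_areas(at, sel, ctx, probe, n_points)
  own <- .sr_areas(at, sel, ctx & at$chain %in% own_chains, probe, n_points)
  structure(list(total_asa = sum(full), buried_asa = sum(own) - sum(full),
                 per_atom = full, own_context_asa = sum(own),
                 probe = probe, n_points = n_points),
            class = "surface_report")
}

# per-atom Shrake-Rupley areas of at[sel,] against context atoms at[ctx,]
.sr_areas <- function(at, sel, ctx, probe, n_points) {
  pts <- sphere_points(n_points)
  isel <- which(sel)
  cx <- at$x[ctx]; cy <- at$y[ctx]; cz <- at$z[ctx]
  cr <- at$vdw[ctx] + probe
  cid <- which(ctx)
  areas <- numeric(length(isel))
  for (j in seq_along(isel)) {
    i <- isel[j]
    ri <- at$vdw[i] + probe
    # neighbours whose expanded spheres can cover points of atom i
    d2 <- (cx - at$x[i])^2 + (cy - at$y[i])^2 + (cz - at$z[i])^2
    nb <- which(d2 < (ri + cr)^2 & d2 > 1e-12 & cid != i)
    if (!length(nb)) { areas[j] <- 4 * pi * ri^2; next }
    p <- sweep(pts * ri, 2L, c(at$x[i], at$y[i], at$z[i]), `+`)
    free <- rep(TRUE, n_points)
    # order neighbours by proximity so the most occluding are tested first
    nb <- nb[order(d2[nb])]
    for (k in nb) {
      if (!any(free)) break
      dd <- (p[free, 1L] - cx[k])^2 + (p[free, 2L] - cy[k])^2 +
        (p[free, 3L] - cz[k])^2
      free[free] <- dd >= cr[k]^2
    }
    areas[j] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  names(areas) <- paste(at$chain[isel], at$resno[isel], at$name[isel],
                        sep = "/")
  areas
}

#' @export
print.surface_report <- function(x, ...) {
  cat(sprintf("surface_report: total ASA %.1f A^2, buried %.1f A^2 (probe %.1f A, %d pts/atom)\n",
              x$total_asa, x$buried_asa, x$probe, x$n_points))
  invisible(x)
}

#' Deviation of observed chi angles from a rotamer library
#'
#' Finds the library entry nearest to the observed angles under the
#' max-over-angles circular distance and reports the per-angle signed
#' circular differences.
#'
#' @param observed numeric length 5, degrees.
#' @param library a `rotamer_library`.
#' @param convention optional chi5 convention tag of the measurement; if
#'   both this and the library's tag are set they must agree.
#' @return list with `nearest` (row index), `nearest_chi`, `delta` (signed,
#'   per angle) and `max_abs_delta`.
#' @export
chi_deviation <- function(observed, library, convention = NULL) {
  stopifnot(inherits(library, "rotamer_library"))
  libconv <- library$metadata$chi5_convention
  if (!is.null(convention) && !is.null(libconv) &&
      !identical(convention, libconv))
    stop("chi5 convention mismatch: observed '", convention,
         "' vs library '", libconv, "'")
  m <- as.matrix(library$entries[, 1:5])
  dmat <- abs(circular_diff(m, matrix(observed, nrow(m), 5L, byrow = TRUE)))
  worst <- apply(dmat, 1L, max)
  i <- which.min(worst)
  list(nearest = unname(i),
       nearest_chi = as.numeric(m[i, ]),
       delta = unname(circular_diff(observed, as.numeric(m[i, ]))),
       max_abs_delta = unname(worst[i]))
}

#' Contacts of one residue with its surroundings
#'
#' Distance-based re-implementation of a Ligplot-style contact listing: a
#' van der Waals contact when the heavy-atom distance is below
#' `r_i + r_j + vdw_slack`, a polar contact when both atoms are N or O
#' within `polar_cutoff`.  Solvent is included (ordered waters mediate real
#' label contacts).
#'
#' @param model a `structure_model`.
#' @param chain,resno the residue whose contacts are listed.
#' @param vdw_slack Angstrom added to the radii sum.
#' @param polar_cutoff Angstrom.
#' @return data.frame: one row per contact (atom, partner, distance, type,
#'   same_chain); zero rows when isolated.
#' @export
contacts <- function(model, chain, resno, vdw_slack = 0.5,
                     polar_cutoff = 3.5) {
  at <- model$atoms
  own <- which(at$chain == chain & at$resno == as.integer(resno) &
                 at$element != "H")
  if (!length(own)) stop("residue ", resno, "/", chain, " not found")
  oth <- which(!(at$chain == chain & at$resno == as.integer(resno)) &
                 at$element != "H")
  out <- list()
  for (i in own) {
    d <- sqrt((at$x[oth] - at$x[i])^2 + (at$y[oth] - at$y[i])^2 +
                (at$z[oth] - at$z[i])^2)
    vlim <- at$vdw[i] + at$vdw[oth] + vdw_slack
    polar <- at$element[i] %in% c("N", "O") &
      at$element[oth] %in% c("N", "O") & d < polar_cutoff
    vdw <- d < vlim & !polar
    hit <- which(polar | vdw)
    if (!length(hit)) next
    j <- oth[hit]
    out[[length(out) + 1L]] <- data.frame(
      atom = at$name[i],
      partner_chain = at$chain[j], partner_resno = at$resno[j],
      partner_resname = at$resname[j], partner_atom = at$name[j],
      distance = d[hit],
      type = ifelse(polar[hit], "polar", "vdw"),
      same_chain = at$chain[j] == chain,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(atom = character(), partner_chain = character(),
                      partner_resno = integer(),
                      partner_resname = character(),
                      partner_atom = character(), distance = numeric(),
                      type = character(), same_chain = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$partner_chain, res$partner_resno, res$distance), ,
      drop = FALSE]
}

#' Plot a label ensemble
#'
#' Polar scatter of the five chi angles (radius = angle index) plus a
#' weighted pair-distance histogram panel when a second ensemble is given.
#'
#' @param x a `label_ensemble`.
#' @param against optional second ensemble for a distance panel.
#' @param ... ignored.
#' @export
plot.label_ensemble <- function(x, against = NULL, ...) {
  if (!length(x$conformers)) stop("empty ensemble")
  ch <- t(vapply(x$conformers, `[[`, numeric(5L), "chi"))
  w <- ensemble_weights(x)
  op <- graphics::par(mfrow = c(1, if (is.null(against)) 1 else 2))
  on.exit(graphics::par(op))
  th <- deg2rad(ch)
  r <- matrix(rep(1:5, each = nrow(ch)), nrow(ch))
  graphics::plot(NA, xlim = c(-5.5, 5.5), ylim = c(-5.5, 5.5), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = paste0(x$method, " ensemble: chi1 (inner) to chi5"))
  for (k in 1:5) graphics::symbols(0, 0, circles = k, inches = FALSE,
                                   add = TRUE, fg = "grey80")
  graphics::points(r * cos(th), r * sin(th), pch = 16,
                   cex = 0.4 + 2 * w / max(w),
                   col = grDevices::adjustcolor("steelblue", 0.6))
  if (!is.null(against)) {
    ed <- ensemble_distance(x, against)
    graphics::plot(ed$distribution$distance, ed$distribution$probability,
                   type = "h", xlab = "distance (A)", ylab = "probability",
                   main = sprintf("pair distances (mean-pos. %.1f A)",
                                  ed$mean_position_distance))
  }
  invisible(x)
}
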