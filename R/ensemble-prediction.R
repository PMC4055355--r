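# The two prediction paradigms: accessible-volume sampling (random chi,
# equal weights for sterically allowed conformers) and rotamer-library
# placement (discrete chi tuples, Boltzmann-reweighted by a soft clash
# energy, with a partition function).

.metal_resnames <- c("CU", "ZN", "CU1", "FE", "FE2", "MG", "MN", "CA",
                     "NA", "K", "NI", "CO", "CD")
.solvent_resnames <- c("HOH", "WAT", "DOD", "GOL", "EDO", "PEG", "SO4",
                       "NO3", "PO4", "CAC", "CL", "ACT", "TRS")

#' Clash environment of a labelling site
#'
#' Extracts the heavy atoms a label built at `site` can clash with: all
#' protein atoms except the site residue itself, plus metal ions.  Solvent
#' and cryo-protectant molecules are excluded by default (neither prediction
#' paradigm uses them), which is itself one of the approximations the
#' benchmark probes; set `include_solvent = TRUE` to keep them.
#'
#' @param model a `structure_model`.
#' @param site list or vector `(chain, resno)`.
#' @param include_solvent keep water/cryo-protectant/buffer molecules.
#' @return data.frame of environment atoms with coordinates and vdW radii.
#' @export
clash_environment <- function(model, site, include_solvent = FALSE) {
  at <- model$atoms
  keep <- at$element != "H"
  own <- at$chain == site[[1L]] & at$resno == as.integer(site[[2L]])
  keep <- keep & !own
  het <- at$record == "HETATM"
  res <- toupper(at$resname)
  if (!include_solvent)
    keep <- keep & (!het | res %in% .metal_resnames | res == "R1A")
  at[keep, c("name", "resname", "chain", "resno", "x", "y", "z", "vdw")]
}

# label atoms entering clash checks: everything the chi angles move (CB and
# the backbone are part of the protein itself)
clash_atoms <- function(conf) {
  conf$atoms[setdiff(rownames(conf$atoms), c("N", "CA", "CB", "C", "O")), ,
             drop = FALSE]
}

#' Count steric clashes between a conformer and its environment
#'
#' A pair clashes when its distance is below `scale` times the sum of the
#' two van der Waals radii.  The count is an exact all-pairs result (a
#' bounding-box prefilter only skips atoms that provably cannot clash).
#'
#' @param conf a `conformer`.
#' @param env environment atom table from [clash_environment()] (or any
#'   data.frame with x, y, z, vdw columns).
#' @param scale vdW scaling factor in (0, 1.5].
#' @return integer clash count.
#' @export
clash_count <- function(conf, env, scale = 0.75) {
  la <- clash_atoms(conf)
  if (is.null(la) || nrow(la) == 0L) stop("conformer has no label atoms")
  if (scale <= 0 || scale > 1.5) stop("scale must be in (0, 1.5]")
  if (nrow(env) == 0L) return(0L)
  lr <- vdw_radius(substr(rownames(la), 1L, 1L))
  .clash_count_xyz(la, lr, env, scale)
}

.clash_count_xyz <- function(lxyz, lr, env, scale) {
  ex <- env$x; ey <- env$y; ez <- env$z; er <- env$vdw
  maxr <- scale * (max(lr) + max(er))
  lo <- apply(lxyz, 2L, min) - maxr; hi <- apply(lxyz, 2L, max) + maxr
  inbox <- ex >= lo[1L] & ex <= hi[1L] & ey >= lo[2L] & ey <= hi[2L] &
    ez >= lo[3L] & ez <= hi[3L]
  if (!any(inbox)) return(0L)
  ex <- ex[inbox]; ey <- ey[inbox]; ez <- ez[inbox]; er <- er[inbox]
  n <- 0L
  for (i in seq_len(nrow(lxyz))) {
    d2 <- (ex - lxyz[i, 1L])^2 + (ey - lxyz[i, 2L])^2 + (ez - lxyz[i, 3L])^2
    lim <- (scale * (lr[i] + er))^2
    n <- n + sum(d2 < lim)
  }
  as.integer(n)
}

# soft quartic overlap penalty: E = sum eps * max(0, scale*(ri+rj) - d)^4,
# smooth and monotone in overlap; eps = 1 kT_eff per A^4
clash_energy <- function(conf, env, scale = 0.75, eps = 1) {
  la <- clash_atoms(conf)
  if (nrow(env) == 0L) return(0)
  lr <- vdw_radius(substr(rownames(la), 1L, 1L))
  e <- 0
  for (i in seq_len(nrow(la))) {
    d <- sqrt((env$x - la[i, 1L])^2 + (env$y - la[i, 2L])^2 +
                (env$z - la[i, 3L])^2)
    ov <- pmax(0, scale * (lr[i] + env$vdw) - d)
    e <- e + eps * sum(ov^4)
  }
  e
}

# backbone of the site residue as required by build_label; rebuilds CB with
# ideal cysteine geometry when absent
site_backbone <- function(model, site) {
  rc <- residue_coords(model, site[[1L]], as.integer(site[[2L]]))
  if (!all(c("N", "CA") %in% rownames(rc)))
    stop("site residue lacks backbone N/CA")
  if (!"CB" %in% rownames(rc)) {
    if (!"C" %in% rownames(rc)) stop("site residue lacks CB and C")
    rc <- rbind(rc, CB = build_cb(rc["N", ], rc["CA", ], rc["C", ]))
  }
  rc[intersect(c("N", "CA", "C", "CB"), rownames(rc)), , drop = FALSE]
}

new_label_ensemble <- function(site, method, conformers, partition_function,
                               n_trials, params, diagnostic = NULL) {
  w <- vapply(conformers, `[[`, numeric(1L), "weight")
  if (length(w) && abs(sum(w) - 1) > 1e-9)
    stop("internal error: ensemble weights do not sum to 1")
  structure(list(site = site, method = method, conformers = conformers,
                 partition_function = partition_function,
                 n_trials = n_trials, params = params,
                 diagnostic = diagnostic),
            class = "label_ensemble")
}

#' @export
print.label_ensemble <- function(x, ...) {
  cat(sprintf("label_ensemble [%s] at %s/%s: %d conformer(s), p.f. %.4g",
              x$method, x$site[[1L]], x$site[[2L]], length(x$conformers),
              x$partition_function))
  if (!is.null(x$params$acceptance_fraction))
    cat(sprintf(", acceptance %.3f", x$params$acceptance_fraction))
  cat("\n")
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' @export
summary.label_ensemble <- function(object, ...) {
  w <- ensemble_weights(object)
  ch <- t(vapply(object$conformers, `[[`, numeric(5L), "chi"))
  out <- list(method = object$method, site = object$site,
              n = length(object$conformers),
              partition_function = object$partition_function,
              weight_range = range(w),
              chi_mean = if (nrow(ch)) apply(ch, 2L, circular_mean) else NULL)
  class(out) <- "summary.label_ensemble"
  out
}

#' @export
print.summary.label_ensemble <- function(x, ...) {
  cat(sprintf("%s ensemble, site %s/%s: %d conformers, p.f. %.4g\n",
              x$method, x$site[[1L]], x$site[[2L]], x$n,
              x$partition_function))
  if (!is.null(x$chi_mean))
    cat(sprintf("  circular mean chi: %s\n",
                paste(sprintf("%.1f", x$chi_mean), collapse = ", ")))
  invisible(x)
}

ensemble_weights <- function(ens)
  vapply(ens$conformers, `[[`, numeric(1L), "weight")

circular_mean <- function(deg) {
  r <- deg2rad(deg)
  wrap_angle(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

# run body with a private, seeded RNG stream; the caller's RNG state is
# untouched
with_private_rng <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  body()
}

#' Accessible-volume prediction of an R1 label ensemble
#'
#' The accessible-volume paradigm: chi1-chi5 are drawn uniformly on
#' (-180, 180]^5, the conformer is built with rigid template geometry, and
#' it is accepted if its clash count against the environment does not exceed
#' `max_clashes`.  Accepted conformers carry equal weight.
#'
#' @param model a `structure_model`.
#' @param site list or vector `(chain, resno)`.
#' @param n_conformers number of accepted conformers to collect.
#' @param max_trials sampling budget.
#' @param scale vdW scaling for the clash criterion (loose 0.75 default, the
#'   customary accessible-volume setting).
#' @param max_clashes accepted conformers may have at most this many clashes.
#' @param seed integer seed; the call owns a private RNG stream.
#' @param topo label topology.
#' @param include_solvent forwarded to [clash_environment()].
#' @return a `label_ensemble`; empty (with a diagnostic) if nothing is
#'   accepted within `max_trials`.
#' @export
sample_accessible_volume <- function(model, site, n_conformers = 200,
                                     max_trials = 50000, scale = 0.75,
                                     max_clashes = 5, seed = 1,
                                     topo = r1_topology(),
                                     include_solvent = FALSE) {
  bb <- site_backbone(model, site)
  env <- clash_environment(model, site, include_solvent)
  # prune the environment once to the label's maximal reach around CB
  reach <- sum(topo$atoms$bond) + 4
  d2 <- (env$x - bb["CB", 1L])^2 + (env$y - bb["CB", 2L])^2 +
    (env$z - bb["CB", 3L])^2
  env <- env[d2 <= reach^2, , drop = FALSE]

  params <- list(n_conformers = n_conformers, max_trials = max_trials,
                 scale = scale, max_clashes = max_clashes, seed = seed)
  res <- with_private_rng(seed, function() {
    acc <- vector("list", n_conformers)
    n_acc <- 0L
    trials <- 0L
    while (n_acc < n_conformers && trials < max_trials) {
      trials <- trials + 1L
      chi <- stats::runif(5L, -180, 180)
      conf <- build_label(bb, chi, topo)
      if (clash_count(conf, env, scale) <= max_clashes) {
        n_acc <- n_acc + 1L
        acc[[n_acc]] <- conf
      }
    }
    list(acc = acc[seq_len(n_acc)], trials = trials)
  })
  n_acc <- length(res$acc)
  params$acceptance_fraction <- if (res$trials > 0) n_acc / res$trials else 0
  if (n_acc == 0L)
    return(new_label_ensemble(site, "accessible_volume", list(), 0,
                              res$trials, params,
                              diagnostic = "no conformer accepted: site appears fully buried"))
  confs <- lapply(res$acc, function(cf) { cf$weight <- 1 / n_acc; cf })
  new_label_ensemble(site, "accessible_volume", confs,
                     partition_function = n_acc, n_trials = res$trials,
                     params = params)
}

#' Rotamer-library prediction of an R1 label ensemble
#'
#' Builds every library entry at the site and reweights its prior by a
#' Boltzmann factor of the soft clash energy,
#' `w_i = prior_i * exp(-E_i / kT_eff)`.  Entries whose hard clash count
#' exceeds `hard_max_clashes` are discarded.  The partition function is the
#' sum of unnormalized weights over retained entries; with no environment it
#' equals 1 (the free-label limit, where the ensemble reproduces the library
#' priors exactly).
#'
#' @param model a `structure_model`.
#' @param site list or vector `(chain, resno)`.
#' @param library a `rotamer_library`.
#' @param scale vdW scaling for both the soft energy and the hard count.
#' @param temperature_factor multiplies the effective kT (1 arbitrary energy
#'   unit); as it approaches 0 the weight concentrates on the minimum-energy
#'   rotamer.
#' @param hard_max_clashes discard threshold on the hard clash count.
#' @param topo label topology.
#' @param include_solvent forwarded to [clash_environment()].
#' @return a `label_ensemble`; empty (with diagnostic) if every entry is
#'   discarded.
#' @export
place_rotamers <- function(model, site, library, scale = 0.75,
                           temperature_factor = 1, hard_max_clashes = 5,
                           topo = r1_topology(), include_solvent = FALSE) {
  stopifnot(inherits(library, "rotamer_library"))
  if (temperature_factor <= 0) stop("temperature_factor must be positive")
  bb <- site_backbone(model, site)
  env <- clash_environment(model, site, include_solvent)
  reach <- sum(topo$atoms$bond) + 4
  d2 <- (env$x - bb["CB", 1L])^2 + (env$y - bb["CB", 2L])^2 +
    (env$z - bb["CB", 3L])^2
  env <- env[d2 <= reach^2, , drop = FALSE]

  kt <- temperature_factor
  n <- nrow(library$entries)
  keep <- logical(n)
  w <- numeric(n)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    conf <- build_label(bb, as.numeric(library$entries[i, 1:5]), topo)
    if (clash_count(conf, env, scale) > hard_max_clashes) next
    e <- clash_energy(conf, env, scale)
    keep[i] <- TRUE
    w[i] <- library$entries$weight[i] * exp(-e / kt)
    confs[[i]] <- conf
  }
  params <- list(scale = scale, temperature_factor = temperature_factor,
                 hard_max_clashes = hard_max_clashes,
                 library = library$metadata$name,
                 chi5_convention = topo$chi5_convention)
  pf <- sum(w[keep])
  if (!any(keep) || pf <= 0)
    return(new_label_ensemble(site, "rotamer", list(), 0, n, params,
                              diagnostic = "all library entries discarded at this site"))
  confs <- confs[keep]
  wk <- w[keep] / pf
  for (i in seq_along(confs)) confs[[i]]$weight <- wk[i]
  new_label_ensemble(site, "rotamer", confs, partition_function = pf,
                     n_trials = n, params = params)
}

#' Predict a label ensemble at a site (front door)
#'
#' Thin dispatcher over the two paradigms, returning the same
#' `label_ensemble` class either way.
#'
#' @param model a `structure_model`.
#' @param site `(chain, resno)`.
#' @param method `"accessible_volume"` or `"rotamer"`.
#' @param library rotamer library (required for the rotamer method).
#' @param ... forwarded to [sample_accessible_volume()] or
#'   [place_rotamers()].
#' @return a `label_ensemble`.
#' @export
spin_label <- function(model, site,
                       method = c("accessible_volume", "rotamer"),
                       library = NULL, ...) {
  method <- match.arg(method)
  if (method == "accessible_volume")
    sample_accessible_volume(model, site, ...)
  else {
    if (is.null(library)) stop("the rotamer method needs a library")
    place_rotamers(model, site, library, ...)
  }
}
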