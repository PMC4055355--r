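# End-to-end benchmark: build the packing assembly, label every site with
# both paradigms, and compare predicted ensembles to any experimentally
# observed label conformations (chi deviations, inter-label distances,
# distance-vector angles, surface areas).

#' Benchmark configuration
#'
#' @param sites list of `(chain, resno)` sites.
#' @param methods subset of `c("accessible_volume", "rotamer")`.
#' @param library rotamer library (needed when the rotamer method runs).
#' @param packing_cutoff Angstrom for crystal-packing expansion (0 = none).
#' @param spin_rule spin-center rule used throughout the report; the
#'   experimental centers of observed labels use the same rule so the
#'   comparison is internally consistent.
#' @param seed integer master seed; per-site streams are derived from it.
#' @param n_conformers,max_trials,scale,max_clashes accessible-volume
#'   parameters.
#' @param temperature_factor,hard_max_clashes rotamer-method parameters.
#' @param env_radius Angstrom: radius of the environment sphere a site needs
#'   for its prediction to count as complete.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(sites,
                             methods = c("accessible_volume", "rotamer"),
                             library = NULL, packing_cutoff = 0,
                             spin_rule = "N1", seed = 1,
                             n_conformers = 200, max_trials = 50000,
                             scale = 0.75, max_clashes = 5,
                             temperature_factor = 1, hard_max_clashes = 5,
                             env_radius = 10) {
  stopifnot(length(sites) >= 1L, length(methods) >= 1L)
  methods <- match.arg(methods, c("accessible_volume", "rotamer"),
                       several.ok = TRUE)
  if ("rotamer" %in% methods && is.null(library))
    stop("the rotamer method needs a library")
  structure(list(sites = sites, methods = methods, library = library,
                 packing_cutoff = packing_cutoff, spin_rule = spin_rule,
                 seed = as.integer(seed), n_conformers = n_conformers,
                 max_trials = max_trials, scale = scale,
                 max_clashes = max_clashes,
                 temperature_factor = temperature_factor,
                 hard_max_clashes = hard_max_clashes,
                 env_radius = env_radius),
            class = "benchmark_config")
}

#' Build the packing assembly for a benchmark
#'
#' Expands the crystal packing around every site's chain (union of contact
#' images), strips solvent and cryo-protectant molecules (metal ions and R1
#' labels are kept), and flags each site whose environment sphere is
#' truncated by the selection — i.e. some lattice image approaches the site
#' within `env_radius` but is not part of the assembly.  Predictions at
#' flagged sites would see an artificially open environment.
#'
#' @param model a `structure_model`.
#' @param sites list of `(chain, resno)`.
#' @param cutoff packing-expansion contact cutoff, Angstrom; 0 skips
#'   expansion (monomeric/synthetic input).
#' @param env_radius completeness radius, Angstrom.
#' @return list: `model` (the assembly) and `site_complete` (named logical).
#' @export
build_benchmark_assembly <- function(model, sites, cutoff, env_radius = 10) {
  for (s in sites)
    residue_coords(model, s[[1L]], as.integer(s[[2L]]))  # errors if absent
  asm <- model
  if (cutoff > 0) {
    # expand around each site's chain from the original model and merge,
    # de-duplicating image chains by their lattice tag
    pieces <- list(model$atoms)
    seen <- unique(model$atoms$chain)
    for (s in sites) {
      ex <- expand_packing(model, s[[1L]], cutoff)
      newch <- setdiff(unique(ex$atoms$chain), seen)
      if (length(newch)) {
        pieces[[length(pieces) + 1L]] <-
          ex$atoms[ex$atoms$chain %in% newch, , drop = FALSE]
        seen <- c(seen, newch)
      }
    }
    asm <- new_structure_model(do.call(rbind, pieces), cell = model$cell,
                               symmetry = model$symmetry)
  }
  at <- asm$atoms
  res <- toupper(at$resname)
  keep <- at$record != "HETATM" | res %in% c(.metal_resnames, "R1A")
  at <- at[keep, , drop = FALSE]
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  asm <- new_structure_model(at, cell = asm$cell, symmetry = asm$symmetry)

  complete <- vapply(sites, function(s) {
    site_env_complete(model, asm, s, env_radius)
  }, logical(1L))
  names(complete) <- vapply(sites, function(s)
    paste0(s[[1L]], "/", s[[2L]]), character(1L))
  list(model = asm, site_complete = complete)
}

# a site's environment is complete when every lattice image that comes
# within env_radius of the site residue is represented in the assembly
site_env_complete <- function(model, assembly, site, env_radius) {
  if (is.null(model$cell)) return(TRUE)
  own <- model$atoms$chain == site[[1L]] &
    model$atoms$resno == as.integer(site[[2L]])
  probe <- model$atoms[own, , drop = FALSE]
  probe$chain <- ".site."
  aug <- new_structure_model(rbind(model$atoms, probe),
                             cell = model$cell, symmetry = model$symmetry)
  ex <- expand_packing(aug, ".site.", env_radius)
  needed <- setdiff(unique(ex$atoms$chain), unique(aug$atoms$chain))
  needed <- grep(".site.", needed, fixed = TRUE, invert = TRUE,
                 value = TRUE)
  all(needed %in% unique(assembly$atoms$chain))
}

site_key <- function(s) paste0(s[[1L]], "/", s[[2L]])

# observed R1 label at a site, if the input carries one
observed_label <- function(model, site, topo) {
  rc <- tryCatch(residue_coords(model, site[[1L]], as.integer(site[[2L]])),
                 error = function(e) NULL)
  if (is.null(rc)) return(NULL)
  need <- unique(unlist(topo$chi_definitions))
  if (!all(need %in% rownames(rc))) return(NULL)
  list(chi = measure_chi(rc, topo), coords = rc)
}

# strip an observed label to backbone + CB so prediction starts from the
# unlabelled site
strip_label <- function(model, site) {
  at <- model$atoms
  own <- at$chain == site[[1L]] & at$resno == as.integer(site[[2L]])
  at <- at[!own | at$name %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  rownames(at) <- NULL
  new_structure_model(at, cell = model$cell, symmetry = model$symmetry)
}

#' Run the full labelling benchmark
#'
#' For every configured site: strip any observed label to backbone + CB,
#' predict an ensemble with every configured method, record the observed
#' chi angles and their deviation from the library (when an observed label
#' and a library are present), and compute the label's surface areas.  For
#' every unordered site pair and method: the predicted mean-position
#' distance, the experimental distance (when both sites carry observed
#' labels) and the angle between the experimental and predicted distance
#' vectors.  Deterministic under a fixed config seed.
#'
#' @param model a `structure_model` (crystal input or synthetic fixture).
#' @param config a [benchmark_config()].
#' @param topo label topology.
#' @return a `benchmark_report`.
#' @export
run_benchmark <- function(model, config, topo = r1_topology()) {
  stopifnot(inherits(config, "benchmark_config"))
  asm <- build_benchmark_assembly(model, config$sites,
                                  config$packing_cutoff, config$env_radius)
  rule <- config$spin_rule
  sites <- config$sites
  site_res <- list()
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    key <- site_key(s)
    obs <- observed_label(asm$model, s, topo)
    work <- strip_label(asm$model, s)
    ens <- list()
    errors <- list()
    for (m in config$methods) {
      fit <- tryCatch({
        if (m == "accessible_volume")
          sample_accessible_volume(work, s,
                                   n_conformers = config$n_conformers,
                                   max_trials = config$max_trials,
                                   scale = config$scale,
                                   max_clashes = config$max_clashes,
                                   seed = config$seed + 1000L * i,
                                   topo = topo)
        else
          place_rotamers(work, s, config$library, scale = config$scale,
                         temperature_factor = config$temperature_factor,
                         hard_max_clashes = config$hard_max_clashes,
                         topo = topo)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[m]] <- conditionMessage(fit)
      } else ens[[m]] <- fit
    }
    dev <- NULL
    if (!is.null(obs) && !is.null(config$library))
      dev <- chi_deviation(obs$chi, config$library)
    surf <- NULL
    if (!is.null(obs))
      surf <- tryCatch(sasa(asm$model, list(chain = s[[1L]],
                                            resno = s[[2L]])),
                       error = function(e) NULL)
    site_res[[key]] <- list(site = s, observed = obs, chi_deviation = dev,
                            ensembles = ens, surface = surf,
                            complete = asm$site_complete[[key]],
                            errors = errors)
  }

  pairs <- list()
  if (length(sites) >= 2L) {
    for (i in seq_len(length(sites) - 1L)) for (j in (i + 1L):length(sites)) {
      ka <- site_key(sites[[i]]); kb <- site_key(sites[[j]])
      ra <- site_res[[ka]]; rb <- site_res[[kb]]
      expd <- NULL
      if (!is.null(ra$observed) && !is.null(rb$observed)) {
        pa <- spin_center(ra$observed$coords, rule)
        pb <- spin_center(rb$observed$coords, rule)
        expd <- list(a = pa, b = pb, distance = vnorm(pb - pa))
      }
      per_method <- list()
      for (m in config$methods) {
        if (is.null(ra$ensembles[[m]]) || is.null(rb$ensembles[[m]])) next
        if (!length(ra$ensembles[[m]]$conformers) ||
            !length(rb$ensembles[[m]]$conformers)) next
        ma <- mean_spin_position(ra$ensembles[[m]], rule)
        mb <- mean_spin_position(rb$ensembles[[m]], rule)
        ang <- if (is.null(expd)) NA_real_ else
          vector_angle_deviation(rbind(expd$a, expd$b), rbind(ma, mb))
        per_method[[m]] <- list(distance = vnorm(mb - ma),
                                vector_angle_deviation = ang)
      }
      pairs[[paste(ka, kb, sep = " <-> ")]] <-
        list(pair = c(ka, kb),
             experimental_distance = if (is.null(expd)) NA_real_ else
               expd$distance,
             predicted = per_method)
    }
  }
  structure(list(sites = site_res, pairs = pairs,
                 provenance = list(config = config, rule = rule,
                                   chi5_convention = topo$chi5_convention,
                                   package_version =
                                     as.character(utils::packageVersion("spinlabelr")))),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report:", length(x$sites), "site(s),",
      length(x$pairs), "pair(s); spin-center rule", x$provenance$rule,
      "; chi5", x$provenance$chi5_convention, "\n")
  for (k in names(x$sites)) {
    s <- x$sites[[k]]
    cat(sprintf("  site %s%s:", k,
                if (isTRUE(s$complete)) "" else " [environment truncated]"))
    if (!is.null(s$observed))
      cat(sprintf(" observed chi (%s)",
                  paste(sprintf("%.0f", s$observed$chi), collapse = ", ")))
    if (!is.null(s$chi_deviation))
      cat(sprintf(", max |dchi| to library %.1f deg",
                  s$chi_deviation$max_abs_delta))
    cat("\n")
    for (m in names(s$ensembles)) {
      e <- s$ensembles[[m]]
      cat(sprintf("    %s: %d conformers, p.f. %.4g\n", m,
                  length(e$conformers), e$partition_function))
    }
    for (m in names(s$errors))
      cat(sprintf("    %s: FAILED (%s)\n", m, s$errors[[m]]))
  }
  for (k in names(x$pairs)) {
    p <- x$pairs[[k]]
    cat(sprintf("  pair %s: experimental %.1f A", k,
                p$experimental_distance))
    for (m in names(p$predicted))
      cat(sprintf("; %s %.1f A (vector dev %.0f deg)", m,
                  p$predicted[[m]]$distance,
                  p$predicted[[m]]$vector_angle_deviation))
    cat("\n")
  }
  invisible(x)
}

#' Write a benchmark report as JSON and TSV
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jse <- function(x) jsonlite::write_json(x, file.path(dir, "report.json"),
                                          auto_unbox = TRUE, digits = NA,
                                          null = "null", force = TRUE)
  slim <- list(
    provenance = report$provenance[c("rule", "chi5_convention",
                                     "package_version")],
    seed = report$provenance$config$seed,
    sites = lapply(report$sites, function(s) list(
      observed_chi = if (is.null(s$observed)) NULL else
        as.list(s$observed$chi),
      max_abs_dchi = if (is.null(s$chi_deviation)) NULL else
        s$chi_deviation$max_abs_delta,
      complete = s$complete,
      total_asa = if (is.null(s$surface)) NULL else s$surface$total_asa,
      buried_asa = if (is.null(s$surface)) NULL else s$surface$buried_asa,
      ensembles = lapply(s$ensembles, function(e) list(
        method = e$method, n = length(e$conformers),
        partition_function = e$partition_function,
        acceptance_fraction = e$params$acceptance_fraction)))),
    pairs = lapply(report$pairs, function(p) list(
      pair = paste(p$pair, collapse = " <-> "),
      experimental_distance = p$experimental_distance,
      predicted = lapply(p$predicted, function(q) q))))
  jse(slim)
  # TSV of the pair table
  rows <- lapply(names(report$pairs), function(k) {
    p <- report$pairs[[k]]
    do.call(rbind, lapply(names(p$predicted), function(m) data.frame(
      pair = k, method = m,
      experimental_distance = p$experimental_distance,
      predicted_distance = p$predicted[[m]]$distance,
      vector_angle_deviation = p$predicted[[m]]$vector_angle_deviation)))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(), method = character(),
               experimental_distance = numeric(),
               predicted_distance = numeric(),
               vector_angle_deviation = numeric())
  utils::write.table(tab, file.path(dir, "distances.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(file.path(dir, "report.json"), file.path(dir, "distances.tsv")))
}
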