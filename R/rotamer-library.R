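# Rotamer libraries: discrete chi tuples with prior weights.  The on-disk
# format is a plain-text table, one rotamer per row (chi1..chi5 in degrees
# plus a prior weight), '#' comments; weights renormalize on load.

new_rotamer_library <- function(entries, name = "unnamed",
                                chi5_convention = "SD-CE-C3-C4",
                                generation = NULL) {
  stopifnot(nrow(entries) >= 1L)
  if (any(entries$weight < 0)) stop("negative prior weight")
  s <- sum(entries$weight)
  if (s <= 0) stop("prior weights sum to zero")
  entries$weight <- entries$weight / s
  entries[, 1:5] <- wrap_angle(as.matrix(entries[, 1:5]))
  structure(list(entries = entries,
                 metadata = list(name = name,
                                 chi5_convention = chi5_convention,
                                 generation = generation)),
            class = "rotamer_library")
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat(sprintf("rotamer_library '%s': %d entries, chi5 convention %s\n",
              x$metadata$name, nrow(x$entries), x$metadata$chi5_convention))
  invisible(x)
}

#' Create a rotamer library from chi tuples and prior weights
#'
#' @param chi n x 5 matrix of dihedrals (degrees).
#' @param weight prior weights (any positive scale; normalized to sum 1).
#' @param name library name carried in metadata.
#' @param chi5_convention convention tag for the chi5 fourth atom.
#' @return a `rotamer_library`.
#' @export
rotamer_library <- function(chi, weight = NULL, name = "unnamed",
                            chi5_convention = "SD-CE-C3-C4") {
  chi <- matrix(as.numeric(chi), ncol = 5L)
  if (is.null(weight)) weight <- rep(1, nrow(chi))
  entries <- data.frame(chi1 = chi[, 1L], chi2 = chi[, 2L], chi3 = chi[, 3L],
                        chi4 = chi[, 4L], chi5 = chi[, 5L], weight = weight)
  new_rotamer_library(entries, name = name,
                      chi5_convention = chi5_convention)
}

#' Load a rotamer library from a plain-text table
#'
#' Rows of six numbers (chi1..chi5, prior weight); `#` starts a comment.
#' Header comments of the form `# name: x` / `# chi5_convention: x` populate
#' the metadata.  Weights are renormalized to sum 1.
#'
#' @param path file path.
#' @return a `rotamer_library`.
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  meta <- list(name = basename(path), chi5_convention = NULL)
  for (key in c("name", "chi5_convention")) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), ln, value = TRUE)
    if (length(hit))
      meta[[key]] <- trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1L]))
  }
  ln <- sub("#.*$", "", ln)
  keep <- which(trimws(ln) != "")
  if (!length(keep)) stop("no rotamer rows in ", path)
  rows <- strsplit(trimws(ln[keep]), "\\s+")
  entries <- matrix(NA_real_, length(rows), 6L)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) != 6L || anyNA(v))
      stop("parse error in ", path, " at line ", keep[i],
           ": expected 6 numeric fields")
    entries[i, ] <- v
  }
  entries <- as.data.frame(entries)
  names(entries) <- c(paste0("chi", 1:5), "weight")
  new_rotamer_library(entries, name = meta$name,
                      chi5_convention = meta$chi5_convention %||%
                        "SD-CE-C3-C4")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a rotamer library to its plain-text format
#'
#' @param library a `rotamer_library`.
#' @param path output path.
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "rotamer_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# name: ", library$metadata$name),
               paste0("# chi5_convention: ", library$metadata$chi5_convention),
               "# chi1 chi2 chi3 chi4 chi5 weight"), con)
  e <- library$entries
  writeLines(sprintf("%12.6f %12.6f %12.6f %12.6f %12.6f %.9e",
                     e$chi1, e$chi2, e$chi3, e$chi4, e$chi5, e$weight), con)
  invisible(path)
}
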