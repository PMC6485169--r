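#' Fragment library
#'
#' A fragment library stores, for every start position i in [1, l-f+1] of a
#' chain of length l, a list of up to 200 fragment configurations; each
#' configuration is f (phi, psi, omega) triples that a fragment-replacement
#' move copies into the chain. Configurations are held as rows of a numeric
#' matrix with 3f columns ordered (phi1, psi1, omega1, phi2, ...).
#'
#' @param f fragment length, 3 or 9.
#' @param entries list over start positions of configuration matrices.
#' @return Object of class `fragment_library` with elements `f` and
#'   `entries`.
#' @export
fragment_library <- function(f, entries) {
  f <- as.integer(f)
  if (!f %in% c(3L, 9L)) stop("fragment length f must be 3 or 9")
  if (length(entries) == 0) stop("library has no positions")
  entries <- lapply(seq_along(entries), function(i) {
    m <- as.matrix(entries[[i]])
    if (ncol(m) != 3 * f)
      stop("position ", i, ": configurations must have ", 3 * f, " angles")
    if (nrow(m) < 1) stop("position ", i, " has no configurations")
    if (nrow(m) > 200) stop("position ", i, " has more than 200 configurations")
    m[] <- normalize_angle(m)
    dimnames(m) <- NULL
    m
  })
  structure(list(f = f, entries = entries), class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  n <- vapply(x$entries, nrow, integer(1))
  cat("<fragment_library> f =", x$f, "|", length(x$entries),
      "positions |", min(n), "-", max(n), "configurations each\n")
  invisible(x)
}

#' Number of chain residues a library covers
#'
#' A library with p start positions covers a chain of l = p + f - 1 residues.
#' @param lib a `fragment_library`.
#' @return Integer chain length.
#' @export
library_chain_length <- function(lib) length(lib$entries) + lib$f - 1L

#' Read a fragment library from its plain-text format
#'
#' The format is columnar text: for each configuration a header line
#' `position entry-index` followed by f lines of `phi psi omega` (degrees).
#' Positions are 1-based and must cover [1, l-f+1] without gaps.
#'
#' @param path text file.
#' @param f fragment length, 3 or 9.
#' @return A [fragment_library()].
#' @export
load_fragment_library <- function(path, f) {
  f <- as.integer(f)
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  toks <- strsplit(lines[keep], "[[:space:]]+")
  i <- 1
  store <- list()
  while (i <= length(toks)) {
    hdr <- suppressWarnings(as.numeric(toks[[i]]))
    if (length(hdr) != 2 || any(is.na(hdr)))
      stop("line ", lineno[i], ": expected 'position entry-index' header")
    pos <- hdr[1]
    if (pos != round(pos) || pos < 1)
      stop("line ", lineno[i], ": position must be a positive integer (1-based)")
    if (i + f > length(toks) + 0)
      stop("line ", lineno[i], ": truncated configuration")
    cfg <- numeric(3 * f)
    for (r in seq_len(f)) {
      ang <- suppressWarnings(as.numeric(toks[[i + r]]))
      if (length(ang) != 3 || any(is.na(ang)))
        stop("line ", lineno[i + r], ": expected 'phi psi omega'")
      cfg[(3 * r - 3) + 1:3] <- ang
    }
    key <- as.character(pos)
    store[[key]] <- c(store[[key]], list(cfg))
    if (length(store[[key]]) > 200)
      stop("line ", lineno[i], ": more than 200 configurations at position ",
           pos)
    i <- i + f + 1
  }
  pos_seen <- sort(as.integer(names(store)))
  if (length(pos_seen) == 0) stop("empty fragment file")
  if (!identical(pos_seen, seq_len(max(pos_seen))))
    stop("position gap: have ", paste(pos_seen, collapse = ","),
         ", expected 1..", max(pos_seen))
  entries <- lapply(seq_len(max(pos_seen)), function(p)
    do.call(rbind, store[[as.character(p)]]))
  fragment_library(f, entries)
}

#' Write a fragment library in the plain-text format
#'
#' @param lib a `fragment_library`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragment_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in seq_along(lib$entries)) {
    m <- lib$entries[[p]]
    for (e in seq_len(nrow(m))) {
      writeLines(sprintf("%d %d", p, e), con)
      for (r in seq_len(lib$f))
        writeLines(sprintf("%.6f %.6f %.6f", m[e, 3 * r - 2],
                           m[e, 3 * r - 1], m[e, 3 * r]), con)
    }
  }
  invisible(path)
}

#' Draw a random fragment-replacement move
#'
#' Picks a start position uniformly on [1, l-f+1] and one of the stored
#' configurations at that position uniformly. Uses R's RNG; the conformation
#' is not modified.
#'
#' @param conf a `conformation`.
#' @param lib a `fragment_library` covering the chain.
#' @return List with `start` (1-based) and `config` (f x 3 matrix).
#' @export
sample_move <- function(conf, lib) {
  l <- length(conf$sequence)
  npos <- l - lib$f + 1L
  if (npos < 1) stop("chain shorter than fragment length")
  if (length(lib$entries) != npos)
    stop("library covers ", library_chain_length(lib),
         " residues but chain has ", l)
  start <- sample.int(npos, 1)
  m <- lib$entries[[start]]
  cfg <- m[sample.int(nrow(m), 1), ]
  list(start = start,
       config = matrix(cfg, ncol = 3, byrow = TRUE,
                       dimnames = list(NULL, c("phi", "psi", "omega"))))
}

#' Apply a fragment-replacement move
#'
#' Overwrites the (phi, psi, omega) triples of residues
#' start..start+f-1 with the configuration and rebuilds coordinates; all
#' other dihedrals are untouched and the parent is not modified.
#'
#' @param conf a `conformation`.
#' @param start 1-based start position.
#' @param config f x 3 matrix of dihedrals (degrees).
#' @return A new `conformation`.
#' @export
apply_move <- function(conf, start, config) {
  config <- as.matrix(config)
  f <- nrow(config)
  l <- length(conf$sequence)
  if (start < 1 || start > l - f + 1)
    stop("start must lie in [1, ", l - f + 1, "]")
  dih <- conf$dihedrals
  dih[start:(start + f - 1), ] <- normalize_angle(config)
  conf$dihedrals <- dih
  rebuild_coordinates(conf)
}

#' Generate a synthetic fragment library around a native conformation
#'
#' A stand-in for server-built fragment libraries so the pipeline runs with
#' no external data. At every start position, a `near_fraction` share of the
#' configurations are the native's local torsions plus Gaussian noise of sd
#' `noise_deg`; the remainder are decoys drawn from the three canonical
#' Ramachandran basins (helix (-57, -47), strand (-120, 120), left-handed
#' (60, 45)). omega gets the same Gaussian noise around its base value
#' (the native's omega, or 180 for basin decoys), but the deviation is
#' clamped to +/- 15 degrees so every peptide bond stays near-trans (cis
#' configurations are not modeled).
#'
#' @param native a `conformation` (the toy target's native).
#' @param f fragment length, 3 or 9.
#' @param n_per_pos configurations per position; the default matches the
#'   200-configuration convention of server-built fragment libraries.
#' @param near_fraction share in [0, 1] of near-native configurations.
#' @param noise_deg Gaussian noise sd in degrees.
#' @return A [fragment_library()].
#' @export
make_synthetic_library <- function(native, f, n_per_pos = 200,
                                   near_fraction = 0.3, noise_deg = 10) {
  if (n_per_pos > 200) stop("library contract allows at most 200 per position")
  if (n_per_pos < 1) stop("need at least one configuration per position")
  if (near_fraction < 0 || near_fraction > 1)
    stop("near_fraction must lie in [0, 1]")
  f <- as.integer(f)
  l <- length(native$sequence)
  npos <- l - f + 1L
  if (npos < 1) stop("native chain shorter than fragment length")
  basins <- matrix(c(-57, -47, -120, 120, 60, 45), ncol = 2, byrow = TRUE)
  n_near <- ceiling(near_fraction * n_per_pos)
  omega_cap <- 15  # peptide bonds stay near-trans; cis is not modeled
  entries <- vector("list", npos)
  for (p in seq_len(npos)) {
    local <- native$dihedrals[p:(p + f - 1), , drop = FALSE]
    cfgs <- matrix(NA_real_, n_per_pos, 3 * f)
    for (e in seq_len(n_per_pos)) {
      if (e <= n_near) {
        base <- local
      } else {
        b <- basins[sample.int(3, f, replace = TRUE), , drop = FALSE]
        base <- cbind(b, rep(180, f))
      }
      cfg <- base + matrix(stats::rnorm(3 * f, 0, noise_deg), f, 3)
      cfg[, 3] <- base[, 3] + pmax(-omega_cap,
                                   pmin(omega_cap, cfg[, 3] - base[, 3]))
      cfgs[e, ] <- as.vector(t(cfg))
    }
    entries[[p]] <- cfgs
  }
  fragment_library(f, entries)
}
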