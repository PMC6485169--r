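#' Synthetic toy target
#'
#' Desk-scale stand-ins for real prediction targets: ideal-torsion natives
#' whose dihedrals are built from canonical basin values, so the whole
#' sampling pipeline is testable with no external data.
#'
#' @param topology `"helix"` (all (-57, -47, 180)), `"hairpin"` (two
#'   antiparallel strand arms of (-120, 120, 180) joined by a four-residue
#'   turn) or `"mixed"` (alternating helix/strand blocks).
#' @param length chain length (>= 12 residues).
#' @param geometry a [backbone_geometry()].
#' @return List of class `toy_target` with `name`, `sequence`, `native`
#'   (a `conformation`) and `topology`.
#' @examples
#' tt <- make_toy_native("helix", 30)
#' tt$native
#' @export
make_toy_native <- function(topology = c("helix", "hairpin", "mixed"),
                            length, geometry = backbone_geometry()) {
  topology <- match.arg(topology)
  l <- as.integer(length)
  if (l < 12) stop("toy targets need at least 12 residues")
  helix <- c(-57, -47, 180)
  strand <- c(-120, 120, 180)
  dih <- matrix(NA_real_, l, 3)
  if (topology == "helix") {
    dih[] <- matrix(helix, l, 3, byrow = TRUE)
  } else if (topology == "hairpin") {
    arm <- (l - 4) %/% 2
    # four-residue turn closing the two strand arms into an antiparallel
    # hairpin with ~4.5-4.8 A CA pairing across the strands
    turn <- rbind(c(16, 159, 180), c(-16, 45, 180),
                  c(119, 71, 180), c(-95, -133, 180))
    dih[seq_len(arm), ] <- matrix(strand, arm, 3, byrow = TRUE)
    dih[arm + 1:4, ] <- turn
    rest <- l - arm - 4
    dih[arm + 4 + seq_len(rest), ] <- matrix(strand, rest, 3, byrow = TRUE)
  } else {
    block <- 10L
    for (s in seq(1L, l, by = block)) {
      e <- min(s + block - 1L, l)
      v <- if (((s - 1L) %/% block) %% 2 == 0) helix else strand
      dih[s:e, ] <- matrix(v, e - s + 1L, 3, byrow = TRUE)
    }
  }
  # deterministic pseudo-sequence: hydrophobic/polar alternation
  seq1 <- rep(c("A", "L", "S", "V", "G", "T", "I", "E", "K", "F"),
              length.out = l)
  structure(list(name = paste0(topology, "-", l), sequence = seq1,
                 native = conformation(seq1, dih, geometry),
                 topology = topology),
            class = "toy_target")
}

#' @export
print.toy_target <- function(x, ...) {
  cat("<toy_target>", x$name, "(", x$topology, ",",
      length(x$sequence), "residues )\n")
  invisible(x)
}

#' Fixed panel of toy targets
#'
#' The deterministic evaluation panel: helix-20, helix-30, hairpin-24 and
#' mixed-40; identical on every call.
#'
#' @param geometry a [backbone_geometry()].
#' @return Named list of [make_toy_native()] targets.
#' @export
default_suite <- function(geometry = backbone_geometry()) {
  targets <- list(make_toy_native("helix", 20, geometry),
                  make_toy_native("helix", 30, geometry),
                  make_toy_native("hairpin", 24, geometry),
                  make_toy_native("mixed", 40, geometry))
  names(targets) <- vapply(targets, `[[`, character(1), "name")
  targets
}

#' Write the toy panel to disk
#'
#' Emits, per target, a FASTA sequence, a native PDB and synthetic f = 9
#' and f = 3 fragment libraries in the package's plain-text format.
#'
#' @param dir output directory (created if missing).
#' @param n_per_pos,near_fraction,noise_deg passed to
#'   [make_synthetic_library()].
#' @return The directory, invisibly.
#' @export
write_fixture_panel <- function(dir, n_per_pos = 200, near_fraction = 0.3,
                                noise_deg = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tt in default_suite()) {
    base <- file.path(dir, tt$name)
    writeLines(c(paste0(">", tt$name),
                 paste(tt$sequence, collapse = "")),
               paste0(base, ".fasta"))
    write_pdb(tt$native, paste0(base, ".pdb"))
    for (f in c(9L, 3L)) {
      lib <- make_synthetic_library(tt$native, f, n_per_pos,
                                    near_fraction, noise_deg)
      write_fragment_library(lib, paste0(base, ".frag", f, ".txt"))
    }
  }
  invisible(dir)
}
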