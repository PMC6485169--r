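aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
aa1to3 <- structure(names(aa3to1), names = unname(aa3to1))

#' Read a single-chain backbone from a PDB file
#'
#' Parses ATOM records (first model, first chain) via `bio3d`, extracts the
#' N/CA/C backbone, back-computes (phi, psi, omega) dihedrals and returns a
#' [conformation()] whose coordinates are rebuilt from those dihedrals under
#' the package's ideal geometry. A residue missing any of its N/CA/C atoms is
#' a format error naming the residue.
#'
#' @param path PDB file.
#' @param geometry a [backbone_geometry()] used for the rebuild.
#' @return A `conformation`.
#' @seealso [write_pdb()]
#' @export
read_pdb <- function(path, geometry = backbone_geometry()) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at <- at[at$chain == at$chain[1] | is.na(at$chain), , drop = FALSE]
  res_ids <- unique(at$resno)
  l <- length(res_ids)
  N <- CA <- C <- matrix(NA_real_, l, 3)
  seq1 <- character(l)
  for (i in seq_len(l)) {
    rows <- at[at$resno == res_ids[i], , drop = FALSE]
    seq1[i] <- unname(aa3to1[rows$resid[1]])
    if (is.na(seq1[i]))
      stop("non-standard residue ", rows$resid[1], " at ", res_ids[i])
    for (nm in c("N", "CA", "C")) {
      j <- which(rows$elety == nm)
      if (length(j) == 0)
        stop("residue ", res_ids[i], " (", rows$resid[1],
             ") is missing backbone atom ", nm)
      m <- switch(nm, N = 1, CA = 2, C = 3)
      if (m == 1) N[i, ] <- unlist(rows[j[1], c("x", "y", "z")])
      if (m == 2) CA[i, ] <- unlist(rows[j[1], c("x", "y", "z")])
      if (m == 3) C[i, ] <- unlist(rows[j[1], c("x", "y", "z")])
    }
  }
  if (l > 1 && any(diff(res_ids) != 1))
    stop("chain break: residue numbering jumps at ",
         res_ids[which(diff(res_ids) != 1)[1]])
  dih <- dihedrals_from_backbone(N, CA, C)
  conformation(seq1, dih, geometry)
}

fmt_atom <- function(serial, name, resid3, resno, xyz) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name4, resid3, resno, xyz[1], xyz[2], xyz[3])
}

#' Write conformations as a (multi-MODEL) PDB file
#'
#' Emits fixed-column ATOM records for the five modeled atoms per residue
#' (N, CA, C, O and the centroid pseudo-atom CEN), one MODEL/ENDMDL block per
#' conformation, occupancy 1.00 and B-factor 0.00.
#'
#' @param conformations a `conformation` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conformations, path) {
  if (inherits(conformations, "conformation"))
    conformations <- list(conformations)
  if (length(conformations) == 0) stop("need at least one conformation")
  con <- file(path, "w")
  on.exit(close(con))
  atoms <- c("N", "CA", "C", "O", "CEN")
  for (m in seq_along(conformations)) {
    conf <- conformations[[m]]
    if (length(conformations) > 1)
      writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    lines <- character(0)
    for (i in seq_along(conf$sequence)) {
      resid3 <- aa1to3[[conf$sequence[i]]]
      for (k in seq_along(atoms)) {
        serial <- serial + 1L
        lines <- c(lines, fmt_atom(serial, atoms[k], resid3, i,
                                   conf$coords[5 * (i - 1) + k, ]))
      }
    }
    writeLines(lines, con)
    writeLines(if (length(conformations) > 1) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a target sequence from a FASTA file
#'
#' The first record is used; its description is kept as the run label.
#'
#' @param path FASTA file.
#' @return Character vector of one-letter codes with attribute `label`.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("no sequences in ", path)
  seq1 <- check_sequence(toupper(as.character(recs[[1]])))
  attr(seq1, "label") <- attr(recs[[1]], "Annot")
  seq1
}
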