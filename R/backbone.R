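#' Ideal backbone geometry constants
#'
#' Bond lengths (Angstrom), bond angles (degrees) and the side-chain centroid
#' placement used by the deterministic internal-to-Cartesian rebuild. The
#' defaults are standard trans-peptide values; all comparisons made by the
#' sampler are internal, so any self-consistent ideal geometry works.
#'
#' @param b_nca,b_cac,b_cn,b_co,b_cacen bond lengths in Angstrom for N-CA,
#'   CA-C, C-N (peptide), C-O and CA-CEN (the single side-chain centroid
#'   pseudo-atom placed along the CB direction).
#' @param a_ncac,a_cacn,a_cnca,a_caco,a_ncacen backbone bond angles in
#'   degrees at the corresponding junctions.
#' @param t_cen improper torsion C-N-CA-CEN (degrees) fixing the centroid on
#'   the L-amino-acid side of the backbone plane.
#' @param omega default peptide-bond torsion in degrees (trans).
#' @return A named numeric vector of class `backbone_geometry`.
#' @examples
#' geo <- backbone_geometry()
#' geo[["b_nca"]]
#' @export
backbone_geometry <- function(b_nca = 1.458, b_cac = 1.525, b_cn = 1.329,
                              b_co = 1.231, b_cacen = 1.53,
                              a_ncac = 111.2, a_cacn = 116.2, a_cnca = 121.7,
                              a_caco = 120.8, a_ncacen = 110.5,
                              t_cen = -120, omega = 180) {
  g <- c(b_nca = b_nca, b_cac = b_cac, b_cn = b_cn, b_co = b_co,
         b_cacen = b_cacen, a_ncac = a_ncac, a_cacn = a_cacn,
         a_cnca = a_cnca, a_caco = a_caco, a_ncacen = a_ncacen,
         t_cen = t_cen, omega = omega)
  lens <- g[startsWith(names(g), "b_")]
  angs <- g[startsWith(names(g), "a_")]
  if (any(lens <= 0)) stop("bond lengths must be positive")
  if (any(angs <= 0 | angs >= 180)) stop("bond angles must lie in (0, 180)")
  structure(g, class = "backbone_geometry")
}

#' Normalize angles to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180]. The map is
#'   idempotent.
#' @examples
#' normalize_angle(c(270, -180, 540))
#' @export
normalize_angle <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

#' Torsion angle of four points
#'
#' IUPAC-signed dihedral angle p1-p2-p3-p4 in degrees, range (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return Torsion angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  .cpp_torsion(as.numeric(p1), as.numeric(p2), as.numeric(p3), as.numeric(p4))
}

aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_sequence <- function(sequence) {
  if (length(sequence) == 1)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(as.character(sequence))
  if (length(sequence) == 0) stop("sequence must be non-empty")
  bad <- setdiff(unique(sequence), aa1)
  if (length(bad) > 0)
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "))
  sequence
}

#' Construct a conformation from sequence and dihedrals
#'
#' A conformation is an amino-acid sequence plus one (phi, psi, omega) triple
#' per residue; Cartesian coordinates of the five modeled atoms per residue
#' (N, CA, C, O and the side-chain centroid CEN) are a pure deterministic
#' function of the dihedrals and the geometry constants. omega of residue i
#' is the peptide torsion between residues i and i+1; phi of the first
#' residue and psi/omega of the last are carried but geometrically inert.
#'
#' @param sequence one-letter amino-acid string or character vector.
#' @param dihedrals l x 3 matrix of (phi, psi, omega) in degrees.
#' @param geometry a [backbone_geometry()].
#' @return An object of class `conformation` with elements `sequence`,
#'   `dihedrals` (normalized to (-180, 180]), `coords` (5l x 3 matrix, rows
#'   N/CA/C/O/CEN per residue) and `geometry`.
#' @seealso [build_extended()], [rebuild_coordinates()]
#' @export
conformation <- function(sequence, dihedrals, geometry = backbone_geometry()) {
  sequence <- check_sequence(sequence)
  dihedrals <- as.matrix(dihedrals)
  if (ncol(dihedrals) != 3 || nrow(dihedrals) != length(sequence))
    stop("dihedrals must be an l x 3 matrix matching the sequence length")
  if (any(!is.finite(dihedrals))) stop("dihedrals must be finite")
  dihedrals <- normalize_angle(dihedrals)
  colnames(dihedrals) <- c("phi", "psi", "omega")
  conf <- structure(list(sequence = sequence, dihedrals = dihedrals,
                         coords = NULL, geometry = geometry),
                    class = "conformation")
  rebuild_coordinates(conf)
}

#' Build an extended chain
#'
#' Every residue gets (phi, psi, omega) = (180, 180, 180) -- the convention
#' used here for the fully extended starting conformation -- and coordinates
#' are rebuilt.
#'
#' @inheritParams conformation
#' @return A `conformation`.
#' @examples
#' ext <- build_extended("AAA")
#' ext$dihedrals
#' @export
build_extended <- function(sequence, geometry = backbone_geometry()) {
  sequence <- check_sequence(sequence)
  conformation(sequence,
               matrix(180, nrow = length(sequence), ncol = 3),
               geometry)
}

#' Rebuild Cartesian coordinates from dihedrals
#'
#' Sequential internal-coordinate (NeRF-style) placement anchored at a
#' canonical origin frame, so the rebuild is deterministic and idempotent.
#' Coordinates of a residue depend only on dihedrals at or before it, so
#' changing angles of residue i never moves residues before i.
#'
#' @param conf a `conformation`.
#' @param geometry optional geometry overriding the one stored in `conf`.
#' @return The conformation with `coords` refreshed.
#' @export
rebuild_coordinates <- function(conf, geometry = NULL) {
  if (!inherits(conf, "conformation")) stop("not a conformation")
  if (!is.null(geometry)) conf$geometry <- geometry
  coords <- .cpp_rebuild(conf$dihedrals, unclass(conf$geometry))
  rownames(coords) <- paste0(rep(c("N", "CA", "C", "O", "CEN"),
                                 length(conf$sequence)),
                             rep(seq_along(conf$sequence), each = 5))
  colnames(coords) <- c("x", "y", "z")
  conf$coords <- coords
  conf
}

#' Coordinates of one backbone atom type
#'
#' @param conf a `conformation`.
#' @param atom one of "N", "CA", "C", "O", "CEN".
#' @return l x 3 matrix of coordinates.
#' @export
atom_coords <- function(conf, atom = "CA") {
  atoms <- c(N = 1, CA = 2, C = 3, O = 4, CEN = 5)
  k <- atoms[[match.arg(atom, names(atoms))]]
  l <- length(conf$sequence)
  conf$coords[5 * (seq_len(l) - 1) + k, , drop = FALSE]
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", length(x$sequence), " residues: ",
      paste(x$sequence, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
length.conformation <- function(x) length(x$sequence)

# Back-compute (phi, psi, omega) from N/CA/C coordinates; terminally inert
# angles are set to the 180-degree convention.
dihedrals_from_backbone <- function(N, CA, C) {
  l <- nrow(N)
  dih <- matrix(180, nrow = l, ncol = 3)
  colnames(dih) <- c("phi", "psi", "omega")
  if (l > 1) {
    for (i in seq_len(l)) {
      if (i > 1)
        dih[i, 1] <- torsion_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
      if (i < l) {
        dih[i, 2] <- torsion_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
        dih[i, 3] <- torsion_angle(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
      }
    }
  }
  normalize_angle(dih)
}
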