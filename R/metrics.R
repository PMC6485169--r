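as_ca <- function(x) {
  if (inherits(x, "conformation")) return(atom_coords(x, "CA"))
  m <- as.matrix(x)
  if (ncol(m) != 3) stop("expected an n x 3 coordinate matrix")
  m
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimizing the RMSD between two
#' paired point sets, via SVD of the covariance matrix with the standard
#' determinant correction so the rotation is proper (no reflection).
#'
#' @param P,Q n x 3 coordinate matrices (P is moved onto Q).
#' @return List of class `superposition` with `rotation` (3 x 3, applied as
#'   `P %*% rotation`), `translation`, and `rmsd` (Angstrom). The
#'   superposed copy of `P` is `P %*% rotation + translation` (row-wise).
#' @export
kabsch <- function(P, Q) {
  P <- as_ca(P); Q <- as_ca(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in length")
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((P0 %*% R - Q0)^2)))
  structure(list(rotation = R, translation = cq - as.vector(cp %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> RMSD =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

apply_superposition <- function(P, sup) {
  sweep(P %*% sup$rotation, 2, sup$translation, "+")
}

#' CA least RMSD
#'
#' Least root-mean-squared deviation of corresponding CA atoms after
#' optimal rigid superposition; symmetric in its arguments.
#'
#' @param model,native `conformation`s or n x 3 CA matrices of equal
#'   length.
#' @return lRMSD in Angstrom (0 iff the CA traces are congruent).
#' @export
lrmsd_ca <- function(model, native) {
  kabsch(as_ca(model), as_ca(native))$rmsd
}

# Superposition search shared by TM-score and GDT_TS: seed superpositions
# from gapless windows of lengths L, L/2 and L/4, then iteratively
# re-superpose on the residue subset within `radius` of the native until
# the subset stops changing. `value(d)` maps the distance vector to the
# quantity being maximized. Deterministic: no randomness involved.
seeded_search <- function(P, Q, radius, value, min_window = 4L,
                          windows = NULL) {
  L <- nrow(P)
  if (is.null(windows)) windows <- unique(pmax(min_window, c(L, L %/% 2, L %/% 4)))
  best <- -Inf
  for (w in windows) {
    for (s in seq_len(L - w + 1)) {
      idx <- s:(s + w - 1)
      for (iter in 1:20) {
        sup <- kabsch(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
        Pm <- apply_superposition(P, sup)
        d <- sqrt(rowSums((Pm - Q)^2))
        best <- max(best, value(d))
        nxt <- which(d < radius)
        if (length(nxt) < 3 || identical(nxt, idx)) break
        idx <- nxt
      }
    }
  }
  best
}

#' Template modeling score
#'
#' Length-normalized structural similarity in (0, 1]:
#' max over superpositions of mean(1 / (1 + (d_i/d0)^2)) with
#' d0 = 1.24 (L - 15)^(1/3) - 1.8, clamped below at 0.5 Angstrom for short
#' chains. The maximization uses the seeded superposition search over
#' windows of lengths L, L/2 and L/4 with iterative inclusion of residues
#' within d0, the standard heuristic for this score.
#'
#' @inheritParams lrmsd_ca
#' @return TM-score in (0, 1]; 1 for identical structures, >= 0.5
#'   indicates the same fold.
#' @export
tm_score <- function(model, native) {
  P <- as_ca(model); Q <- as_ca(native)
  if (nrow(P) != nrow(Q)) stop("chains differ in length")
  L <- nrow(P)
  d0 <- max(0.5, 1.24 * (max(L - 15, 0))^(1 / 3) - 1.8)
  seeded_search(P, Q, radius = d0,
                value = function(d) mean(1 / (1 + (d / d0)^2)))
}

#' Global distance test, total score
#'
#' Mean over the cutoffs 1, 2, 4 and 8 Angstrom of the maximal fraction of
#' CA atoms superposable within the cutoff, using the same seeded
#' superposition search as [tm_score()] with the cutoff as inclusion
#' radius.
#'
#' @inheritParams lrmsd_ca
#' @return GDT_TS in [0, 1]; 1 is a perfect match.
#' @export
gdt_ts <- function(model, native) {
  P <- as_ca(model); Q <- as_ca(native)
  if (nrow(P) != nrow(Q)) stop("chains differ in length")
  cuts <- c(1, 2, 4, 8)
  mean(vapply(cuts, function(cut)
    seeded_search(P, Q, radius = cut,
                  value = function(d) mean(d <= cut)),
    numeric(1)))
}
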