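#' Default coarse-grained energy parameters
#'
#' @return Named list of weights and cutoffs: `w_steric`, `w_hb`, `w_rg`
#'   (largest stage-3 weight, driving compaction), `w_tor`; clash radius
#'   `r_clash` (Angstrom, CA-CA and CEN-CEN); hydrogen-bond distance window
#'   `hb_lo`..`hb_hi` (Angstrom, on backbone O...N) and well depth
#'   `hb_depth` (a.u.); sequence-separation cutoff `s_cut` splitting short-
#'   from long-range hydrogen bonds; Ramachandran `basin_radius` (degrees)
#'   for the torsion-preference penalty; and the compactness target
#'   Rg0(l) = `rg_a` * l ^ `rg_b` (Angstrom).
#' @export
energy_defaults <- function() {
  list(w_steric = 10, w_hb = 1, w_rg = 2, w_tor = 0.1,
       r_clash = 4.0, hb_lo = 2.6, hb_hi = 3.4, hb_depth = 1,
       s_cut = 4L, basin_radius = 60, rg_a = 2.2, rg_b = 0.38)
}

#' Staged scoring model with evaluation accounting
#'
#' Bundles the coarse-grained energy parameters with a monotone counter of
#' scoring calls. The three stages mirror the roles of the staged scoring
#' used in fragment-assembly pipelines: stage 0 is a soft steric repulsion
#' only (used to randomize chains without self-collisions), stage 1 adds the
#' hydrogen-bond well (lets secondary structure form), stage 3 adds an
#' upweighted compactness penalty (drives tertiary packing). The
#' three-objective decomposition used by selection splits the same total
#' into short-range hydrogen bonds, long-range hydrogen bonds, and
#' everything else.
#'
#' @param params optional list overriding entries of [energy_defaults()].
#' @return An environment of class `score_model` with fields `params` and
#'   `count`.
#' @examples
#' m <- score_model()
#' evaluations(m)
#' @export
score_model <- function(params = list()) {
  p <- utils::modifyList(energy_defaults(), params)
  if (any(unlist(p[c("w_steric", "w_hb", "w_rg", "w_tor")]) < 0))
    stop("stage weights must be non-negative")
  p$s_cut <- as.integer(p$s_cut)
  e <- new.env(parent = emptyenv())
  e$params <- p
  e$count <- 0
  class(e) <- "score_model"
  e
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model>", x$count, "evaluations; r_clash =", x$params$r_clash,
      "A; hb window", x$params$hb_lo, "-", x$params$hb_hi, "A; s_cut =",
      x$params$s_cut, "\n")
  invisible(x)
}

count_eval <- function(model, n = 1) {
  if (!is.null(model)) model$count <- model$count + n
  invisible(model)
}

#' Evaluations consumed so far
#'
#' One energy evaluation is one scoring call of any stage function; the
#' budget accounting of the sampler counts every such call.
#'
#' @param model a [score_model()].
#' @return Non-decreasing numeric count.
#' @export
evaluations <- function(model) model$count

stage_score <- function(conf, model, stage) {
  count_eval(model)
  .cpp_stage_score(conf$dihedrals, as.integer(stage), model$params,
                   unclass(conf$geometry))
}

#' Soft steric repulsion (stage-0 score)
#'
#' Sum over CA-CA and CEN-CEN pairs with sequence separation >= 2 of
#' ((r_clash - d) / r_clash)^2 for d below the clash radius; zero at or
#' above it. Always non-negative.
#'
#' @param conf a `conformation`.
#' @param model a [score_model()]; its evaluation counter is incremented.
#' @return Steric score (a.u.).
#' @export
steric_energy <- function(conf, model = score_model()) {
  stage_score(conf, model, 0)
}

#' Stage-1 score: steric plus hydrogen-bond well
#'
#' `w_steric * steric + w_hb * hb`, where hb adds a well of depth
#' -`hb_depth` for every backbone O(i)...N(j) pair with |i - j| >= 3 whose
#' distance falls in the hydrogen-bond window. Lower is better; formation of
#' secondary structure is rewarded.
#'
#' @inheritParams steric_energy
#' @return Stage-1 score (a.u.).
#' @export
score1 <- function(conf, model = score_model()) {
  stage_score(conf, model, 1)
}

#' Stage-3 score: stage 1 plus compactness
#'
#' Adds `w_rg * max(0, Rg - Rg0(l))^2` with Rg the CA radius of gyration and
#' Rg0(l) = rg_a * l^rg_b, so only chains more extended than the target are
#' penalized. The compactness weight is the largest of the stage, favoring
#' compact tertiary structure; this is the score the greedy improvement
#' operator descends.
#'
#' @inheritParams steric_energy
#' @return Stage-3 score (a.u.).
#' @export
score3 <- function(conf, model = score_model()) {
  stage_score(conf, model, 3)
}

#' Three-objective energy decomposition
#'
#' The optimization objectives used by the multi-objective selection:
#' `E_sr_hb` (hydrogen bonds with sequence separation <= s_cut, the helical
#' i,i+3 / i,i+4 contacts), `E_lr_hb` (separation > s_cut) and `E_other`
#' (steric + compactness + a torsion-preference penalty for residues outside
#' the three canonical Ramachandran basins). Their sum is the total energy.
#' Increments the evaluation counter by one.
#'
#' @inheritParams steric_energy
#' @return Named numeric vector (E_sr_hb, E_lr_hb, E_other).
#' @export
objectives <- function(conf, model = score_model()) {
  count_eval(model)
  .cpp_objectives(conf$dihedrals, model$params, unclass(conf$geometry))
}

#' Raw energy terms (no weights, no evaluation accounting)
#'
#' Diagnostic accessor returning the unweighted steric, short/long-range
#' hydrogen-bond, compactness and torsion-preference terms.
#'
#' @inheritParams steric_energy
#' @return Named numeric vector.
#' @export
energy_terms <- function(conf, model = score_model()) {
  .cpp_energy_terms(conf$dihedrals, model$params, unclass(conf$geometry))
}
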