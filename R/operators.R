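#' Metropolis acceptance criterion
#'
#' Downhill and flat moves (`delta_e <= 0`) are always accepted; uphill
#' moves are accepted with probability `exp(-delta_e / alpha)`. The scaling
#' parameter alpha plays the role of a temperature: `alpha = 0` never
#' accepts an uphill move, larger alpha is more permissive.
#'
#' @param delta_e finite score change of the proposed move.
#' @param alpha non-negative scaling parameter.
#' @return Logical: accept the move?
#' @examples
#' set.seed(1)
#' metropolis_accept(-1, 0)  # downhill: always TRUE
#' metropolis_accept(1, 0)   # uphill at alpha 0: always FALSE
#' @export
metropolis_accept <- function(delta_e, alpha) {
  if (!is.finite(delta_e)) stop("delta_e must be finite")
  if (alpha < 0) stop("alpha must be non-negative")
  if (delta_e <= 0) return(TRUE)
  if (alpha == 0) return(FALSE)
  stats::runif(1) < exp(-delta_e / alpha)
}

#' Operator configuration
#'
#' @param n_stage1_per_res attempted stage-1 moves per residue during
#'   initialization (stage-1 trajectory length is `n_stage1_per_res * l`).
#' @param alpha_stage1,alpha_stage2 Metropolis scaling of the two
#'   initialization stages (0 forbids uphill moves; 2 is permissive).
#' @param stage2_fail_limit_per_res stage 2 ends when this many times l
#'   consecutive moves fail (1 reproduces the "l consecutive failures"
#'   rule).
#' @param stage2_max_attempts_per_res safety cap on stage-2 proposals per
#'   residue, guarding against libraries whose moves are always accepted.
#' @param k_per_res greedy improvement stops after `k_per_res * l`
#'   consecutive failing moves.
#' @return Named list of operator parameters.
#' @export
operator_config <- function(n_stage1_per_res = 5, alpha_stage1 = 0,
                            alpha_stage2 = 2, stage2_fail_limit_per_res = 1,
                            stage2_max_attempts_per_res = 50, k_per_res = 1) {
  list(n_stage1_per_res = n_stage1_per_res, alpha_stage1 = alpha_stage1,
       alpha_stage2 = alpha_stage2,
       stage2_fail_limit_per_res = stage2_fail_limit_per_res,
       stage2_max_attempts_per_res = stage2_max_attempts_per_res,
       k_per_res = k_per_res)
}

check_lib <- function(lib, f, l) {
  if (!inherits(lib, "fragment_library")) stop("not a fragment_library")
  if (lib$f != f) stop("need an f = ", f, " library")
  if (library_chain_length(lib) != l)
    stop("library covers ", library_chain_length(lib),
         " residues but chain has ", l)
}

#' Initial population by two-stage Monte Carlo local search
#'
#' Each of the N individuals starts from the extended chain and passes
#' through two Metropolis Monte Carlo stages of f = 9 fragment replacements.
#' Stage 1 randomizes the chain under the steric-only stage-0 score with
#' alpha = 0, so no self-collision is ever accepted; stage 2 switches to the
#' stage-1 score with alpha = 2, letting secondary structure form, and runs
#' until l consecutive moves fail. Every proposal costs one energy
#' evaluation; if `max_evals` is exhausted the local searches stop early.
#'
#' @param sequence amino-acid sequence (string or character vector).
#' @param N population size.
#' @param lib9 an f = 9 [fragment_library()] covering the sequence.
#' @param model a [score_model()] accumulating evaluations.
#' @param config an [operator_config()].
#' @param max_evals evaluation budget available for initialization.
#' @param geometry a [backbone_geometry()].
#' @return List of N `conformation`s.
#' @export
init_population <- function(sequence, N, lib9, model = score_model(),
                            config = operator_config(), max_evals = Inf,
                            geometry = backbone_geometry()) {
  sequence <- check_sequence(sequence)
  l <- length(sequence)
  if (l < 9) stop("chain must have at least 9 residues for f = 9 moves")
  if (N < 1) stop("N must be at least 1")
  check_lib(lib9, 9L, l)
  ext <- build_extended(sequence, geometry)
  pop <- vector("list", N)
  for (i in seq_len(N)) {
    conf <- ext
    left <- max_evals - evaluations(model)
    s1 <- .cpp_mmc_stage(conf$dihedrals, lib9$entries, 9L, 0L,
                         config$alpha_stage1,
                         as.integer(config$n_stage1_per_res * l), -1L,
                         model$params, unclass(conf$geometry),
                         as.numeric(min(left, .Machine$double.xmax)))
    count_eval(model, s1$evals)
    left <- max_evals - evaluations(model)
    s2 <- .cpp_mmc_stage(s1$dihedrals, lib9$entries, 9L, 1L,
                         config$alpha_stage2,
                         as.integer(config$stage2_max_attempts_per_res * l),
                         as.integer(config$stage2_fail_limit_per_res * l),
                         model$params, unclass(conf$geometry),
                         as.numeric(min(left, .Machine$double.xmax)))
    count_eval(model, s2$evals)
    conf$dihedrals <- s2$dihedrals
    colnames(conf$dihedrals) <- c("phi", "psi", "omega")
    pop[[i]] <- rebuild_coordinates(conf)
  }
  pop
}

#' Variation operator: one unconditional f = 3 fragment replacement
#'
#' Asexual reproduction: a single fragment replacement is drawn at random
#' and applied; the result is accepted regardless of its score, so at most
#' nine dihedral values differ from the parent. The parent is not modified.
#'
#' @param parent a `conformation`.
#' @param lib3 an f = 3 [fragment_library()].
#' @return Offspring `conformation`.
#' @export
variation <- function(parent, lib3) {
  check_lib(lib3, 3L, length(parent$sequence))
  mv <- sample_move(parent, lib3)
  apply_move(parent, mv$start, mv$config)
}

#' Greedy improvement operator
#'
#' Maps an offspring toward a nearby local minimum of the stage-3 score by
#' f = 3 fragment replacements, each accepted only if it strictly lowers the
#' score (a zero change counts as a failure). Terminates after k consecutive
#' failing proposals, or when the evaluation budget runs out. The returned
#' conformation never scores higher than the input; the accepted-score trace
#' is attached as attribute `trace`.
#'
#' @param offspring a `conformation`.
#' @param lib3 an f = 3 [fragment_library()].
#' @param model a [score_model()].
#' @param k consecutive-failure budget (default l).
#' @param max_evals evaluation budget available to this call.
#' @return Improved `conformation` with attributes `trace` and `evals`.
#' @export
improvement <- function(offspring, lib3, model = score_model(),
                        k = length(offspring$sequence), max_evals = Inf) {
  check_lib(lib3, 3L, length(offspring$sequence))
  if (k < 0) stop("k must be non-negative")
  res <- .cpp_improve(offspring$dihedrals, lib3$entries, as.integer(k),
                      model$params, unclass(offspring$geometry),
                      as.numeric(min(max_evals, .Machine$double.xmax)))
  count_eval(model, res$evals)
  offspring$dihedrals <- res$dihedrals
  colnames(offspring$dihedrals) <- c("phi", "psi", "omega")
  out <- rebuild_coordinates(offspring)
  attr(out, "trace") <- res$trace
  attr(out, "evals") <- res$evals
  out
}
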