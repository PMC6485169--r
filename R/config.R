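#' Default run configuration
#'
#' Nested configuration for a sampling run. The published study-scale
#' setting is N = 100 with a 10,000,000-evaluation budget and 5 runs; the
#' shipped default is a desk-scale budget of 1e5 evaluations so a run
#' completes in minutes, with the full budget one config edit away.
#'
#' @param N population size (>= 2).
#' @param budget maximum energy evaluations (> 0).
#' @param selector one of `"evo_diverse"`, `"mea"`, `"mea_pr"`,
#'   `"mea_prpc"`.
#' @param runs number of independent runs in [multi_run()].
#' @param seed base RNG seed; run r uses `seed + r - 1`.
#' @param operators an [operator_config()].
#' @param energy overrides for [energy_defaults()].
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(N = 100, budget = 1e5,
                       selector = c("evo_diverse", "mea", "mea_pr",
                                    "mea_prpc"),
                       runs = 5, seed = 1,
                       operators = operator_config(), energy = list()) {
  selector <- match.arg(selector)
  if (N < 2) stop("population size must be at least 2")
  if (budget <= 0) stop("budget must be positive")
  structure(list(N = as.integer(N), budget = budget, selector = selector,
                 runs = as.integer(runs), seed = as.integer(seed),
                 operators = operators,
                 energy = utils::modifyList(energy_defaults(), energy)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Keys mirror [run_config()]: top-level `N`, `budget`, `selector`, `runs`,
#' `seed`, plus nested `operators:` and `energy:` blocks overriding the
#' defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- run_config()
  args <- list()
  for (k in c("N", "budget", "selector", "runs", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  args$operators <- utils::modifyList(base$operators,
                                      if (is.null(y$operators)) list()
                                      else y$operators)
  args$energy <- if (is.null(y$energy)) list() else y$energy
  do.call(run_config, args)
}

#' Serialize a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path optional output file; if `NULL` the YAML text is returned.
#' @return YAML string (invisibly when written to a file).
#' @export
dump_run_config <- function(config = run_config(), path = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> N =", x$N, "| budget =", format(x$budget, big.mark = ","),
      "| selector =", x$selector, "| runs =", x$runs, "| seed =", x$seed,
      "\n")
  invisible(x)
}
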