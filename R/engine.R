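record_pop <- function(pop, model, generation) {
  lapply(pop, function(conf) {
    ob <- objectives(conf, model)
    list(conformation = conf, objectives = ob, total = sum(ob),
         generation = generation)
  })
}

archive_df <- function(records) {
  data.frame(generation = vapply(records, `[[`, numeric(1), "generation"),
             E_sr_hb = vapply(records, function(r) r$objectives[[1]],
                              numeric(1)),
             E_lr_hb = vapply(records, function(r) r$objectives[[2]],
                              numeric(1)),
             E_other = vapply(records, function(r) r$objectives[[3]],
                              numeric(1)),
             total = vapply(records, `[[`, numeric(1), "total"))
}

#' Run the memetic multi-objective sampler
#'
#' The full decoy-generation loop: an initial population built by two-stage
#' Monte Carlo local search, then generations in which every parent yields
#' one offspring by a single f = 3 fragment replacement, each offspring is
#' refined by greedy improvement, and survival over the combined 2N
#' individuals is decided by the configured selector. The run stops before
#' any offspring pipeline would exceed the evaluation budget; every
#' generation's population is archived as decoys. With a fixed seed
#' (`set.seed` before the call) the run is bit-reproducible.
#'
#' @param sequence amino-acid sequence (string or character vector).
#' @param lib9,lib3 fragment libraries of length 9 and 3 covering the
#'   sequence.
#' @param config a [run_config()].
#' @param native optional native `conformation`; when given, per-decoy CA
#'   lRMSD values are included in the archive.
#' @param geometry a [backbone_geometry()].
#' @return Object of class `evodiverse_run`: list with `archive` (decoy
#'   records), `decoys` (data.frame view), `population` (final records),
#'   `evaluations`, `generations`, `config`, `native`.
#' @export
run_evodiverse <- function(sequence, lib9, lib3, config = run_config(),
                           native = NULL, geometry = backbone_geometry()) {
  sequence <- check_sequence(sequence)
  l <- length(sequence)
  if (l < 9) stop("need at least 9 residues")
  check_lib(lib9, 9L, l)
  check_lib(lib3, 3L, l)
  model <- score_model(config$energy)
  N <- config$N
  budget <- config$budget
  if (budget < N)
    stop("budget (", budget, ") cannot even score the initial population")
  k <- max(0L, as.integer(config$operators$k_per_res * l))
  # reserve N evaluations so the initial population can always be scored
  # without the counter passing the budget
  pop <- init_population(sequence, N, lib9, model, config$operators,
                         max_evals = budget - N, geometry = geometry)
  parents <- record_pop(pop, model, 0L)
  archive <- parents
  generation <- 0L
  # worst-case evaluation cost of one offspring pipeline: improvement's
  # initial score + up to (k + accepted) proposals is unbounded in theory;
  # we stop a generation early when fewer than N * (k + 2) evaluations
  # remain, and additionally cap every improvement call at the remaining
  # budget so the counter can never pass it.
  while (evaluations(model) + N * 2 <= budget) {
    generation <- generation + 1L
    offspring <- vector("list", N)
    for (i in seq_len(N)) {
      child <- variation(parents[[i]]$conformation, lib3)
      left <- budget - evaluations(model) - 1  # reserve the objectives call
      if (left < 1) break
      child <- improvement(child, lib3, model, k, max_evals = left)
      ob <- objectives(child, model)
      offspring[[i]] <- list(conformation = child, objectives = ob,
                             total = sum(ob), generation = generation)
    }
    done <- !vapply(offspring, is.null, logical(1))
    if (!all(done)) {  # budget ran out mid-generation: discard partials
      generation <- generation - 1L
      break
    }
    pool <- c(parents, offspring)
    obj <- do.call(rbind, lapply(pool, `[[`, "objectives"))
    idx <- select_indices(obj, N, config$selector)
    parents <- lapply(pool[idx], function(r) {
      r$generation <- generation
      r
    })
    archive <- c(archive, offspring)
    if (evaluations(model) >= budget) break
  }
  out <- structure(list(archive = archive, population = parents,
                        evaluations = evaluations(model),
                        generations = generation, config = config,
                        native = native, sequence = sequence),
                   class = "evodiverse_run")
  out$decoys <- archive_df(archive)
  if (!is.null(native)) {
    nat_ca <- as_ca(native)
    out$decoys$lrmsd <- vapply(archive, function(r)
      lrmsd_ca(r$conformation, nat_ca), numeric(1))
  }
  out
}

#' @export
print.evodiverse_run <- function(x, ...) {
  cat("<evodiverse_run>", length(x$sequence), "residues |",
      x$generations, "generations |", length(x$archive), "decoys |",
      format(x$evaluations, big.mark = ","), "evaluations (",
      x$config$selector, ")\n", sep = " ")
  if (!is.null(x$decoys$lrmsd))
    cat("  best lRMSD:", format(min(x$decoys$lrmsd), digits = 4),
        "A | lowest total energy:", format(min(x$decoys$total), digits = 6),
        "\n")
  invisible(x)
}

#' @export
summary.evodiverse_run <- function(object, ...) {
  df <- object$decoys
  s <- list(decoys = nrow(df), generations = object$generations,
            evaluations = object$evaluations,
            lowest_total = min(df$total),
            lowest_total_avg10 = mean(sort(df$total)[seq_len(min(10,
                                                                 nrow(df)))]))
  if (!is.null(df$lrmsd)) {
    s$best_lrmsd <- min(df$lrmsd)
    s$best_lrmsd_avg10 <- mean(sort(df$lrmsd)[seq_len(min(10, nrow(df)))])
  }
  structure(s, class = "summary.evodiverse_run")
}

#' @export
print.summary.evodiverse_run <- function(x, ...) {
  cat("decoys:", x$decoys, " generations:", x$generations,
      " evaluations:", format(x$evaluations, big.mark = ","), "\n")
  cat("lowest total energy:", format(x$lowest_total, digits = 6),
      " (avg of 10 best:", format(x$lowest_total_avg10, digits = 6), ")\n")
  if (!is.null(x$best_lrmsd))
    cat("best lRMSD:", format(x$best_lrmsd, digits = 4),
        "A  (avg of 10 best:", format(x$best_lrmsd_avg10, digits = 4),
        ")\n")
  invisible(x)
}

#' @export
plot.evodiverse_run <- function(x, ...) {
  if (is.null(x$decoys$lrmsd))
    stop("plotting the landscape needs a native structure (rerun with one)")
  graphics::plot(x$decoys$lrmsd, x$decoys$total, pch = 20, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "CA lRMSD to native (A)",
                 ylab = "total energy (a.u.)",
                 main = paste("energy landscape,", x$config$selector), ...)
  invisible(x)
}

#' Repeated runs and combined summary
#'
#' Runs the sampler `runs` times with seeds `seed`, `seed + 1`, ... and
#' summarizes the combined decoy sets: lowest total energy over all runs
#' and, when a native is given, lowest lRMSD / highest TM-score / highest
#' GDT_TS, plus the average over the 10 best decoys for each metric.
#'
#' @inheritParams run_evodiverse
#' @return Object of class `evodiverse_multirun` with `runs` (list of
#'   [run_evodiverse()] results) and `summary` (named list).
#' @export
multi_run <- function(sequence, lib9, lib3, config = run_config(),
                      native = NULL, geometry = backbone_geometry()) {
  runs <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    set.seed(config$seed + r - 1L)
    runs[[r]] <- run_evodiverse(sequence, lib9, lib3, config, native,
                                geometry)
  }
  totals <- unlist(lapply(runs, function(x) x$decoys$total))
  avg_best <- function(v, decreasing = FALSE)
    mean(sort(v, decreasing = decreasing)[seq_len(min(10, length(v)))])
  s <- list(lowest_total = min(totals),
            lowest_total_avg10 = avg_best(totals),
            per_run_lowest_total = vapply(runs, function(x)
              min(x$decoys$total), numeric(1)))
  if (!is.null(native)) {
    lr <- unlist(lapply(runs, function(x) x$decoys$lrmsd))
    s$best_lrmsd <- min(lr)
    s$best_lrmsd_avg10 <- avg_best(lr)
    s$per_run_best_lrmsd <- vapply(runs, function(x) min(x$decoys$lrmsd),
                                   numeric(1))
    nat_ca <- as_ca(native)
    best_conf <- function(x) {
      x$archive[[which.min(x$decoys$lrmsd)]]$conformation
    }
    tms <- vapply(runs, function(x) tm_score(best_conf(x), nat_ca),
                  numeric(1))
    gdt <- vapply(runs, function(x) gdt_ts(best_conf(x), nat_ca),
                  numeric(1))
    s$best_tm <- max(tms)
    s$best_gdt_ts <- max(gdt)
  }
  structure(list(runs = runs, summary = s, config = config),
            class = "evodiverse_multirun")
}

#' @export
print.evodiverse_multirun <- function(x, ...) {
  cat("<evodiverse_multirun>", length(x$runs), "runs (",
      x$config$selector, ")\n")
  cat("lowest total energy over all runs:",
      format(x$summary$lowest_total, digits = 6), "\n")
  if (!is.null(x$summary$best_lrmsd))
    cat("best lRMSD:", format(x$summary$best_lrmsd, digits = 4),
        "A | best TM:", format(x$summary$best_tm, digits = 3),
        "| best GDT_TS:", format(x$summary$best_gdt_ts, digits = 3), "\n")
  invisible(x)
}

#' Decoy energy-landscape table
#'
#' One row per archived decoy with its CA lRMSD to the native and its total
#' energy, for funnel/landscape scatter plots.
#'
#' @param run an [run_evodiverse()] result.
#' @param native native `conformation` (required if the run was made
#'   without one).
#' @param path optional TSV output file.
#' @return `data.frame(lrmsd, total)`, invisibly when written.
#' @export
export_landscape <- function(run, native = run$native, path = NULL) {
  if (is.null(native)) stop("lRMSD is undefined without a native structure")
  nat_ca <- as_ca(native)
  df <- data.frame(lrmsd = vapply(run$archive, function(r)
    lrmsd_ca(r$conformation, nat_ca), numeric(1)),
    total = vapply(run$archive, `[[`, numeric(1), "total"))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Coverage of the lRMSD axis by a decoy set
#'
#' Number of distinct 1-Angstrom lRMSD bins occupied by a run's decoys --
#' the desk-scale diversity measure used to compare selectors.
#'
#' @param run an [run_evodiverse()] result (made with a native).
#' @param width bin width in Angstrom.
#' @return Integer bin count.
#' @export
lrmsd_bins <- function(run, width = 1) {
  if (is.null(run$decoys$lrmsd)) stop("run has no native lRMSD values")
  length(unique(floor(run$decoys$lrmsd / width)))
}
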