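as_obj_matrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || any(!is.finite(m))) stop("objectives must be finite")
  m
}

#' Strong Pareto dominance
#'
#' `u` dominates `v` iff every component of `u` is strictly lower. Equality
#' in any component breaks dominance (soft dominance is not used).
#'
#' @param u,v numeric objective vectors of equal length.
#' @return Logical.
#' @examples
#' dominates(c(1, 1, 1), c(2, 2, 2))
#' dominates(c(1, 2, 3), c(1, 3, 4))  # FALSE: first components equal
#' @export
dominates <- function(u, v) {
  if (length(u) != length(v)) stop("objective vectors differ in length")
  all(u < v)
}

# n x n logical matrix D with D[i, j] = TRUE iff row i strongly dominates
# row j.
domination_matrix <- function(obj) {
  obj <- as_obj_matrix(obj)
  n <- nrow(obj)
  D <- matrix(TRUE, n, n)
  for (k in seq_len(ncol(obj)))
    D <- D & outer(obj[, k], obj[, k], "<")
  diag(D) <- FALSE
  D
}

#' Pareto rank (domination count)
#'
#' For each individual, the number of individuals in the set that strongly
#' dominate it; rank 0 individuals form the Pareto front.
#'
#' @param obj numeric matrix, one row per individual, one column per
#'   objective.
#' @return Integer vector of domination counts.
#' @export
pareto_rank <- function(obj) {
  colSums(domination_matrix(obj))
}

#' Pareto count (dominated-set size)
#'
#' For each individual, the number of individuals it strongly dominates.
#'
#' @inheritParams pareto_rank
#' @return Integer vector.
#' @export
pareto_count <- function(obj) {
  rowSums(domination_matrix(obj))
}

#' Fast non-dominated sorting into fronts
#'
#' The classic bookkeeping algorithm: individuals with domination count 0
#' form the first front F1; each next front is found by decrementing the
#' domination counts of the individuals dominated by the previous front's
#' members and collecting those that reach 0. Front generation stops at the
#' first front whose inclusion makes the cumulative count reach or exceed
#' `N` (pass `N` = number of individuals for a full sort).
#'
#' @inheritParams pareto_rank
#' @param N population size at which front generation may stop.
#' @return List with `fronts` (list of index vectors, input order preserved
#'   within fronts), `PR` (domination counts) and `PC` (dominated-set
#'   sizes).
#' @export
fast_nondominated_sort <- function(obj, N = nrow(as.matrix(obj))) {
  obj <- as_obj_matrix(obj)
  if (nrow(obj) == 0) stop("empty objective list")
  if (N < 1) stop("N must be at least 1")
  D <- domination_matrix(obj)
  PR <- colSums(D)
  PC <- rowSums(D)
  counts <- PR
  fronts <- list()
  current <- which(counts == 0)
  total <- 0
  while (length(current) > 0 && total < N) {
    fronts[[length(fronts) + 1]] <- current
    total <- total + length(current)
    if (total >= N) break
    counts[current] <- -1L  # already assigned
    nxt <- integer(0)
    for (i in current) {
      S <- which(D[i, ])
      counts[S] <- counts[S] - 1L
      nxt <- c(nxt, S[counts[S] == 0])
    }
    current <- sort(unique(nxt))
  }
  list(fronts = fronts, PR = PR, PC = PC)
}

#' Crowding distance within a front
#'
#' Density estimate used to keep selection diverse: distances start at 0;
#' for each objective the front is sorted ascending, the two extreme
#' individuals get infinite distance, and each interior individual adds the
#' normalized gap between its two neighbors. A degenerate objective
#' (max = min) contributes nothing to interior members.
#'
#' @param obj numeric matrix of the front's objective vectors.
#' @return Numeric vector of crowding distances (may be `Inf`).
#' @examples
#' crowding_distance(cbind(c(0, 5, 10)))  # middle member gets 1
#' @export
crowding_distance <- function(obj) {
  obj <- as_obj_matrix(obj)
  n <- nrow(obj)
  d <- numeric(n)
  if (n <= 2) return(rep(Inf, n))
  for (k in seq_len(ncol(obj))) {
    ord <- order(obj[, k])
    lo <- obj[ord[1], k]
    hi <- obj[ord[n], k]
    d[ord[c(1, n)]] <- Inf
    if (hi > lo) {
      gaps <- (obj[ord[3:n], k] - obj[ord[1:(n - 2)], k]) / (hi - lo)
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] + gaps
    }
  }
  d
}

# Survival selection on the combined objective matrix (parents stacked over
# offspring). Returns the selected row indices, in selection order.
select_indices <- function(obj, N, method = c("evo_diverse", "mea",
                                              "mea_pr", "mea_prpc")) {
  method <- match.arg(method)
  obj <- as_obj_matrix(obj)
  n <- nrow(obj)
  if (N > n) stop("cannot select ", N, " from ", n)
  total <- rowSums(obj)
  if (method == "mea") {
    return(order(total)[seq_len(N)])
  }
  if (method == "mea_pr") {
    PR <- pareto_rank(obj)
    return(order(PR, total)[seq_len(N)])
  }
  if (method == "mea_prpc") {
    PR <- pareto_rank(obj)
    PC <- pareto_count(obj)
    return(order(PR, -PC, total)[seq_len(N)])
  }
  fs <- fast_nondominated_sort(obj, N)
  picked <- integer(0)
  for (front in fs$fronts) {
    if (length(picked) + length(front) <= N) {
      picked <- c(picked, front)
      if (length(picked) == N) break
    } else {
      need <- N - length(picked)
      cd <- crowding_distance(obj[front, , drop = FALSE])
      picked <- c(picked, front[order(-cd)[seq_len(need)]])
      break
    }
  }
  picked
}

combine_sets <- function(parents, offspring) {
  if (is.matrix(parents) || is.data.frame(parents))
    return(rbind(as_obj_matrix(parents), as_obj_matrix(offspring)))
  NULL
}

select_pop <- function(parents, offspring, N, method) {
  obj <- combine_sets(parents, offspring)
  if (!is.null(obj)) {
    idx <- select_indices(obj, N, method)
    return(structure(obj[idx, , drop = FALSE], selected = idx))
  }
  stopifnot(is.list(parents), is.list(offspring))
  pool <- c(parents, offspring)
  obj <- do.call(rbind, lapply(pool, function(r) r$objectives))
  idx <- select_indices(obj, N, method)
  structure(pool[idx], selected = idx)
}

#' Diversity-aware multi-objective survival selection
#'
#' The selection operator of the Evo-Diverse sampler: non-dominated fronts
#' of the combined parent + offspring population are taken whole, in order,
#' for as long as they fit; the first front that does not fit is ranked by
#' crowding distance (descending) and only its least-crowded members fill
#' the remaining slots. Only the current 2N individuals are used -- no
#' archive. Output size is exactly N; whenever the first front fits it
#' survives entirely (front elitism). Ties in crowding distance are broken
#' by input order so runs are reproducible.
#'
#' `parents` and `offspring` may be numeric objective matrices (one row per
#' individual) or lists of records with an `objectives` field; the combined
#' pool is parents stacked over offspring. The selected input indices are
#' attached as attribute `selected`.
#'
#' @param parents,offspring objective matrices or record lists, N each.
#' @param N number of survivors.
#' @return Selected rows (matrix in, matrix out) or records.
#' @export
select_evo_diverse <- function(parents, offspring, N) {
  select_pop(parents, offspring, N, "evo_diverse")
}

#' Total-energy truncation selection (memetic-EA baseline)
#'
#' Keeps the N individuals of the combined population with the lowest total
#' energy (sum of the objectives); ties keep input order.
#'
#' @inheritParams select_evo_diverse
#' @return As [select_evo_diverse()].
#' @export
select_mea <- function(parents, offspring, N) {
  select_pop(parents, offspring, N, "mea")
}

#' Pareto-rank then total-energy selection (baseline)
#'
#' Lexicographic: Pareto rank ascending, then total energy ascending.
#'
#' @inheritParams select_evo_diverse
#' @return As [select_evo_diverse()].
#' @export
select_mea_pr <- function(parents, offspring, N) {
  select_pop(parents, offspring, N, "mea_pr")
}

#' Pareto-rank, Pareto-count, total-energy selection (baseline)
#'
#' Lexicographic: Pareto rank ascending, Pareto count descending, then
#' total energy ascending.
#'
#' @inheritParams select_evo_diverse
#' @return As [select_evo_diverse()].
#' @export
select_mea_prpc <- function(parents, offspring, N) {
  select_pop(parents, offspring, N, "mea_prpc")
}
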