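# Independent oracles used across the suite. Each deliberately re-derives
# its quantity through a different route than the package implementation.

# Horn's closed-form quaternion superposition: minimal RMSD from the largest
# eigenvalue of the 4x4 key matrix.
horn_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(P0, Q0)
  K <- rbind(
    c(S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
      S[3, 1] - S[1, 3], S[1, 2] - S[2, 1]),
    c(S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
      S[1, 2] + S[2, 1], S[3, 1] + S[1, 3]),
    c(S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
      -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2]),
    c(S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
      S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]))
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)))
}

# Explicit cross-product torsion formula (reference IUPAC implementation).
torsion_oracle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

# Direct trigonometric placement of a planar trans dipeptide: the CA-CA
# distance implied by the geometry constants alone.
trans_ca_ca_oracle <- function(geo) {
  u <- function(th) c(cos(th * pi / 180), sin(th * pi / 180))
  dir <- 0
  ca1 <- c(0, 0) + geo[["b_nca"]] * u(dir)
  dir <- dir + (180 - geo[["a_ncac"]])
  c1 <- ca1 + geo[["b_cac"]] * u(dir)
  dir <- dir - (180 - geo[["a_cacn"]])
  n2 <- c1 + geo[["b_cn"]] * u(dir)
  dir <- dir + (180 - geo[["a_cnca"]])
  ca2 <- n2 + geo[["b_nca"]] * u(dir)
  sqrt(sum((ca2 - ca1)^2))
}

# Brute-force domination counts via explicit double loops.
brute_pr_pc <- function(obj) {
  n <- nrow(obj)
  PR <- PC <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(obj[j, ] < obj[i, ])) {
        PR[i] <- PR[i] + 1L
        PC[j] <- PC[j] + 1L
      }
    }
  }
  list(PR = PR, PC = PC)
}

# Repeated-peeling front oracle: remove the non-dominated set, repeat, stop
# once at least N individuals have been assigned.
peel_fronts <- function(obj, N) {
  left <- seq_len(nrow(obj))
  fronts <- list()
  total <- 0
  while (length(left) > 0 && total < N) {
    sub <- obj[left, , drop = FALSE]
    nd <- vapply(seq_along(left), function(i)
      !any(vapply(seq_along(left), function(j)
        j != i && all(sub[j, ] < sub[i, ]), logical(1))), logical(1))
    fr <- left[nd]
    fronts[[length(fronts) + 1]] <- fr
    total <- total + length(fr)
    left <- setdiff(left, fr)
  }
  fronts
}

# Straight-line reimplementation of the printed selection rules.
brute_select <- function(obj, N, method) {
  n <- nrow(obj)
  total <- rowSums(obj)
  cnt <- brute_pr_pc(obj)
  if (method == "mea") return(order(total)[seq_len(N)])
  if (method == "mea_pr") return(order(cnt$PR, total)[seq_len(N)])
  if (method == "mea_prpc") return(order(cnt$PR, -cnt$PC, total)[seq_len(N)])
  # evo_diverse: whole peeled fronts, then descending crowding distance
  fronts <- peel_fronts(obj, N)
  picked <- integer(0)
  for (fr in fronts) {
    if (length(picked) + length(fr) <= N) {
      picked <- c(picked, fr)
    } else {
      cd <- brute_crowding(obj[fr, , drop = FALSE])
      picked <- c(picked, fr[order(-cd)[seq_len(N - length(picked))]])
      break
    }
    if (length(picked) == N) break
  }
  picked
}

# Literal transcription of the crowding-distance assignment.
brute_crowding <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    ord <- order(obj[, k])
    rng <- obj[ord[n], k] - obj[ord[1], k]
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    if (rng > 0)
      for (i in 2:(n - 1))
        d[ord[i]] <- d[ord[i]] +
          (obj[ord[i + 1], k] - obj[ord[i - 1], k]) / rng
  }
  d
}

# Exhaustive-seed superposition search: every gapless window of every
# length >= 4 seeds the iterative extension. Bounds the heuristic search
# used by tm_score() / gdt_ts().
exhaustive_metric <- function(P, Q, radius, value) {
  L <- nrow(P)
  best <- -Inf
  for (w in 4:L) {
    for (s in seq_len(L - w + 1)) {
      idx <- s:(s + w - 1)
      for (iter in 1:20) {
        sup <- kabsch(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
        Pm <- sweep(P %*% sup$rotation, 2, sup$translation, "+")
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

exhaustive_tm <- function(P, Q) {
  L <- nrow(P)
  d0 <- max(0.5, 1.24 * (max(L - 15, 0))^(1 / 3) - 1.8)
  exhaustive_metric(P, Q, d0, function(d) mean(1 / (1 + (d / d0)^2)))
}

exhaustive_gdt <- function(P, Q) {
  mean(vapply(c(1, 2, 4, 8), function(cut)
    exhaustive_metric(P, Q, cut, function(d) mean(d <= cut)), numeric(1)))
}

random_rigid_motion <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, 0, 10))
}

# Small random-coil conformation for property tests.
random_conformation <- function(l, seq1 = NULL) {
  if (is.null(seq1)) seq1 <- sample(c("A", "G", "L", "S", "V"), l, TRUE)
  conformation(seq1, cbind(stats::runif(l, -180, 179),
                           stats::runif(l, -180, 179),
                           180 + stats::rnorm(l, 0, 5)))
}

# Library whose only configuration at each position is the chain's current
# local torsions (every move is the identity).
identity_library <- function(conf, f) {
  l <- length(conf$sequence)
  entries <- lapply(seq_len(l - f + 1), function(p)
    matrix(as.vector(t(conf$dihedrals[p:(p + f - 1), ])), nrow = 1))
  fragment_library(f, entries)
}
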