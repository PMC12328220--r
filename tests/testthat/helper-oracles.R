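# Independent oracles: deliberately naive reimplementations used to check
# the package's results. They share no code with the implementation paths
# they validate.

# best-achievable RMSD by scanning rotations on an Euler-angle grid
# (coarse pass + local refinement), translations handled by centering
oracle_rmsd_grid <- function(A, B, coarse = 15, fine = 1.5) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, c) {
    sqrt(mean(rowSums((B %*% t(rot(a, b, c)) - A)^2)))
  }
  best <- c(0, 0, 0); best_v <- Inf
  step <- coarse * pi / 180
  for (a in seq(0, 2 * pi, by = step)) {
    for (b in seq(0, pi, by = step)) {
      for (c in seq(0, 2 * pi, by = step)) {
        v <- eval_rmsd(a, b, c)
        if (v < best_v) { best_v <- v; best <- c(a, b, c) }
      }
    }
  }
  step2 <- fine * pi / 180
  for (rounds in 1:2) {
    grid <- expand.grid(a = best[1] + seq(-step, step, by = step2),
                        b = best[2] + seq(-step, step, by = step2),
                        c = best[3] + seq(-step, step, by = step2))
    for (r in seq_len(nrow(grid))) {
      v <- eval_rmsd(grid$a[r], grid$b[r], grid$c[r])
      if (v < best_v) { best_v <- v; best <- as.numeric(grid[r, ]) }
    }
    step <- step2; step2 <- step2 / 5
  }
  best_v
}

# connected components by explicit depth-first search
oracle_components_dfs <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)),
                                as.character(nodes)), function(x) integer(0))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- as.character(edges[r, 1]); b <- as.character(edges[r, 2])
      adj[[a]] <- c(adj[[a]], edges[r, 2])
      adj[[b]] <- c(adj[[b]], edges[r, 1])
    }
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), as.character(nodes))
  comps <- list()
  for (start in nodes) {
    if (seen[[as.character(start)]]) next
    stack <- start
    comp <- integer(0)
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[as.character(v)]]) next
      seen[[as.character(v)]] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[as.character(v)]])
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Kendall's tau-b by explicit pair counting with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- D <- 0; tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx * dy > 0) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Cliff's delta by explicit double loop
oracle_cliffs <- function(a, b) {
  gt <- lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1 else if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# AUC by explicit pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by a hand-evaluated step-up pass
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# average-linkage agglomeration from first principles; flat clusters are
# formed by merging while the smallest average inter-cluster distance is
# at or below the cutoff
oracle_average_linkage <- function(D, cutoff) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  ## canonical labelling by first occurrence
  match(labels, unique(labels))
}

# Kabsch-Sander style H-bond energies computed independently for the
# secondary-structure checks (CO of i with NH of j)
oracle_hbond_energy <- function(N, CA, C, O) {
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    d1 <- N[i, ] - C[i - 1, ]; d1 <- d1 / sqrt(sum(d1^2))
    d2 <- N[i, ] - O[i - 1, ]; d2 <- d2 / sqrt(sum(d2^2))
    s <- d1 + d2
    H[i, ] <- N[i, ] + s / sqrt(sum(s^2))
  }
  E <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (abs(i - j) <= 1 || anyNA(H[j, ])) next
      rON <- sqrt(sum((O[i, ] - N[j, ])^2))
      rCH <- sqrt(sum((C[i, ] - H[j, ])^2))
      rOH <- sqrt(sum((O[i, ] - H[j, ])^2))
      rCN <- sqrt(sum((C[i, ] - N[j, ])^2))
      E[i, j] <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}
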