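# Shared fixtures and independent oracles for the test suite.

# The two digestive-system diseases used throughout as a golden example:
# focal terms with hand-checkable ancestor DAGs.
worked_example_dags <- function(delta = 0.5) {
  dsn <- disease_dag(
    "Digestive System Neoplasms",
    data.frame(
      child  = c("Digestive System Neoplasms", "Digestive System Neoplasms",
                 "Digestive System Diseases", "Neoplasms by Site"),
      parent = c("Digestive System Diseases", "Neoplasms by Site",
                 "Neoplasms", "Neoplasms")
    ),
    delta = delta
  )
  bgn <- disease_dag(
    "Breast Gastrointestinal Neoplasms",
    data.frame(
      child  = c("Breast Gastrointestinal Neoplasms",
                 "Breast Gastrointestinal Neoplasms",
                 "Gastrointestinal Diseases",
                 "Digestive System Neoplasms", "Digestive System Neoplasms",
                 "Digestive System Diseases", "Neoplasms by Site"),
      parent = c("Gastrointestinal Diseases", "Digestive System Neoplasms",
                 "Digestive System Diseases",
                 "Digestive System Diseases", "Neoplasms by Site",
                 "Neoplasms", "Neoplasms")
    ),
    delta = delta
  )
  list(dsn = dsn, bgn = bgn)
}

# Independent oracle for term contributions: delta^(shortest hop count
# from the focal term), by breadth-first search over child -> parent edges.
bfs_contributions <- function(dag) {
  dist <- setNames(rep(Inf, length(dag$nodes)), dag$nodes)
  dist[dag$disease_id] <- 0
  frontier <- dag$disease_id
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (node in frontier) {
      parents <- dag$edges$parent[dag$edges$child == node]
      improve <- parents[dist[parents] > dist[node] + 1]
      dist[improve] <- dist[node] + 1
      nxt <- c(nxt, improve)
    }
    frontier <- unique(nxt)
  }
  dag$delta^dist
}

# Exhaustive O(m * n) pair-counting AUC oracle.
pairwise_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) {
    wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  }
  wins / (length(pos) * length(neg))
}

# Brute-force minimizer of w' A w over the probability simplex,
# enumerated on a grid of the given step (k <= 3).
grid_simplex_min <- function(A, step = 1e-3) {
  k <- nrow(A)
  if (k == 1) {
    return(list(weights = 1, objective = A[1, 1]))
  }
  if (k == 2) {
    w1 <- seq(0, 1, by = step)
    obj <- A[1, 1] * w1^2 + A[2, 2] * (1 - w1)^2 + 2 * A[1, 2] * w1 * (1 - w1)
    i <- which.min(obj)
    return(list(weights = c(w1[i], 1 - w1[i]), objective = obj[i]))
  }
  if (k == 3) {
    g <- seq(0, 1, by = step)
    grid <- expand.grid(w1 = g, w2 = g)
    grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
    w1 <- grid$w1; w2 <- grid$w2; w3 <- pmax(0, 1 - w1 - w2)
    obj <- A[1, 1] * w1^2 + A[2, 2] * w2^2 + A[3, 3] * w3^2 +
      2 * (A[1, 2] * w1 * w2 + A[1, 3] * w1 * w3 + A[2, 3] * w2 * w3)
    i <- which.min(obj)
    return(list(weights = c(w1[i], w2[i], w3[i]), objective = obj[i]))
  }
  stop("grid oracle only supports k <= 3")
}

# Independent truncated random-walk-with-restart on a single network:
# the averaged two-network update with identical networks and equal caps.
balanced_rwr <- function(P0, M, Y0, alpha, steps) {
  P <- P0
  for (i in seq_len(steps)) {
    P <- ((1 - alpha) * P %*% M + alpha * Y0 +
            (1 - alpha) * M %*% P + alpha * Y0) / 2
  }
  P
}

# Random labeled binary association matrix.
random_Y <- function(nl, nd, density = 0.3, seed = 1) {
  set.seed(seed)
  Y <- matrix(rbinom(nl * nd, 1, density), nl,
              dimnames = list(paste0("l", seq_len(nl)),
                              paste0("d", seq_len(nd))))
  if (sum(Y) == 0) Y[1, 1] <- 1
  association_matrix(Y)
}

# Random symmetric similarity matrix with unit diagonal.
random_sim <- function(n, seed = 1, labels = paste0("e", seq_len(n))) {
  set.seed(seed)
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(labels, labels)
  S
}
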