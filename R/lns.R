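#' Gram matrix of reconstruction differences
#'
#' For an entity with feature vector `xi` and neighbor feature vectors
#' `N` (one per row), `G[j, k] = (xi - N[j, ]) . (xi - N[k, ])`. `G` is
#' symmetric positive semidefinite by construction.
#'
#' @param xi numeric feature vector.
#' @param neighbors matrix of neighbor feature vectors, one per row.
#' @return k x k symmetric PSD matrix.
#' @export
build_gram <- function(xi, neighbors) {
  neighbors <- as.matrix(neighbors)
  if (length(xi) != ncol(neighbors)) {
    stop("feature dimensions of entity and neighbors disagree", call. = FALSE)
  }
  D <- sweep(-neighbors, 2, xi, "+")   # rows: xi - x_ij
  G <- tcrossprod(D)
  (G + t(G)) / 2
}

#' Simplex-constrained reconstruction weights
#'
#' Solves `min w' (G + lam I) w` subject to `sum(w) = 1`, `w >= 0`
#' exactly, by a finite active-set iteration on the KKT system: the
#' equality-constrained minimizer over the current free set is
#' `(G_F + lam I)^{-1} 1`, normalized to sum 1; variables that come out
#' negative are clamped to zero, and a clamped variable re-enters when
#' its KKT multiplier `2 (A w)_i - mu` is negative. The ridge `lam > 0`
#' makes the objective strictly convex, so the solution is unique and
#' the iteration terminates.
#'
#' @param G symmetric PSD k x k matrix from [build_gram()].
#' @param lam ridge regularizer > 0.
#' @return list with `weights` (nonnegative, summing to 1) and
#'   `objective` (`w' (G + lam I) w` at the optimum).
#' @export
solve_weights <- function(G, lam = 1) {
  G <- as.matrix(G)
  k <- nrow(G)
  stopifnot(k == ncol(G), lam > 0)
  if (k == 1) {
    return(list(weights = 1, objective = as.numeric(G[1, 1] + lam)))
  }
  A <- (G + t(G)) / 2 + diag(lam, k)

  free <- rep(TRUE, k)
  w <- rep(0, k)
  for (iter in seq_len(3 * k + 10)) {
    # equality-constrained minimizer on the free set
    af <- A[free, free, drop = FALSE]
    v <- tryCatch(solve(af, rep(1, sum(free))),
                  error = function(e) NULL)
    if (is.null(v)) {
      stop("LNS quadratic program: singular KKT system", call. = FALSE)
    }
    wf <- v / sum(v)
    if (min(wf) < -1e-12) {
      # clamp the most negative variable and retry
      drop_idx <- which(free)[which.min(wf)]
      free[drop_idx] <- FALSE
      if (!any(free)) {
        stop("LNS quadratic program: no feasible free set", call. = FALSE)
      }
      next
    }
    w[] <- 0
    w[free] <- pmax(wf, 0)
    # dual feasibility of the clamped variables
    mu <- 2 * sum(w * (A %*% w))   # = w' A w * 2 since (Aw)_F = mu/2 * 1
    grad <- 2 * as.numeric(A %*% w)
    viol <- !free & (grad - mu < -1e-10)
    if (!any(viol)) {
      w <- w / sum(w)
      return(list(weights = w,
                  objective = as.numeric(t(w) %*% A %*% w)))
    }
    free[which(viol)[which.max((mu - grad)[viol])]] <- TRUE
  }
  stop("LNS quadratic program did not converge", call. = FALSE)
}

#' Linear neighborhood similarity weight matrix
#'
#' Every entity is reconstructed from its k most similar neighbors by
#' the simplex-constrained quadratic program of [solve_weights()]; the
#' optimal weights form row i of the (generally asymmetric) weight
#' matrix W. Rows are nonnegative, sum to 1, have at most k nonzeros and
#' zero diagonal.
#'
#' @param features n x m matrix of feature vectors, one entity per row
#'   (typically WKNKN-preprocessed association profiles).
#' @param k neighbor count, `1 <= k < n`.
#' @param lam ridge regularizer > 0.
#' @param neighbor_similarity optional n x n matrix used to pick each
#'   entity's neighbors (largest entries of column/row i, self
#'   excluded, ties by ascending index). Defaults to negative squared
#'   Euclidean feature distance.
#' @param symmetrize if `TRUE`, return `(W + t(W)) / 2`.
#' @return n x n weight matrix (kind `"lns"`).
#' @export
lns_matrix <- function(features, k, lam = 1, neighbor_similarity = NULL,
                       symmetrize = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1 || k >= n) {
    stop(sprintf("`k` = %d must satisfy 1 <= k < n = %d", k, n), call. = FALSE)
  }
  if (is.null(neighbor_similarity)) {
    sq <- rowSums(features^2)
    neighbor_similarity <- -(outer(sq, sq, "+") - 2 * tcrossprod(features))
  } else {
    neighbor_similarity <- as.matrix(neighbor_similarity)
    stopifnot(nrow(neighbor_similarity) == n, ncol(neighbor_similarity) == n)
  }

  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- top_k_neighbors(neighbor_similarity[i, ], i, k)
    G <- build_gram(features[i, ], features[nb, , drop = FALSE])
    sol <- tryCatch(solve_weights(G, lam), error = function(e) {
      stop(sprintf("LNS failed for entity %d ('%s'): %s",
                   i, rownames(features)[i] %||% as.character(i),
                   conditionMessage(e)), call. = FALSE)
    })
    W[i, nb] <- sol$weights
  }
  if (symmetrize) {
    W <- (W + t(W)) / 2
  }
  labels <- rownames(features) %||% paste0("e", seq_len(n))
  dimnames(W) <- list(labels, labels)
  similarity_matrix(W, kind = "lns")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
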