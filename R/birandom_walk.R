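#' Column-normalize a network matrix
#'
#' Divides every nonzero column by its sum; all-zero columns (isolated
#' nodes) are left zero, so the result is column-stochastic on the
#' non-isolated part of the network.
#'
#' @param W square nonnegative matrix (e.g. LNS weights).
#' @return column-normalized matrix with the same labels.
#' @export
column_normalize <- function(W) {
  W <- as.matrix(unclass_sim(W))
  if (nrow(W) != ncol(W)) {
    stop("network matrix must be square", call. = FALSE)
  }
  if (any(W < 0)) {
    stop("network matrix must be nonnegative", call. = FALSE)
  }
  cs <- colSums(W)
  nz <- cs > 0
  W[, nz] <- sweep(W[, nz, drop = FALSE], 2, cs[nz], "/")
  W
}

#' One walk step on the disease network
#'
#' `(1 - alpha) * P %*% MD + alpha * Y0`: the current probability mass
#' diffuses along disease-disease edges, anchored to the restart matrix
#' with weight `alpha`.
#'
#' @param P current nl x nd probability matrix.
#' @param MD column-normalized nd x nd disease network.
#' @param Y0 nl x nd restart matrix.
#' @param alpha restart weight in (0, 1\].
#' @return updated nl x nd matrix.
#' @export
walk_step_disease <- function(P, MD, Y0, alpha) {
  if (ncol(P) != nrow(MD) || !identical(dim(P), dim(Y0))) {
    stop("dimension mismatch in disease walk step", call. = FALSE)
  }
  (1 - alpha) * P %*% MD + alpha * Y0
}

#' One walk step on the lncRNA network
#'
#' `(1 - alpha) * ML %*% P + alpha * Y0`.
#'
#' @param P current nl x nd probability matrix.
#' @param ML column-normalized nl x nl lncRNA network.
#' @inheritParams walk_step_disease
#' @return updated nl x nd matrix.
#' @export
walk_step_lnc <- function(P, ML, Y0, alpha) {
  if (nrow(P) != ncol(ML) || !identical(dim(P), dim(Y0))) {
    stop("dimension mismatch in lncRNA walk step", call. = FALSE)
  }
  (1 - alpha) * ML %*% P + alpha * Y0
}

#' Unbalanced bi-random walk
#'
#' Runs restart walks on the disease network and the lncRNA network
#' simultaneously, with independent step caps `s1` and `s2` to respect
#' the different topologies of the two networks. While both walks are
#' active their updates are averaged; after a cap is passed only the
#' other walk continues. The walk runs exactly `max(s1, s2)` iterations
#' (the caps are step counts, not a convergence tolerance).
#'
#' `P(0)` is the preprocessed association matrix divided by its total
#' sum; by default the restart matrix is this same `P(0)`, so identity
#' networks (or `alpha = 1`) leave `P(0)` fixed. Set
#' `restart_unnormalized = TRUE` to restart to the raw matrix instead.
#'
#' @param Y_init preprocessed association matrix (nl x nd), not all
#'   zero.
#' @param MD,ML column-normalized disease / lncRNA networks.
#' @param alpha restart weight in (0, 1\].
#' @param s1,s2 step caps (nonnegative integers, `s1 + s2 >= 1`).
#' @param restart_unnormalized restart to raw `Y_init` instead of the
#'   sum-normalized `P(0)`.
#' @return final score matrix `F` (nl x nd) with the labels of
#'   `Y_init`; higher scores rank candidate associations first.
#' @export
unbalanced_birandom_walk <- function(Y_init, MD, ML, alpha = 0.9,
                                     s1 = 3, s2 = 1,
                                     restart_unnormalized = FALSE) {
  check_labels_agree(colnames(Y_init), colnames(MD), "disease")
  check_labels_agree(rownames(Y_init), colnames(ML), "lncRNA")
  if (s1 < 0 || s2 < 0 || s1 + s2 < 1) {
    stop("step caps must be nonnegative with s1 + s2 >= 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  total <- sum(Y_init)
  if (total == 0) {
    stop("association matrix is all zero: nothing to walk from", call. = FALSE)
  }

  P <- unclass_sim(as.matrix(Y_init)) / total
  Y0 <- if (restart_unnormalized) unclass_sim(as.matrix(Y_init)) else P

  for (p in seq_len(max(s1, s2))) {
    rD <- 0; rL <- 0
    DP <- NULL; LP <- NULL
    if (p <= s1) {
      DP <- walk_step_disease(P, MD, Y0, alpha)
      rD <- 1
    }
    if (p <= s2) {
      LP <- walk_step_lnc(P, ML, Y0, alpha)
      rL <- 1
    }
    P <- if (rD == 1 && rL == 1) (DP + LP) / 2 else if (rD == 1) DP else LP
  }
  dimnames(P) <- dimnames(Y_init)
  P
}
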