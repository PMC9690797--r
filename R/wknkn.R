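#' WKNKN preprocessing of a sparse association matrix
#'
#' Weighted K-nearest known neighbors: every zero cell of the binary
#' association matrix is replaced by an interaction likelihood inferred
#' from the profiles of the K most similar diseases and the K most
#' similar lncRNAs. Known associations (cells equal to 1) are left
#' untouched.
#'
#' For each disease `dj`, the K most similar other diseases (by `FD`,
#' descending; ties broken by ascending index) contribute
#' `Yd(, dj) = (1/Zd) * sum_r eta^(r-1) * FD(dr, dj) * Y(, dr)` with
#' `Zd = sum_r FD(dr, dj)`; symmetrically for each lncRNA row with
#' `FL`. Zero cells become the average `(Yd + Yl) / 2` at that cell.
#' With `eta = 1` the fill is an exact similarity-weighted mean of the
#' neighbor profiles; with `eta < 1` later neighbors are down-weighted
#' in the numerator only (set `normalize_with_decay = TRUE` to carry the
#' decay into the normalizer as well).
#'
#' Fused similarities are divided by their maximum entry before use so
#' the filled cells are probabilities in \[0, 1\] regardless of the
#' fusion weights. An entity whose neighbor similarities are all zero
#' contributes a zero profile.
#'
#' @param Y binary association matrix (lncRNAs x diseases).
#' @param FD fused disease similarity over `colnames(Y)`.
#' @param FL fused lncRNA similarity over `rownames(Y)`.
#' @param K neighbor count, `1 <= K < min(dim(Y))`.
#' @param eta decay factor in (0, 1\].
#' @param normalize_with_decay if `TRUE`, `Zd` (and `Zl`) also carry the
#'   `eta^(r-1)` decay.
#' @return association matrix with zero cells filled in \[0, 1\].
#' @export
wknkn <- function(Y, FD, FL, K = 7, eta = 1, normalize_with_decay = FALSE) {
  check_labels_agree(colnames(Y), rownames(FD), "disease")
  check_labels_agree(rownames(Y), rownames(FL), "lncRNA")
  if (K < 1 || K != round(K)) {
    stop("`K` must be an integer >= 1", call. = FALSE)
  }
  if (K >= min(dim(Y))) {
    stop(sprintf("`K` = %d must be smaller than min(nl, nd) = %d",
                 K, min(dim(Y))), call. = FALSE)
  }
  if (eta <= 0 || eta > 1) {
    stop("`eta` must lie in (0, 1]", call. = FALSE)
  }

  FD <- max_normalize(FD)
  FL <- max_normalize(FL)
  decay <- eta^(seq_len(K) - 1)

  nl <- nrow(Y); nd <- ncol(Y)
  Yd <- matrix(0, nl, nd)
  for (j in seq_len(nd)) {
    nb <- top_k_neighbors(FD[, j], j, K)
    sims <- FD[nb, j]
    Z <- if (normalize_with_decay) sum(decay * sims) else sum(sims)
    if (Z > 0) {
      Yd[, j] <- Y[, nb, drop = FALSE] %*% (decay * sims) / Z
    }
  }
  Yl <- matrix(0, nl, nd)
  for (i in seq_len(nl)) {
    nb <- top_k_neighbors(FL[, i], i, K)
    sims <- FL[nb, i]
    Z <- if (normalize_with_decay) sum(decay * sims) else sum(sims)
    if (Z > 0) {
      Yl[i, ] <- crossprod(Y[nb, , drop = FALSE], decay * sims) / Z
    }
  }

  out <- unclass_sim(Y)
  fill <- (Yd + Yl) / 2
  zero <- Y == 0
  out[zero] <- pmin(1, pmax(0, fill[zero]))
  association_matrix(out, rownames(Y), colnames(Y))
}

# indices of the k largest entries of `sims`, excluding `self`,
# descending; ties broken by ascending index (stable order sort)
top_k_neighbors <- function(sims, self, k) {
  idx <- setdiff(seq_along(sims), self)
  idx[order(-sims[idx], idx)][seq_len(k)]
}

max_normalize <- function(S) {
  m <- max(S)
  if (m > 0) S / m else S
}
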