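#' Gaussian interaction profile kernel bandwidths
#'
#' The disease bandwidth normalizes by the average squared norm of the
#' disease interaction profiles (columns of `Y`), the lncRNA bandwidth
#' by that of the rows. Under the default convention
#' `gamma_d = nd / sum_j ||Y(, j)||^2`, so the kernel is scale-free in
#' the number of entities; `"reciprocal"` selects the literal mean
#' squared norm instead.
#'
#' @param Y association matrix (lncRNAs x diseases), not all zero.
#' @param convention `"normalized"` (default) or `"reciprocal"`.
#' @return list with `gamma_d`, `gamma_l`, `mu` (number of diseases) and
#'   `nu` (number of lncRNAs).
#' @export
gip_bandwidths <- function(Y, convention = c("normalized", "reciprocal")) {
  convention <- match.arg(convention)
  total <- sum(Y^2)
  if (total == 0) {
    stop("all-zero association matrix: GIP bandwidth undefined", call. = FALSE)
  }
  mu <- ncol(Y)   # diseases
  nu <- nrow(Y)   # lncRNAs
  if (convention == "normalized") {
    list(gamma_d = mu / total, gamma_l = nu / total, mu = mu, nu = nu)
  } else {
    list(gamma_d = total / mu, gamma_l = total / nu, mu = mu, nu = nu)
  }
}

#' GIP kernel similarity of diseases
#'
#' `KD[i, j] = exp(-gamma_d * ||Y(, i) - Y(, j)||^2)` over the disease
#' interaction profiles (columns of `Y`).
#'
#' @param Y association matrix.
#' @param params bandwidths from [gip_bandwidths()]; computed from `Y`
#'   when omitted.
#' @return symmetric disease similarity matrix with unit diagonal
#'   (kind `"gip"`).
#' @export
gip_disease <- function(Y, params = gip_bandwidths(Y)) {
  K <- gaussian_profile_kernel(t(Y), params$gamma_d)
  dimnames(K) <- list(colnames(Y), colnames(Y))
  similarity_matrix(K, kind = "gip")
}

#' GIP kernel similarity of lncRNAs
#'
#' `KL[i, j] = exp(-gamma_l * ||Y(i, ) - Y(j, )||^2)` over the lncRNA
#' interaction profiles (rows of `Y`).
#'
#' @inheritParams gip_disease
#' @return symmetric lncRNA similarity matrix (kind `"gip"`).
#' @export
gip_lnc <- function(Y, params = gip_bandwidths(Y)) {
  K <- gaussian_profile_kernel(Y, params$gamma_l)
  dimnames(K) <- list(rownames(Y), rownames(Y))
  similarity_matrix(K, kind = "gip")
}

# rows of X are profiles; returns exp(-gamma * squared distances)
gaussian_profile_kernel <- function(X, gamma) {
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0   # guard tiny negative round-off
  exp(-gamma * d2)
}

#' Logistic rescaling of a kernel matrix
#'
#' Elementwise `L = 1 / (1 + exp(c * K + x))`. With `x = log(9999)` a
#' kernel value of 0 maps to exactly 1e-4, and a negative `c` makes the
#' map increasing, spreading the compressed upper range of the Gaussian
#' kernel over (0, 1). The exponent is clipped to +/-709 so the result
#' never overflows and never reaches exactly 0 or 1.
#'
#' @param K similarity matrix.
#' @param c slope (typically negative).
#' @param x offset (default `log(9999)`).
#' @return rescaled matrix (kind `"logistic"`).
#' @export
logistic_transform <- function(K, c = -21, x = log(9999)) {
  arg <- c * K + x
  arg[arg > 709] <- 709
  arg[arg < -709] <- -709
  L <- 1 / (1 + exp(arg))
  dimnames(L) <- dimnames(K)
  similarity_matrix(L, kind = "logistic")
}

#' Linear fusion of two similarity matrices
#'
#' `F = f1 * S_a + f2 * S_b`, no renormalization: the pipeline uses raw
#' weights such as `f1 = 2`, `f2 = 10`, so fused entries may exceed 1.
#'
#' @param S_a,S_b similarity matrices with identical labels.
#' @param f1,f2 nonnegative weights, not both zero.
#' @return fused matrix (kind `"fused"`).
#' @export
fuse <- function(S_a, S_b, f1 = 2, f2 = 10) {
  if (!identical(dim(S_a), dim(S_b))) {
    stop("fused matrices must have the same shape", call. = FALSE)
  }
  check_labels_agree(rownames(S_a), rownames(S_b), "entity")
  if (f1 < 0 || f2 < 0 || f1 + f2 == 0) {
    stop("fusion weights must be >= 0 and not both zero", call. = FALSE)
  }
  F_ <- f1 * unclass_sim(S_a) + f2 * unclass_sim(S_b)
  dimnames(F_) <- dimnames(S_a)
  similarity_matrix(F_, kind = "fused")
}

unclass_sim <- function(m) {
  attr(m, "kind") <- NULL
  m
}
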