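#' Pipeline configuration
#'
#' Collects every tunable of the prediction pipeline with validation.
#' Defaults are the values tuned by leave-one-out cross-validation on the
#' curated lncRNA-disease dataset the method was developed on.
#'
#' @param delta semantic contribution factor in \[0, 1\]: each hop up the
#'   disease term hierarchy multiplies a term's contribution by `delta`.
#' @param c slope of the logistic rescaling of the Gaussian interaction
#'   profile (GIP) kernel; negative so that larger kernel values map to
#'   larger similarities.
#' @param x offset of the logistic rescaling. The default `log(9999)`
#'   pins the image of a zero kernel value at exactly 1e-4.
#' @param f1,f2 nonnegative linear fusion weights for the
#'   semantic/functional similarity and the logistic-rescaled GIP kernel
#'   respectively; not both zero.
#' @param K neighbor count for WKNKN preprocessing (>= 1).
#' @param eta WKNKN decay factor in (0, 1\]: the r-th nearest neighbor's
#'   weight carries a factor `eta^(r-1)`.
#' @param kl,kd neighbor counts for the linear neighborhood similarity
#'   (LNS) of lncRNAs and diseases (>= 1; capped at n - 1 at run time).
#' @param lam ridge regularizer (> 0) of the LNS quadratic program.
#' @param alpha restart weight of the bi-random walk, in (0, 1\].
#' @param s1,s2 step caps (nonnegative integers, `s1 + s2 >= 1`) of the
#'   walks on the disease and lncRNA networks.
#' @param seed integer seed for any stochastic routine.
#' @param bandwidth_convention `"normalized"` (default) sets the GIP
#'   bandwidth to n / sum of squared profile norms; `"reciprocal"` uses
#'   the literal mean squared norm instead.
#' @param normalize_with_decay if `TRUE`, the WKNKN normalizer also
#'   carries the `eta^(r-1)` decay; default `FALSE` (normalizer is the
#'   plain sum of neighbor similarities).
#' @param restart_unnormalized if `TRUE`, the walk restarts to the raw
#'   preprocessed association matrix instead of its sum-normalized form.
#' @param lns_features `"wknkn"` (default) reconstructs entities from
#'   their WKNKN-preprocessed association profiles; `"fused"` uses rows
#'   of the fused similarity matrix as feature vectors.
#' @param lns_neighbor_metric `"fused"` (default) picks LNS neighbors by
#'   fused similarity; `"euclidean"` by feature-space distance.
#' @param lns_symmetrize if `TRUE`, the LNS weight matrix is replaced by
#'   `(W + t(W)) / 2` before column normalization; default `FALSE`.
#'
#' @return An object of class `ubrw_config` (a validated named list).
#' @examples
#' cfg <- ubrw_config()
#' cfg$alpha
#' @export
ubrw_config <- function(delta = 0.5,
                        c = -21,
                        x = log(9999),
                        f1 = 2,
                        f2 = 10,
                        K = 7,
                        eta = 1,
                        kl = 40,
                        kd = 60,
                        lam = 1,
                        alpha = 0.9,
                        s1 = 3,
                        s2 = 1,
                        seed = 1L,
                        bandwidth_convention = c("normalized", "reciprocal"),
                        normalize_with_decay = FALSE,
                        restart_unnormalized = FALSE,
                        lns_features = c("wknkn", "fused"),
                        lns_neighbor_metric = c("fused", "euclidean"),
                        lns_symmetrize = FALSE) {
  bandwidth_convention <- match.arg(bandwidth_convention)
  lns_features <- match.arg(lns_features)
  lns_neighbor_metric <- match.arg(lns_neighbor_metric)

  stop_unless(is.numeric(delta), length(delta) == 1, delta >= 0, delta <= 1,
              msg = "`delta` must be a single number in [0, 1]")
  stop_unless(is.numeric(c), length(c) == 1, is.finite(c),
              msg = "`c` must be a single finite number")
  stop_unless(is.numeric(x), length(x) == 1, is.finite(x),
              msg = "`x` must be a single finite number")
  stop_unless(is.numeric(f1), f1 >= 0, is.numeric(f2), f2 >= 0, f1 + f2 > 0,
              msg = "`f1`, `f2` must be >= 0 and not both zero")
  stop_unless(is.numeric(K), K >= 1, K == round(K),
              msg = "`K` must be an integer >= 1")
  stop_unless(is.numeric(eta), eta > 0, eta <= 1,
              msg = "`eta` must lie in (0, 1]")
  stop_unless(is.numeric(kl), kl >= 1, kl == round(kl),
              is.numeric(kd), kd >= 1, kd == round(kd),
              msg = "`kl`, `kd` must be integers >= 1")
  stop_unless(is.numeric(lam), lam > 0,
              msg = "`lam` must be > 0")
  stop_unless(is.numeric(alpha), alpha > 0, alpha <= 1,
              msg = "`alpha` must lie in (0, 1]")
  stop_unless(is.numeric(s1), s1 >= 0, s1 == round(s1),
              is.numeric(s2), s2 >= 0, s2 == round(s2), s1 + s2 >= 1,
              msg = "`s1`, `s2` must be nonnegative integers with s1 + s2 >= 1")
  stop_unless(is.numeric(seed), length(seed) == 1, seed == round(seed),
              msg = "`seed` must be an integer")

  structure(
    list(delta = delta, c = c, x = x, f1 = f1, f2 = f2,
         K = as.integer(K), eta = eta,
         kl = as.integer(kl), kd = as.integer(kd), lam = lam,
         alpha = alpha, s1 = as.integer(s1), s2 = as.integer(s2),
         seed = as.integer(seed),
         bandwidth_convention = bandwidth_convention,
         normalize_with_decay = isTRUE(normalize_with_decay),
         restart_unnormalized = isTRUE(restart_unnormalized),
         lns_features = lns_features,
         lns_neighbor_metric = lns_neighbor_metric,
         lns_symmetrize = isTRUE(lns_symmetrize)),
    class = "ubrw_config"
  )
}

#' @export
print.ubrw_config <- function(x, ...) {
  cat("ubrw pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]], digits = 6)))
  }
  invisible(x)
}

# assert helper: all ... must be TRUE, otherwise stop with msg
stop_unless <- function(..., msg) {
  if (!all(vapply(list(...), isTRUE, logical(1)))) {
    stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}
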