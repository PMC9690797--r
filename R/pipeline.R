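#' Full link-prediction pipeline
#'
#' Runs the complete method on a binary association matrix and a disease
#' semantic similarity matrix:
#' \enumerate{
#'   \item GIP kernel similarities of lncRNAs and diseases from `Y`,
#'     rescaled by the logistic transform;
#'   \item lncRNA functional similarity from the associated disease
#'     sets;
#'   \item linear fusion `FD = f1 * Sdis + f2 * LD`,
#'     `FL = f1 * Sl + f2 * LL`;
#'   \item WKNKN preprocessing of `Y` with the fused similarities;
#'   \item linear neighborhood similarity (LNS) weight matrices of both
#'     entity sets, from the preprocessed profiles;
#'   \item unbalanced bi-random walk on the column-normalized LNS
#'     networks.
#' }
#'
#' `K`, `kl` and `kd` are silently capped at the largest admissible
#' value for the matrix at hand (`min(dim(Y)) - 1` and `n - 1`), so the
#' defaults tuned on a 115 x 178 dataset remain usable at desk scale.
#'
#' @param Y binary association matrix (lncRNAs x diseases).
#' @param Sdis disease semantic similarity matrix over `colnames(Y)`.
#' @param cfg a [ubrw_config()].
#' @param keep_intermediates if `TRUE` (default), the fitted object
#'   retains every intermediate matrix.
#' @return object of class `ubrw_fit`: a list with the final score
#'   matrix `F` and (optionally) the intermediates `Sl`, `KD`, `KL`,
#'   `LD`, `LL`, `FD`, `FL`, `Y_wknkn`, `Wd`, `Wl`, `MD`, `ML`, plus
#'   `config`.
#' @examples
#' sim <- synthetic_dataset(synthetic_spec(n_lnc = 12, n_dis = 9,
#'                                         n_blocks = 3, seed = 7))
#' fit <- predict_associations(sim$Y, sim$Sdis,
#'                             ubrw_config(kl = 5, kd = 5, K = 3))
#' fit$F[1:3, 1:3]
#' @export
predict_associations <- function(Y, Sdis, cfg = ubrw_config(),
                                 keep_intermediates = TRUE) {
  stopifnot(inherits(cfg, "ubrw_config"))
  Y <- association_matrix(Y)
  check_labels_agree(colnames(Y), colnames(Sdis), "disease")

  params <- gip_bandwidths(Y, cfg$bandwidth_convention)
  KD <- gip_disease(Y, params)
  KL <- gip_lnc(Y, params)
  LD <- logistic_transform(KD, cfg$c, cfg$x)
  LL <- logistic_transform(KL, cfg$c, cfg$x)
  Sl <- lnc_functional_similarity(Y, Sdis)
  FD <- fuse(Sdis, LD, cfg$f1, cfg$f2)
  FL <- fuse(Sl, LL, cfg$f1, cfg$f2)

  K_eff <- min(cfg$K, min(dim(Y)) - 1)
  Yw <- wknkn(Y, FD, FL, K = K_eff, eta = cfg$eta,
              normalize_with_decay = cfg$normalize_with_decay)

  kl_eff <- min(cfg$kl, nrow(Y) - 1)
  kd_eff <- min(cfg$kd, ncol(Y) - 1)
  lnc_features <- if (cfg$lns_features == "wknkn") Yw else unclass_sim(FL)
  dis_features <- if (cfg$lns_features == "wknkn") t(Yw) else unclass_sim(FD)
  lnc_metric <- if (cfg$lns_neighbor_metric == "fused") unclass_sim(FL) else NULL
  dis_metric <- if (cfg$lns_neighbor_metric == "fused") unclass_sim(FD) else NULL
  Wl <- lns_matrix(lnc_features, k = kl_eff, lam = cfg$lam,
                   neighbor_similarity = lnc_metric,
                   symmetrize = cfg$lns_symmetrize)
  Wd <- lns_matrix(dis_features, k = kd_eff, lam = cfg$lam,
                   neighbor_similarity = dis_metric,
                   symmetrize = cfg$lns_symmetrize)

  MD <- column_normalize(Wd)
  ML <- column_normalize(Wl)
  F_ <- unbalanced_birandom_walk(Yw, MD, ML, alpha = cfg$alpha,
                                 s1 = cfg$s1, s2 = cfg$s2,
                                 restart_unnormalized = cfg$restart_unnormalized)

  out <- list(F = F_, config = cfg)
  if (keep_intermediates) {
    out <- c(out, list(Sl = Sl, KD = KD, KL = KL, LD = LD, LL = LL,
                       FD = FD, FL = FL, Y_wknkn = Yw,
                       Wl = Wl, Wd = Wd, MD = MD, ML = ML))
  }
  structure(out, class = "ubrw_fit")
}

#' @export
print.ubrw_fit <- function(x, ...) {
  cat(sprintf("link-prediction fit: %d lncRNAs x %d diseases\n",
              nrow(x$F), ncol(x$F)))
  cat(sprintf("  score range [%.3g, %.3g]\n", min(x$F), max(x$F)))
  invisible(x)
}

#' Degenerate baseline: restart walk on raw GIP networks
#'
#' Reference predictor that skips every enrichment stage of the
#' pipeline: no logistic rescaling, no similarity fusion, no WKNKN, no
#' LNS. The bi-random walk runs directly on the column-normalized GIP
#' kernels of the raw binary matrix. Useful as a floor when assessing
#' what the full pipeline adds.
#'
#' @inheritParams predict_associations
#' @return object of class `ubrw_fit` with the score matrix `F`.
#' @export
predict_baseline <- function(Y, Sdis = NULL, cfg = ubrw_config()) {
  Y <- association_matrix(Y)
  params <- gip_bandwidths(Y, cfg$bandwidth_convention)
  MD <- column_normalize(gip_disease(Y, params))
  ML <- column_normalize(gip_lnc(Y, params))
  F_ <- unbalanced_birandom_walk(Y, MD, ML, alpha = cfg$alpha,
                                 s1 = cfg$s1, s2 = cfg$s2,
                                 restart_unnormalized = cfg$restart_unnormalized)
  structure(list(F = F_, config = cfg), class = "ubrw_fit")
}
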