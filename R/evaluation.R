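#' Mann-Whitney AUC from score lists
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted half:
#' `(#\{pos > neg\} + 0.5 * #\{pos == neg\}) / (|pos| * |neg|)`.
#' Computed via midranks, so it is exact and O((m + n) log(m + n)).
#'
#' @param pos_scores,neg_scores nonempty numeric vectors.
#' @return a single number in \[0, 1\].
#' @export
auc_score <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  if (anyNA(pos_scores) || anyNA(neg_scores)) {
    stop("scores must not contain NA", call. = FALSE)
  }
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validation scheme
#'
#' @param mode `"loocv"` (every known association held out in turn) or
#'   `"kfold"`.
#' @param folds number of folds (>= 2, `"kfold"` only).
#' @param repeats number of repetitions of the k-fold split (>= 1).
#' @param seed integer seed for the fold shuffle.
#' @return object of class `cv_scheme`.
#' @export
cv_scheme <- function(mode = c("loocv", "kfold"), folds = 5, repeats = 1,
                      seed = 1L) {
  mode <- match.arg(mode)
  stop_unless(is.numeric(folds), folds >= 2, folds == round(folds),
              msg = "`folds` must be an integer >= 2")
  stop_unless(is.numeric(repeats), repeats >= 1, repeats == round(repeats),
              msg = "`repeats` must be an integer >= 1")
  structure(list(mode = mode, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Cross-validated AUC of a link predictor
#'
#' Known associations (1-cells of `Y`) are split into folds; each fold
#' is masked to 0 in the training matrix and the entire pipeline is
#' re-fit from the masked matrix (the disease semantic similarity
#' depends only on the term DAGs and is passed in precomputed). The
#' held-out cells' scores are the positives; the negatives are all
#' cells that are 0 in the full `Y`, scored by the same fold's fit.
#' Per repeat, pair comparisons are pooled across folds into one AUC;
#' the mean and sd over repeats are reported. A fold may leave an
#' entity with no remaining association — the isolated-node conventions
#' of the pipeline apply.
#'
#' @param Y binary association matrix.
#' @param Sdis disease semantic similarity over `colnames(Y)`.
#' @param cfg a [ubrw_config()].
#' @param scheme a [cv_scheme()]; LOOCV by default.
#' @param predictor function `(Y_train, Sdis, cfg) -> list(F = matrix)`
#'   scoring all cells; defaults to [predict_associations()]. Pass
#'   [predict_baseline()] for the degenerate reference.
#' @return object of class `ubrw_cv`: list with `auc_mean`, `auc_sd`
#'   (`NA` for a single repeat) and `per_repeat`.
#' @export
run_cv <- function(Y, Sdis, cfg = ubrw_config(),
                   scheme = cv_scheme("loocv"),
                   predictor = predict_associations) {
  stopifnot(inherits(scheme, "cv_scheme"))
  Y <- association_matrix(Y)
  if (!all(Y %in% c(0, 1))) {
    stop("cross-validation requires a binary association matrix", call. = FALSE)
  }
  ones <- which(Y == 1)
  zeros <- which(Y == 0)
  if (length(ones) < 1 || length(zeros) < 1) {
    stop("need at least one known and one unknown association", call. = FALSE)
  }

  if (scheme$mode == "loocv") {
    n_folds <- length(ones)
  } else {
    if (scheme$folds > length(ones)) {
      stop("more folds than known associations", call. = FALSE)
    }
    n_folds <- scheme$folds
  }
  repeats <- if (scheme$mode == "loocv") 1L else scheme$repeats

  per_repeat <- numeric(repeats)
  for (rep_i in seq_len(repeats)) {
    set.seed(scheme$seed + rep_i - 1L)
    if (scheme$mode == "loocv") {
      assignment <- seq_along(ones)           # one association per fold
    } else {
      assignment <- sample(rep_len(seq_len(n_folds), length(ones)))
    }
    wins <- 0; pairs <- 0
    for (f in seq_len(max(assignment))) {
      test_cells <- ones[assignment == f]
      Y_train <- Y
      Y_train[test_cells] <- 0
      fit <- predictor(Y_train, Sdis, cfg)
      pos <- fit$F[test_cells]
      neg <- fit$F[zeros]
      # pooled pair counting: each positive vs this fold's negatives
      for (s in pos) {
        wins <- wins + sum(s > neg) + 0.5 * sum(s == neg)
      }
      pairs <- pairs + length(pos) * length(neg)
    }
    per_repeat[rep_i] <- wins / pairs
  }

  structure(list(auc_mean = mean(per_repeat),
                 auc_sd = if (repeats > 1) stats::sd(per_repeat) else NA_real_,
                 per_repeat = per_repeat,
                 scheme = scheme),
            class = "ubrw_cv")
}

#' @export
print.ubrw_cv <- function(x, ...) {
  if (is.na(x$auc_sd)) {
    cat(sprintf("%s AUC: %.4f\n", toupper(x$scheme$mode), x$auc_mean))
  } else {
    cat(sprintf("%s AUC: %.4f(±%.4f) over %d repeats\n",
                toupper(x$scheme$mode), x$auc_mean, x$auc_sd,
                length(x$per_repeat)))
  }
  invisible(x)
}

#' Top-k candidate lncRNAs for one disease
#'
#' Ranks lncRNAs by descending predicted score for the given disease
#' (ties broken by ascending row index) and flags each as a known
#' association or a novel candidate.
#'
#' @param F score matrix (lncRNAs x diseases).
#' @param Y_known binary association matrix with the same labels.
#' @param disease disease label (column of `F`).
#' @param k number of top candidates, `k <= nrow(F)`.
#' @return data frame with columns `rank`, `lncRNA`, `score`, `known`.
#' @export
top_k_report <- function(F, Y_known, disease, k = 20) {
  check_labels_agree(dimnames(as.matrix(unclass_sim(F))),
                     dimnames(as.matrix(unclass_sim(Y_known))), "matrix")
  if (!disease %in% colnames(F)) {
    stop(sprintf("unknown disease label '%s'", disease), call. = FALSE)
  }
  if (k < 1 || k > nrow(F)) {
    stop(sprintf("`k` must lie in [1, %d]", nrow(F)), call. = FALSE)
  }
  scores <- F[, disease]
  ord <- order(-scores, seq_along(scores))[seq_len(k)]
  data.frame(rank = seq_len(k),
             lncRNA = rownames(F)[ord],
             score = unname(scores[ord]),
             known = unname(Y_known[ord, disease] == 1),
             stringsAsFactors = FALSE)
}

#' Serialize a cross-validation result as JSON
#'
#' @param cv a [run_cv()] result.
#' @param path optional output path; when `NULL`, the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
cv_to_json <- function(cv, path = NULL) {
  stopifnot(inherits(cv, "ubrw_cv"))
  obj <- list(auc_mean = cv$auc_mean, auc_sd = cv$auc_sd,
              per_repeat = cv$per_repeat)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(js)
}
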