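#' Subject-wise k-fold split
#'
#' Assigns each subject to exactly one of `k` folds: seeded shuffle, then
#' round-robin dealing, so fold sizes differ by at most one (38 subjects give
#' sizes 13/13/12).
#'
#' @param subject_ids character vector of unique subject ids (>= k).
#' @param k number of folds (default 3).
#' @param seed RNG seed for the shuffle.
#' @return A `bp_fold_split`: data.frame (`subject`, `fold`) with attributes
#'   `k` and `seed`.
#' @export
subject_kfold_split <- function(subject_ids, k = 3L, seed = 1L) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop_cf("subject ids must be unique")
  if (length(subject_ids) < k)
    stop_cf("need at least k = %d subjects, got %d", k, length(subject_ids))
  shuffled <- with_seed(seed, sample(subject_ids))
  out <- data.frame(subject = shuffled,
                    fold = rep_len(seq_len(k), length(shuffled)))
  out <- out[order(out$subject), ]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- seed
  class(out) <- c("bp_fold_split", "data.frame")
  out
}

# Closed-form ridge regression on a standardized design; the intercept is
# unpenalized. `lambda` is the per-observation penalty, so the fit is
# invariant to the number of training rows.
ridge_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdev, `/`)
  ybar <- mean(y)
  n <- nrow(Z)
  A <- crossprod(Z) / n + diag(lambda, ncol(Z))
  b <- crossprod(Z, y - ybar) / n
  gamma <- solve(A, b)
  beta <- as.numeric(gamma) / sdev
  list(beta = setNames(beta, colnames(X)),
       intercept = ybar - sum(beta * mu))
}

ridge_predict <- function(fit, X) {
  as.numeric(as.matrix(X) %*% fit$beta + fit$intercept)
}

#' Train the 3-fold regression ensemble
#'
#' For each BP parameter, member `m` is a ridge-regularized linear regression
#' trained on the segments of the two folds *excluding* fold `m`, with the
#' calibrated reference segment values as targets. The three members form the
#' parameter's ensemble.
#'
#' @param features matrix or data.frame of per-segment features (rows =
#'   segments).
#' @param targets data.frame/matrix with columns `sbp`, `dbp`, `map`:
#'   calibrated reference segment values aligned with `features` rows.
#' @param subjects character vector: subject id of each row.
#' @param split a [subject_kfold_split()] over (at least) these subjects.
#' @param lambda ridge penalty (per observation; default `1e-3`, small).
#' @return A `bp_ensemble`: per-parameter list of fitted members, plus the
#'   split and feature names.
#' @export
train_ensemble <- function(features, targets, subjects, split,
                           lambda = 1e-3) {
  stopifnot(inherits(split, "bp_fold_split"))
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  targets <- as.data.frame(targets)
  params <- intersect(c("sbp", "dbp", "map"), names(targets))
  if (!length(params)) stop_cf("targets must contain sbp, dbp and/or map")
  subjects <- as.character(subjects)
  stopifnot(nrow(X) == nrow(targets), length(subjects) == nrow(X))
  fold_of <- setNames(split$fold, split$subject)
  if (any(!subjects %in% split$subject))
    stop_cf("subjects absent from the fold split: %s",
            paste(unique(subjects[!subjects %in% split$subject]), collapse = ", "))
  row_fold <- fold_of[subjects]
  k <- attr(split, "k")
  finite_X <- apply(is.finite(X), 1L, all)
  models <- list()
  for (p in params) {
    y <- targets[[p]]
    usable <- finite_X & is.finite(y)
    if (!any(usable)) stop_cf("all targets missing for %s", p)
    members <- vector("list", k)
    for (m in seq_len(k)) {
      tr <- usable & row_fold != m
      if (!any(tr))
        stop_cf("fold %d has no training segments for %s", m, p)
      members[[m]] <- ridge_fit(X[tr, , drop = FALSE], y[tr], lambda)
    }
    models[[p]] <- members
  }
  structure(list(models = models, split = split, lambda = lambda,
                 feature_names = colnames(X), k = k),
            class = "bp_ensemble")
}

#' Predict segment blood pressure from an ensemble
#'
#' Two evaluation modes:
#' * `"strict"` (default): a subject's predictions come from the single
#'   member whose training folds exclude that subject — genuinely held-out,
#'   no test-time leakage. Subjects outside the split fall back to the
#'   ensemble average.
#' * `"paper"`: the final averaged ensemble — the arithmetic mean of all
#'   members' outputs — predicts for everyone.
#'
#' Rows with non-finite features yield `NA` predictions.
#'
#' @param object a `bp_ensemble`.
#' @param features per-segment feature matrix/data.frame (same columns as
#'   in training).
#' @param subjects subject id per row (required for `"strict"`).
#' @param mode `"strict"` or `"paper"`.
#' @param ... unused.
#' @return data.frame with one column per fitted parameter.
#' @export
predict.bp_ensemble <- function(object, features, subjects = NULL,
                                mode = c("strict", "paper"), ...) {
  mode <- match.arg(mode)
  X <- as.matrix(features)
  if (!is.null(colnames(X)) && !identical(colnames(X), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X)))
      stop_cf("features lack columns: %s",
              paste(setdiff(object$feature_names, colnames(X)), collapse = ", "))
    X <- X[, object$feature_names, drop = FALSE]
  }
  finite <- apply(is.finite(X), 1L, all)
  Xs <- X[finite, , drop = FALSE]
  fold_of <- setNames(object$split$fold, object$split$subject)
  out <- as.data.frame(
    setNames(rep(list(rep(NA_real_, nrow(X))), length(object$models)),
             names(object$models)))
  if (mode == "strict" && is.null(subjects))
    stop_cf("strict mode needs the subject id of every row")
  for (p in names(object$models)) {
    members <- object$models[[p]]
    preds <- vapply(members, function(m) ridge_predict(m, Xs),
                    numeric(nrow(Xs)))
    if (nrow(Xs) == 1L) preds <- matrix(preds, nrow = 1L)
    if (mode == "paper") {
      out[[p]][finite] <- rowMeans(preds)
    } else {
      rf <- fold_of[as.character(subjects)[finite]]
      val <- rowMeans(preds)                      # fallback: unseen subject
      known <- !is.na(rf)
      val[known] <- preds[cbind(which(known), rf[known])]
      out[[p]][finite] <- val
    }
  }
  out
}

#' @export
print.bp_ensemble <- function(x, ...) {
  cat(sprintf("<bp_ensemble> %d-member ridge ensembles for %s (lambda = %g)\n",
              x$k, paste(names(x$models), collapse = ", "), x$lambda))
  invisible(x)
}
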