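# Two-fold SVM anomaly classifier: a one-class SVM bootstrapped from
# healthy-only training data, whose detected negatives seed an iterated
# two-class SVM self-training loop that runs until no new negatives appear.

feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  nm <- intersect(feature_names(), colnames(x))
  if (!length(nm)) abort("no cc_* feature columns found")
  as.matrix(x[, nm])
}

subject_ids_of <- function(x, n) {
  if (!is.matrix(x) && "subject_id" %in% colnames(x)) x$subject_id
  else sprintf("P%03d", seq_len(n))
}

#' Split healthy controls into training and test sets
#'
#' Random disjoint partition of the healthy-control feature rows into
#' `n_train` positive-class training samples and the remaining test
#' samples; deterministic given `seed`.
#'
#' @param hc_features Feature tibble (or matrix) of healthy controls.
#' @param n_train Training-set size (default 50); must leave a non-empty
#'   test set.
#' @param seed Integer seed.
#' @return List with `train` and `test` subsets.
#' @export
split_training <- function(hc_features, n_train = 50, seed = 1) {
  n <- nrow(hc_features)
  if (n_train >= n) {
    abort(sprintf("`n_train` (%d) must leave a non-empty test set (n = %d)",
                  n_train, n))
  }
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = hc_features[idx, , drop = FALSE],
       test = hc_features[-idx, , drop = FALSE])
}

ocsvm_predict_labels <- function(model, x) {
  if (nrow(x) == 0L) return(integer(0))
  dv <- attr(predict(model, x, decision.values = TRUE), "decision.values")
  ifelse(as.vector(dv) >= 0, 1L, -1L)
}

#' One-class SVM stage with grid-searched hyperparameters
#'
#' RBF one-class SVM trained on positive-class features only. For each
#' (nu, gamma) grid point, `folds`-fold cross-validation on the positives
#' measures the mean held-out acceptance rate (fraction predicted +1); the
#' pair maximizing it is selected, with ties broken towards the smallest nu
#' and then the smallest gamma (the least-rejecting, smoothest boundary).
#' The model is refit on all training data with the selected pair.
#' Features are used unscaled. Decision convention: a non-negative decision
#' value maps to +1.
#'
#' @param train Positive-class feature tibble or matrix.
#' @param nu_grid,gamma_grid Candidate values (defaults: nu in
#'   \{0.01, 0.05, 0.1, 0.2\}, gamma in `2^seq(-15, 3, 2)`).
#' @param folds Cross-validation folds (default 7); must not exceed the
#'   number of training samples.
#' @param seed Integer seed (fold assignment).
#' @return An `ocsvm_stage`: fitted e1071 model, selected `nu`/`gamma`, and
#'   the CV table.
#' @export
ocsvm_fit <- function(train, nu_grid = c(0.01, 0.05, 0.1, 0.2),
                      gamma_grid = 2^seq(-15, 3, 2), folds = 7, seed = 1) {
  x <- feature_matrix(train)
  if (!length(nu_grid) || !length(gamma_grid)) {
    abort("hyperparameter grids must be non-empty")
  }
  if (folds > nrow(x)) {
    abort(sprintf("folds (%d) exceed the training-set size (%d)",
                  folds, nrow(x)))
  }
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(x))))
  grid <- expand.grid(nu = nu_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(folds), function(k) {
      m <- e1071::svm(x[fold_id != k, , drop = FALSE],
                      type = "one-classification", kernel = "radial",
                      nu = grid$nu[g], gamma = grid$gamma[g], scale = FALSE)
      mean(ocsvm_predict_labels(m, x[fold_id == k, , drop = FALSE]) == 1L)
    }, numeric(1)))
  }, numeric(1))
  # CV acceptance has granularity ~ 1/n; near-ties within one sample of the
  # maximum count as ties so the smallest-nu / smallest-gamma preference is
  # not overridden by fold noise
  tied <- acc >= max(acc) - 1 / nrow(x)
  best <- which(tied)[order(grid$nu[tied], grid$gamma[tied])[1]]
  model <- e1071::svm(x, type = "one-classification", kernel = "radial",
                      nu = grid$nu[best], gamma = grid$gamma[best],
                      scale = FALSE)
  structure(list(model = model, nu = grid$nu[best], gamma = grid$gamma[best],
                 cv = as_tibble(cbind(grid, acceptance = acc)),
                 folds = folds, seed = seed),
            class = "ocsvm_stage")
}

#' @export
predict.ocsvm_stage <- function(object, newdata, ...) {
  ocsvm_predict_labels(object$model, feature_matrix(newdata))
}

tcsvm_fit <- function(x, y, c_grid = 2^seq(-5, 15, 2),
                      gamma_grid = 2^seq(-15, 3, 2), folds = 5, seed = 1) {
  y <- factor(y, levels = c(-1, 1))
  if (any(table(y) < 1L)) abort("both classes must be present")
  # stratified folds so every training split sees both classes
  fold_id <- integer(length(y))
  fold_id[y == -1] <- with_seed(derive_seed(seed, 1),
                                sample(rep_len(seq_len(folds), sum(y == -1))))
  fold_id[y == 1] <- with_seed(derive_seed(seed, 2),
                               sample(rep_len(seq_len(folds), sum(y == 1))))
  grid <- expand.grid(cost = c_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                      kernel = "radial", cost = grid$cost[g],
                      gamma = grid$gamma[g], scale = FALSE)
      mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- order(-acc, grid$cost, grid$gamma)[1]
  model <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE)
  structure(list(model = model, cost = grid$cost[best],
                 gamma = grid$gamma[best], cv_accuracy = acc[best]),
            class = "tcsvm_stage")
}

#' @export
predict.tcsvm_stage <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (nrow(x) == 0L) return(integer(0))
  as.integer(as.character(predict(object$model, x)))
}

#' Fit the two-fold SVM classifier
#'
#' Stage one fits a one-class SVM on the positive-class training features;
#' pool members it predicts as -1 form the initial negative set. Stage two
#' then iterates: a two-class SVM is grid-search cross-validated on
#' positives (+1) plus all accumulated negatives (-1), the remaining pool
#' members are predicted, and newly negative ones join the set. Negatives
#' never revert to +1 (unless `allow_relabel = TRUE`), so the loop
#' terminates after at most `nrow(pool)` rounds, when a round adds no new
#' negative. A pool with zero initial negatives yields a valid model with
#' no two-class stage.
#'
#' @param train_pos Positive-class (healthy training) feature tibble/matrix.
#' @param pool Unlabeled feature tibble/matrix to screen.
#' @param nu_grid,ocsvm_gamma_grid,ocsvm_folds One-class grid-search
#'   controls (see [ocsvm_fit()]).
#' @param c_grid,tcsvm_gamma_grid,tcsvm_folds Two-class grid-search
#'   controls: soft-margin cost and RBF width candidates with
#'   `tcsvm_folds`-fold CV maximizing accuracy.
#' @param seed Integer seed; all fold assignments derive from it.
#' @param allow_relabel If `TRUE`, accumulated negatives are re-predicted
#'   each round and may revert (sensitivity analysis only; default `FALSE`).
#' @return A `tfsvm` model: `ocsvm` stage, final `tcsvm` stage (or `NULL`),
#'   `negative_ids`, and `iteration_log` (tibble with one row per round).
#' @export
tfsvm_fit <- function(train_pos, pool,
                      nu_grid = c(0.01, 0.05, 0.1, 0.2),
                      ocsvm_gamma_grid = 2^seq(-15, 3, 2), ocsvm_folds = 7,
                      c_grid = 2^seq(-5, 15, 2),
                      tcsvm_gamma_grid = 2^seq(-15, 3, 2), tcsvm_folds = 5,
                      seed = 1, allow_relabel = FALSE) {
  if (nrow(pool) == 0L) abort("`pool` must be non-empty.")
  x_pos <- feature_matrix(train_pos)
  x_pool <- feature_matrix(pool)
  pool_ids <- subject_ids_of(pool, nrow(x_pool))

  oc <- ocsvm_fit(train_pos, nu_grid, ocsvm_gamma_grid,
                  folds = ocsvm_folds, seed = derive_seed(seed, 101))
  neg <- pool_ids[ocsvm_predict_labels(oc$model, x_pool) == -1L]
  log <- tibble(round = 0L, stage = "ocsvm",
                n_new_negative = length(neg), n_negative_total = length(neg),
                par1 = oc$nu, par2 = oc$gamma, cv_score = NA_real_)

  tc <- NULL
  if (length(neg)) {
    for (r in seq_len(nrow(x_pool))) {
      x_tr <- rbind(x_pos, x_pool[match(neg, pool_ids), , drop = FALSE])
      y_tr <- c(rep(1L, nrow(x_pos)), rep(-1L, length(neg)))
      tc <- tcsvm_fit(x_tr, y_tr, c_grid, tcsvm_gamma_grid,
                      folds = tcsvm_folds, seed = derive_seed(seed, 200 + r))
      if (allow_relabel) {
        lab <- predict(tc, x_pool)
        new_neg <- pool_ids[lab == -1L]
        n_new <- length(setdiff(new_neg, neg))
        neg <- new_neg
      } else {
        rest <- setdiff(pool_ids, neg)
        lab <- predict(tc, x_pool[match(rest, pool_ids), , drop = FALSE])
        found <- rest[lab == -1L]
        n_new <- length(found)
        neg <- c(neg, found)
      }
      log <- bind_rows(log, tibble(round = r, stage = "tcsvm",
                                   n_new_negative = n_new,
                                   n_negative_total = length(neg),
                                   par1 = tc$cost, par2 = tc$gamma,
                                   cv_score = tc$cv_accuracy))
      if (n_new == 0L) break
    }
  } else {
    inform("one-class stage found no negatives; returning the model without a two-class stage")
  }
  structure(list(ocsvm = oc, tcsvm = tc, negative_ids = neg,
                 iteration_log = log, seed = seed),
            class = "tfsvm")
}

#' @export
predict.tfsvm <- function(object, newdata, ...) {
  if (!is.null(object$tcsvm)) predict(object$tcsvm, newdata)
  else predict(object$ocsvm, newdata)
}

#' @export
print.tfsvm <- function(x, ...) {
  cat(sprintf("<tfsvm> ocsvm(nu=%g, gamma=%g)", x$ocsvm$nu, x$ocsvm$gamma))
  if (!is.null(x$tcsvm)) {
    cat(sprintf(" + tcsvm(cost=%g, gamma=%g), %d round(s)",
                x$tcsvm$cost, x$tcsvm$gamma, max(x$iteration_log$round)))
  }
  cat(sprintf(", %d negative(s)\n", length(x$negative_ids)))
  invisible(x)
}

#' Screening metrics on an all-positive test set
#'
#' The held-out test set contains healthy controls only, so the metrics
#' collapse to: accuracy = percentage labeled +1, false-positive rate =
#' percentage labeled -1 (a healthy subject flagged as abnormal), and
#' true-positive rate = percentage labeled +1. By construction
#' `accuracy + fpr = 100` and `tpr = accuracy`.
#'
#' @param labels Predicted class labels (+1 / -1).
#' @param truth True labels; must all be +1.
#' @return One-row tibble: `n`, `accuracy`, `fpr`, `tpr` (percentages).
#' @examples
#' evaluate_screening(c(rep(1, 22), -1, -1), rep(1, 24))  # 91.67% accuracy
#' @export
evaluate_screening <- function(labels, truth) {
  if (length(labels) == 0L) abort("empty prediction set")
  if (length(labels) != length(truth)) abort("length mismatch")
  if (!all(truth == 1)) abort("`truth` must be all-positive (+1)")
  if (!all(labels %in% c(-1, 1))) abort("labels must be +1 or -1")
  acc <- 100 * mean(labels == 1)
  tibble(n = length(labels), accuracy = acc, fpr = 100 - acc, tpr = acc)
}
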