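#' Recursive feature elimination with cross-validated AUC trace
#'
#' Starting from the full covariate set, repeatedly drops the least
#' important feature — smallest absolute Wald z statistic for the logistic
#' base learner, smallest mean impurity (Gini) decrease for the random
#' forest — recording the stratified cross-validated AUC of the model at
#' each set size. The elimination order ranks features (last eliminated =
#' most informative) and the AUC trace shows where performance plateaus.
#'
#' @param data data frame of records (complete cases over outcome +
#'   covariates are used).
#' @param outcome binary outcome column name.
#' @param covariates character vector of candidate feature names (>= 2).
#' @param base \code{"logistic"} or \code{"forest"}.
#' @param folds number of stratified CV folds (default 5; folds are reduced
#'   with a warning if a class is too small).
#' @param seed integer seed governing fold assignment (and forest fits).
#' @param ntree trees for the forest base learner.
#' @param importance for the forest: \code{"impurity"} (mean Gini decrease,
#'   default) or \code{"permutation"}.
#' @return tibble with one row per model size: \code{n_features},
#'   \code{features} (list column), \code{cv_auc}, \code{eliminated} (the
#'   feature dropped after this step, \code{NA} for the final single
#'   feature).
#' @export
recursive_feature_elimination <- function(data, outcome, covariates,
                                          base = c("logistic", "forest"),
                                          folds = 5, seed = NULL, ntree = 200,
                                          importance = c("impurity", "permutation")) {
  base <- match.arg(base)
  importance <- match.arg(importance)
  if (length(covariates) < 2) stop("at least two covariates required", call. = FALSE)
  data <- as.data.frame(data)
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y)) {
    lv <- sort(unique(as.character(y[!is.na(y)])))
    if (length(lv) != 2) stop("outcome must be binary", call. = FALSE)
    y <- as.character(y) == lv[2]
  }
  y <- as.logical(y)
  X <- as.data.frame(lapply(data[, covariates, drop = FALSE], as.numeric))
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]

  n_min <- min(sum(y), sum(!y))
  if (n_min < folds) {
    folds <- max(2, n_min)
    warning("degenerate folds; reduced to ", folds, call. = FALSE)
  }

  with_seed(seed, {
    # stratified fold assignment, fixed across all set sizes
    fold <- integer(length(y))
    fold[y] <- sample(rep_len(seq_len(folds), sum(y)))
    fold[!y] <- sample(rep_len(seq_len(folds), sum(!y)))

    cv_auc <- function(feats) {
      oof <- rep(NA_real_, length(y))
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (base == "logistic") {
          df <- cbind(.y = as.numeric(y[tr]), X[tr, feats, drop = FALSE])
          fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
          oof[!tr] <- predict(fit, newdata = X[!tr, feats, drop = FALSE])
        } else {
          fit <- randomForest::randomForest(
            x = X[tr, feats, drop = FALSE], y = factor(y[tr]), ntree = ntree)
          oof[!tr] <- predict(fit, X[!tr, feats, drop = FALSE],
                              type = "prob")[, "TRUE"]
        }
      }
      roc_auc(oof, y, ci = FALSE)$auc
    }

    rank_least <- function(feats) {
      if (base == "logistic") {
        if (length(feats) == 1) return(feats)
        df <- cbind(.y = as.numeric(y), X[, feats, drop = FALSE])
        fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
        z <- abs(coef(summary(fit))[-1, "z value"])
        feats[which.min(z[feats])]
      } else {
        fit <- randomForest::randomForest(
          x = X[, feats, drop = FALSE], y = factor(y), ntree = ntree,
          importance = (importance == "permutation"))
        imp <- if (importance == "permutation") {
          randomForest::importance(fit, type = 1)[, 1]
        } else {
          randomForest::importance(fit, type = 2)[, 1]
        }
        feats[which.min(imp[feats])]
      }
    }

    feats <- covariates
    rows <- list()
    step <- 0L
    while (length(feats) >= 1) {
      step <- step + 1L
      auc <- cv_auc(feats)
      drop <- if (length(feats) > 1) rank_least(feats) else NA_character_
      rows[[step]] <- tibble::tibble(
        n_features = length(feats), features = list(feats),
        cv_auc = auc, eliminated = drop)
      if (is.na(drop)) break
      feats <- setdiff(feats, drop)
    }
    dplyr::bind_rows(rows)
  })
}
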