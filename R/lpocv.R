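#' Cross-validation configuration for the LPOCV classifier
#'
#' @param penalty `"l1"` or `"l2"` regularized logistic regression.
#' @param grid Hyperparameter grid; values are interpreted as inverse
#'   regularization strengths (larger = weaker penalty, the convention of
#'   the usual machine-learning implementation of regularized logistic
#'   regression). Internally mapped to a coordinate-descent penalty
#'   `lambda = 1 / (n * omega)`. A length-1 grid skips the inner CV.
#' @param fraction Fraction of features kept by the AUC filter
#'   (`floor(fraction * F)` features), or `"all"` to skip filtering.
#' @param inner_folds Number of stratified inner CV folds (reduced
#'   automatically when a class has fewer members than folds).
#' @param seed Integer seed for fold assignment; each LPOCV round draws its
#'   folds from a round-indexed sub-seed.
#' @param normalization `"training"` (z-score by each round's training rows
#'   only; leak-free, default), `"global"` (z-score the full table once,
#'   matching the common pre-CV practice), or `"none"`.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(penalty = c("l1", "l2"),
                      grid = c(0.001, 0.01, 0.1, 1, 10),
                      fraction = 0.01, inner_folds = 10L, seed = 1L,
                      normalization = c("training", "global", "none")) {
  penalty <- match.arg(penalty)
  normalization <- match.arg(normalization)
  if (length(grid) == 0L) stop("hyperparameter grid must be non-empty")
  if (!identical(fraction, "all") && (fraction <= 0 || fraction > 1))
    stop("fraction must be in (0, 1] or 'all'")
  structure(list(penalty = penalty, grid = grid, fraction = fraction,
                 inner_folds = as.integer(inner_folds), seed = as.integer(seed),
                 normalization = normalization),
            class = "cv_config")
}

#' Flipped Mann-Whitney AUC of a single feature
#'
#' AUC of `values` against `labels` with ties counted 0.5 per tied pair,
#' returned as `max(auc, 1 - auc)` so inversely correlated features rank as
#' high as positively correlated ones.
#'
#' @param values Numeric vector.
#' @param labels Vector with both -1 and +1 present.
#' @return AUC in [0.5, 1].
#' @export
feature_auc <- function(values, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(values) # midranks give the 0.5-per-tie convention
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

# column-wise flipped AUCs of a matrix (midrank formulation)
.col_aucs <- function(x, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  a <- apply(x, 2, function(v)
    (sum(rank(v)[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  pmax(a, 1 - a)
}

#' Indices of the top AUC-ranked fraction of features
#'
#' Ranks features by flipped AUC on the given rows and returns the indices
#' of the best `floor(fraction * F)`; ties at the cutoff are broken by
#' ascending column index, which makes the selection deterministic.
#'
#' @param x Feature matrix (training rows only).
#' @param labels Labels for those rows.
#' @param fraction Fraction in (0, 1], or `"all"` for every feature.
#' @return Integer vector of column indices (ascending AUC rank).
#' @export
select_top_fraction <- function(x, labels, fraction = 0.01) {
  if (identical(fraction, "all")) return(seq_len(ncol(x)))
  m <- floor(fraction * ncol(x))
  if (m < 1L) stop("fraction too small: floor(fraction * F) = 0")
  a <- .col_aucs(x, labels)
  order(-a, seq_along(a))[seq_len(m)]
}

# stratified fold ids; folds reduced so each fold holds >= 1 of each class
.stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  k <- max(2L, min(k, min(sum(labels > 0), sum(labels < 0))))
  fold <- integer(length(labels))
  for (cls in c(-1, 1)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.glmnet_fit <- function(x, y, penalty, omega) {
  lam <- 1 / (nrow(x) * omega)
  # glmnet warns on small class counts ("dangerous ground"); LPOCV training
  # sets are deliberately small, so muffle that specific warning
  withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(-1, 1)), family = "binomial",
                   alpha = if (penalty == "l1") 1 else 0,
                   lambda = lam, standardize = FALSE, thresh = 1e-10,
                   maxit = 1e6),
    warning = function(w) {
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# linear predictor without the S4 predict() dispatch (hot path in LPOCV)
.glmnet_link <- function(fit, x) {
  as.numeric(x %*% as.numeric(fit$beta)) + fit$a0[[1]]
}

#' Inner cross-validated hyperparameter selection
#'
#' Stratified k-fold CV over the hyperparameter grid; each candidate is
#' scored by the mean AUC of its held-out-fold predictions, and the argmax
#' is returned. Ties are broken in favor of the largest grid value (the
#' weakest penalty, since grid values are inverse strengths). Folds whose
#' hold-out lacks a class, or whose training part has fewer than 2 members
#' of a class (the coordinate-descent fitter's minimum), are dropped from
#' the mean; the fold count is automatically reduced toward the minority
#' class size. If no usable fold remains (minority class of 2 in the
#' training set), the weakest penalty is returned as the documented
#' fallback rather than failing the LPOCV round.
#'
#' @param x Numeric matrix (training rows x selected features).
#' @param y Labels in {-1, +1}.
#' @param config A [cv_config()].
#' @param seed Fold-assignment seed (default `config$seed`).
#' @return The selected hyperparameter (element of `config$grid`).
#' @export
inner_select_hyperparam <- function(x, y, config, seed = config$seed) {
  if (length(config$grid) == 1L) return(config$grid)
  fold <- .stratified_folds(y, config$inner_folds, seed)
  scores <- vapply(config$grid, function(om) {
    aucs <- c()
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2L) next
      if (min(sum(y[tr] > 0), sum(y[tr] < 0)) < 2L) next
      fit <- .glmnet_fit(x[tr, , drop = FALSE], y[tr], config$penalty, om)
      p <- .glmnet_link(fit, x[!tr, , drop = FALSE])
      aucs <- c(aucs, feature_auc_raw(p, y[!tr]))
    }
    if (length(aucs) == 0L) return(NA_real_)
    mean(aucs)
  }, numeric(1))
  if (all(is.na(scores))) return(max(config$grid)) # documented fallback
  best <- which(scores == max(scores, na.rm = TRUE))
  config$grid[max(best)] # ties go to the largest omega (weakest penalty)
}

#' Unflipped Mann-Whitney AUC
#'
#' Plain AUC of scores against labels (ties 0.5), without the
#' inverse-correlation flip; used for scoring model predictions.
#'
#' @param scores Numeric vector.
#' @param labels Vector with both classes present.
#' @return AUC in [0, 1].
#' @export
feature_auc_raw <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  (sum(rank(scores)[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-pair-out cross-validation of the regularized logistic model
#'
#' For every unordered pair of lesions: all other lesions form the training
#' set; features are (optionally) z-scored by training statistics, the
#' AUC filter keeps the top fraction, the hyperparameter is chosen by inner
#' stratified CV, a regularized logistic model is fitted, and the held-out
#' pair's predictions are compared. The win matrix entry is the Heaviside
#' of the prediction difference with H(0) = 0.5, each lesion's score is its
#' number of wins (in [0, n-1]), and the score-vs-label ROC gives the
#' cross-validated AUC with a DeLong-type 95% CI.
#'
#' @param table A [feature_table()] (labels are taken from it).
#' @param config A [cv_config()].
#' @return Object of class `lpocv_result`: `scores`, `auc`, `ci`
#'   (length 2), `selected` (list of per-round feature-index vectors),
#'   `alphas` (per-round chosen hyperparameter), `config`.
#' @export
run_lpocv <- function(table, config = cv_config()) {
  y <- table$label
  n <- length(y)
  if (n < 4L) stop("need at least 4 lesions")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(sum(y > 0), sum(y < 0)) < 4L)
    stop("each class needs >= 4 lesions so every training set keeps >= 2")
  x_all <- table$features
  if (config$normalization == "global")
    x_all <- normalize_features(table)$features
  wins <- numeric(n)
  pairs <- utils::combn(n, 2)
  selected <- vector("list", ncol(pairs))
  alphas <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    C <- setdiff(seq_len(n), c(i, j))
    if (length(unique(y[C])) < 2L) stop("degenerate training set: single class")
    xtr <- x_all[C, , drop = FALSE]
    xte <- x_all[c(i, j), , drop = FALSE]
    if (config$normalization == "training") {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu, `-`), 2, sdv, `/`)
      xte <- sweep(sweep(xte, 2, mu, `-`), 2, sdv, `/`)
    }
    B <- select_top_fraction(xtr, y[C], config$fraction)
    selected[[p]] <- B
    round_seed <- (config$seed + 7919L * p) %% .Machine$integer.max
    al <- inner_select_hyperparam(xtr[, B, drop = FALSE], y[C], config,
                                  seed = round_seed)
    alphas[p] <- al
    fit <- .glmnet_fit(xtr[, B, drop = FALSE], y[C], config$penalty, al)
    pred <- .glmnet_link(fit, xte[, B, drop = FALSE])
    h <- if (pred[1] > pred[2]) 1 else if (pred[1] < pred[2]) 0 else 0.5
    wins[i] <- wins[i] + h
    wins[j] <- wins[j] + (1 - h)
  }
  ci <- unname(auc_with_ci(wins, y))
  structure(list(scores = wins, auc = ci[1], ci = ci[2:3],
                 selected = selected, alphas = alphas, config = config),
            class = "lpocv_result")
}

#' @export
print.lpocv_result <- function(x, ...) {
  cat(sprintf("LPOCV AUC = %.3f (95%% CI %.3f-%.3f), %d rounds\n",
              x$auc, x$ci[1], x$ci[2], length(x$alphas)))
  invisible(x)
}

#' AUC with a DeLong-type 95% confidence interval
#'
#' Mann-Whitney AUC of scores against labels with an influence-function
#' (DeLong) variance estimate from the per-observation placement values;
#' the normal-approximation 95% CI is clipped to [0, 1]. Perfectly
#' separated scores give zero variance and a degenerate CI at the AUC.
#'
#' @param scores Numeric vector.
#' @param labels Vector with both classes present (-1/+1).
#' @return Numeric vector `c(auc, ci_low, ci_high)`.
#' @export
auc_with_ci <- function(scores, labels) {
  pos <- which(labels > 0); neg <- which(labels < 0)
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes must be present")
  sp <- scores[pos]; sn <- scores[neg]
  # placements: V10[i] = P(X_i > Y) + 0.5 P(X_i = Y) over negatives
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), numeric(1))
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), numeric(1))
  auc <- mean(v10)
  var_auc <- stats::var(v10) / length(sp) + stats::var(v01) / length(sn)
  half <- 1.96 * sqrt(max(var_auc, 0))
  c(auc = auc, ci_low = max(auc - half, 0), ci_high = min(auc + half, 1))
}

#' Train the final model on the full table
#'
#' AUC filter, inner CV hyperparameter selection, and a single regularized
#' logistic fit on all lesions; returns the model coefficients and the
#' selected feature names for reporting.
#'
#' @param table A [feature_table()].
#' @param config A [cv_config()].
#' @return List with `selected_features`, `alpha`, `coefficients` (named,
#'   including the intercept), `training_auc`.
#' @export
train_final_model <- function(table, config = cv_config()) {
  y <- table$label
  x <- table$features
  if (config$normalization != "none") {
    mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
  }
  B <- select_top_fraction(x, y, config$fraction)
  al <- inner_select_hyperparam(x[, B, drop = FALSE], y, config)
  fit <- .glmnet_fit(x[, B, drop = FALSE], y, config$penalty, al)
  co <- as.numeric(stats::coef(fit))
  names(co) <- c("(intercept)", colnames(x)[B])
  pred <- .glmnet_link(fit, x[, B, drop = FALSE])
  list(selected_features = colnames(x)[B], alpha = al, coefficients = co,
       training_auc = feature_auc_raw(pred, y))
}
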