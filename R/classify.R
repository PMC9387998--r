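#' Yeo-Johnson transformation with train-only parameter estimation
#'
#' Estimates, per feature column, the Yeo-Johnson power parameter lambda
#' by profile maximum likelihood (searched on \[-5, 5\]), transforms the
#' training matrix and scales each column to mean 0, variance 1.
#' The same lambda, centre and scale — estimated on the training data only
#' — are applied to `apply_to`, keeping evaluation splits leak-free.
#' Constant training columns cannot be transformed or scaled and are
#' dropped (recorded in `dropped`).
#'
#' @param train numeric matrix (rows = participants); `NA` not allowed
#'   (impute first, see [impute_median()]).
#' @param apply_to optional matrix with the same columns.
#' @return list with `train`, `apply` (transformed matrices), `lambda`,
#'   `center`, `scale`, `dropped` (column names).
#' @export
yeo_johnson_standardize <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (anyNA(train))
    abort("`train` contains NA; impute before transforming.",
          class = "saccadom_domain_error")
  keep <- apply(train, 2, function(col) isTRUE(sd(col) > 0))
  dropped <- colnames(train)[!keep]
  train <- train[, keep, drop = FALSE]
  lambda <- apply(train, 2, yeo_johnson_lambda)
  tr <- train
  for (j in seq_len(ncol(tr)))
    tr[, j] <- yeo_johnson(tr[, j], lambda[j])
  center <- colMeans(tr)
  scale_ <- apply(tr, 2, sd)
  tr <- sweep(sweep(tr, 2, center), 2, scale_, "/")
  ap <- NULL
  if (!is.null(apply_to)) {
    ap <- as.matrix(apply_to)[, keep, drop = FALSE]
    for (j in seq_len(ncol(ap)))
      ap[, j] <- yeo_johnson(ap[, j], lambda[j])
    ap <- sweep(sweep(ap, 2, center), 2, scale_, "/")
  }
  list(train = tr, apply = ap, lambda = lambda, center = center,
       scale = scale_, dropped = dropped)
}

#' Yeo-Johnson power transform
#'
#' The Yeo-Johnson family extends the Box-Cox transform to the whole real
#' line: for x >= 0, \eqn{((x+1)^\lambda - 1)/\lambda} (log(x+1) at
#' lambda = 0); for x < 0, \eqn{-((1-x)^{2-\lambda} - 1)/(2-\lambda)}
#' (-log(1-x) at lambda = 2). `lambda = 1` is the identity.
#'
#' @param x numeric vector.
#' @param lambda power parameter.
#' @return transformed vector.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  if (abs(lambda) > 1e-8) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else out[pos] <- log1p(x[pos])
  neg <- !is.na(x) & x < 0
  if (abs(lambda - 2) > 1e-8) {
    out[neg] <- -((1 - x[neg])^(2 - lambda) - 1) / (2 - lambda)
  } else out[neg] <- -log1p(-x[neg])
  out[is.na(x)] <- NA_real_
  out
}

# Profile log-likelihood MLE of the Yeo-Johnson parameter.
yeo_johnson_lambda <- function(x, interval = c(-5, 5)) {
  x <- x[is.finite(x)]
  n <- length(x)
  ll <- function(lambda) {
    z <- yeo_johnson(x, lambda)
    v <- var(z) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
  }
  # 1e-4 on lambda is far below any downstream sensitivity
  optimize(ll, interval, maximum = TRUE, tol = 1e-4)$maximum
}

#' Column-median imputation with train-only statistics
#'
#' Replaces missing entries by the training-column median; columns whose
#' training values are all missing are filled with 0 (and should be
#' dropped downstream as constant).
#'
#' @param train numeric matrix.
#' @param apply_to optional matrix with the same columns.
#' @return list with `train`, `apply`, `medians`.
#' @export
impute_median <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  med <- apply(train, 2, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train),
       apply = if (is.null(apply_to)) NULL else fill(as.matrix(apply_to)),
       medians = med)
}

#' Mutual information by equal-frequency binning
#'
#' Plug-in estimate (natural log) of the mutual information between `x`
#' and `y`. Continuous variables are discretised into equal-frequency
#' bins, `max(4, floor(sqrt(n)))` of them; variables with few distinct
#' values (such as a binary class label) are used as-is.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar (nats).
#' @export
mutual_information <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) return(0)
  ix <- as.integer(discretize_ef(x))
  iy <- as.integer(discretize_ef(y))
  mi_codes(ix, max(ix), iy, max(iy))
}

# Plug-in MI from pre-computed integer bin codes.
mi_codes <- function(ix, nx, iy, ny) {
  n <- length(ix)
  p <- tabulate(ix + nx * (iy - 1L), nx * ny) / n
  px <- tabulate(ix, nx) / n
  py <- tabulate(iy, ny) / n
  ind <- as.vector(outer(px, py))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / ind[nz]))
}

# Equal-frequency discretisation: sqrt(n) bins (minimum 4); variables
# that already take few distinct values are left as they are.
discretize_ef <- function(x) {
  ux <- unique(x)
  n_bins <- max(4, floor(sqrt(length(x))))
  if (length(ux) <= n_bins) return(factor(x))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Forward feature selection by residual mutual information
#'
#' Greedy forward selection for a binary label. The first feature
#' maximises the estimated mutual information (MI) with the label; each
#' subsequent candidate is scored by its MI with the residual of the
#' current model (label minus predicted class-1 probability of an
#' L2-regularised logistic fit on the selected set), so features that
#' explain what the current model misses are preferred over features
#' merely correlated with the label. After each addition the mean ROC-AUC
#' over stratified k-fold cross-validation is recorded; selection stops
#' at the first AUC decrease (or after three successive additions that
#' fail to improve on the running maximum — a plateau guard for
#' degenerate data) and the prefix achieving the maximum AUC is
#' returned. Score ties break toward the lowest column index.
#'
#' @param x numeric feature matrix (no missing values).
#' @param y binary labels (0/1).
#' @param folds number of stratified CV folds (default 5; requires at
#'   least `folds` participants per class).
#' @param l2_strength ridge penalty passed to [train_logistic()].
#' @param seed seed for the fold assignment (recorded in the result).
#' @param max_features optional cap on the number of selected features.
#' @return list with `selected` (the returned prefix, column names in
#'   selection order), `path` (every feature appended during the search,
#'   including those beyond the AUC peak), `auc_trace`, `fold_seed`.
#' @export
rmi_forward_select <- function(x, y, folds = 5, l2_strength = 1,
                               seed = NULL, max_features = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  # with very small training sets, shrink the fold count to the class sizes
  folds <- min(folds, min(table(y)))
  if (folds < 2)
    abort("need at least 2 observations per class.",
          class = "saccadom_domain_error")
  p <- ncol(x)
  if (is.null(max_features)) max_features <- p
  fold_id <- stratified_folds(y, folds, seed)

  usable <- which(apply(x, 2, sd) > 0)
  # feature bin codes are fixed across steps; only the target is re-binned
  codes <- lapply(seq_len(p), function(j) as.integer(discretize_ef(x[, j])))
  n_codes <- vapply(codes, max, integer(1))
  selected <- integer(0)
  auc_trace <- numeric(0)
  repeat {
    cand <- setdiff(usable, selected)
    if (!length(cand) || length(selected) >= max_features) break
    target <- if (!length(selected)) y else {
      fit <- train_logistic(x[, selected, drop = FALSE], y, l2_strength)
      y - predict(fit, x[, selected, drop = FALSE])
    }
    ty <- as.integer(discretize_ef(target))
    ny <- max(ty)
    scores <- vapply(cand, function(j) mi_codes(codes[[j]], n_codes[j], ty, ny),
                     numeric(1))
    if (all(scores <= 0) && length(selected)) break
    pick <- cand[which.max(scores)]  # which.max takes the first = lowest index
    selected <- c(selected, pick)
    auc <- cv_auc(x[, selected, drop = FALSE], y, fold_id, l2_strength)
    auc_trace <- c(auc_trace, auc)
    if (length(auc_trace) >= 2 &&
        auc < auc_trace[length(auc_trace) - 1]) break
    # plateau guard: stop after 3 additions that fail to set a new maximum
    k_best <- which.max(auc_trace)
    if (length(auc_trace) - k_best >= 3) break
  }
  k <- if (length(auc_trace)) which.max(auc_trace) else 0
  list(selected = colnames(x)[selected[seq_len(k)]],
       path = colnames(x)[selected],
       auc_trace = auc_trace, fold_seed = seed)
}

stratified_folds <- function(y, folds, seed = NULL) {
  id <- integer(length(y))
  with_seed_(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  id
}

# Mean per-fold ROC-AUC of an L2 logistic model under fixed fold ids.
cv_auc <- function(x, y, fold_id, l2_strength) {
  aucs <- vapply(sort(unique(fold_id)), function(k) {
    tr <- fold_id != k
    const <- apply(x[tr, , drop = FALSE], 2, sd) == 0
    if (all(const) || min(table(y[tr])) < 2 ||
        length(unique(y[tr])) < 2) return(0.5)
    fit <- train_logistic(x[tr, !const, drop = FALSE], y[tr], l2_strength)
    auc_mw(predict(fit, x[!tr, !const, drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(aucs)
}

#' L2-regularised logistic regression
#'
#' Ridge-penalised logistic regression (via `glmnet` with `alpha = 0` and
#' a single fixed penalty `lambda = l2_strength` on glmnet's
#' per-observation scale, so the optimum is invariant under duplicating
#' the dataset). Deterministic given the data and penalty. `predict()`
#' returns class-1 probabilities.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (0/1); both classes must be present.
#' @param l2_strength penalty strength (default 1).
#' @return object of class `saccadom_logistic`.
#' @export
train_logistic <- function(x, y, l2_strength = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    abort("both classes must be present.", class = "saccadom_domain_error")
  pad <- ncol(x) < 2   # glmnet requires >= 2 columns; pad with a dead column
  if (pad) x <- cbind(x, `.pad` = 0)
  # glmnet warns about classes below 8 observations on every small fold;
  # expected at these cohort sizes, so silenced here
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = l2_strength, standardize = FALSE))
  structure(list(fit = fit, pad = pad, lambda = l2_strength),
            class = "saccadom_logistic")
}

#' @export
predict.saccadom_logistic <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$pad) newdata <- cbind(newdata, `.pad` = 0)
  as.vector(predict(object$fit, newx = newdata, s = object$lambda,
                    type = "response"))
}

#' Random-forest classifier
#'
#' Probability forest with `n_trees` trees (via `ranger`), seeded for
#' determinism; `predict()` returns the fraction of tree votes for
#' class 1. Impurity importances are stored for feature ranking.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (0/1).
#' @param n_trees number of trees (default 400).
#' @param seed RNG seed.
#' @return object of class `saccadom_forest`.
#' @export
train_forest <- function(x, y, n_trees = 400, seed = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    abort("both classes must be present.", class = "saccadom_domain_error")
  df <- as.data.frame(x)
  df$.label <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df, probability = TRUE,
    num.trees = n_trees, importance = "impurity",
    seed = if (is.null(seed)) 1L else as.integer(seed),
    num.threads = 1)
  structure(list(fit = fit, features = colnames(x)),
            class = "saccadom_forest")
}

#' @export
predict.saccadom_forest <- function(object, newdata, ...) {
  df <- as.data.frame(as.matrix(newdata))
  colnames(df) <- object$features
  predict(object$fit, data = df, num.threads = 1)$predictions[, "1"]
}

#' Model-fitting procedures for cross-validated evaluation
#'
#' Trainer factories wrap the full leak-free modelling pipeline into a
#' single function `trainer(x, y, seed)` returning a predictor
#' `function(x_new) -> probabilities`, the only interface
#' [tlpo_cv()] and [five_by_two_f_test()] accept. All preprocessing
#' (median imputation, Yeo-Johnson scaling, forward feature selection and
#' its internal cross-validation) is estimated inside the trainer on the
#' training rows only, so evaluation data never leak into the pipeline.
#'
#' `logistic_trainer(select = FALSE)` omits the forward-selection step
#' (transformation and ridge fit only).
#'
#' @param l2_strength ridge penalty.
#' @param select run residual-mutual-information forward selection.
#' @param folds CV folds inside selection.
#' @param n_trees forest size.
#' @return a trainer function.
#' @export
logistic_trainer <- function(l2_strength = 1, select = TRUE, folds = 5) {
  function(x, y, seed = NULL) {
    imp <- impute_median(x)
    yj <- yeo_johnson_standardize(imp$train)
    xt <- yj$train
    sel <- colnames(xt)
    if (select) {
      s <- rmi_forward_select(xt, y, folds = folds,
                              l2_strength = l2_strength, seed = seed)
      if (length(s$selected)) sel <- s$selected
    }
    fit <- train_logistic(xt[, sel, drop = FALSE], y, l2_strength)
    structure(function(x_new) {
      m <- as.matrix(x_new)
      for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- imp$medians[j]
      keep <- setdiff(colnames(m), yj$dropped)
      m <- m[, keep, drop = FALSE]
      for (j in seq_len(ncol(m))) m[, j] <- yeo_johnson(m[, j], yj$lambda[j])
      m <- sweep(sweep(m, 2, yj$center), 2, yj$scale, "/")
      predict(fit, m[, sel, drop = FALSE])
    }, selected = sel)
  }
}

#' @rdname logistic_trainer
#' @export
forest_trainer <- function(n_trees = 400) {
  function(x, y, seed = NULL) {
    imp <- impute_median(x)
    fit <- train_forest(imp$train, y, n_trees = n_trees, seed = seed)
    function(x_new) {
      m <- as.matrix(x_new)
      for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- imp$medians[j]
      predict(fit, m)
    }
  }
}

#' Feature-importance ranking over participant subsets
#'
#' Draws `n_subsets` random overlapping subsets of `subset_fraction` of
#' the participants and trains the chosen model on each. Logistic
#' features are scored by the proportion of subset fits in which forward
#' selection retained them; forest features by the mean decrease in Gini
#' impurity, averaged over subsets and normalised to sum 1.
#'
#' @param features feature table (`participant_id`, `group`, features).
#' @param model `"logistic"` or `"forest"`.
#' @param n_subsets number of subsets (default 75).
#' @param subset_fraction fraction of participants per subset (default
#'   2/3).
#' @param seed master seed.
#' @param ... passed to the trainer factory.
#' @return object of class `feature_ranking`: tibble with `feature`,
#'   `score`, `rank`, plus attributes `model`, `n_subsets`.
#' @export
rank_features <- function(features, model = c("logistic", "forest"),
                          n_subsets = 75, subset_fraction = 2 / 3,
                          seed = 1L, ...) {
  model <- match.arg(model)
  d <- cohort_matrix(features)
  n <- nrow(d$x)
  m <- floor(n * subset_fraction)
  score <- setNames(numeric(ncol(d$x)), colnames(d$x))
  denom <- 0
  for (s in seq_len(n_subsets)) {
    sub_seed <- derive_seed(seed, s)
    idx <- with_seed_(sub_seed, sample(n, m))
    if (length(unique(d$y[idx])) < 2) next
    denom <- denom + 1
    if (model == "logistic") {
      imp <- impute_median(d$x[idx, , drop = FALSE])
      yj <- yeo_johnson_standardize(imp$train)
      sel <- tryCatch(
        rmi_forward_select(yj$train, d$y[idx], seed = sub_seed, ...)$selected,
        error = function(e) character(0))
      score[sel] <- score[sel] + 1
    } else {
      imp <- impute_median(d$x[idx, , drop = FALSE])
      fit <- train_forest(imp$train, d$y[idx], seed = sub_seed, ...)
      imp_scores <- fit$fit$variable.importance
      score[names(imp_scores)] <- score[names(imp_scores)] + imp_scores
    }
  }
  score <- score / max(denom, 1)
  if (model == "forest" && sum(score) > 0) score <- score / sum(score)
  out <- tibble(feature = names(score), score = unname(score)) %>%
    arrange(dplyr::desc(.data$score)) %>%
    mutate(rank = row_number())
  structure(out, class = c("feature_ranking", class(out)),
            model = model, n_subsets = n_subsets)
}

# Feature table -> numeric matrix + 0/1 labels (pd = 1).
cohort_matrix <- function(features) {
  stopifnot(all(c("participant_id", "group") %in% names(features)))
  fcols <- setdiff(names(features), c("participant_id", "group"))
  x <- as.matrix(features[fcols])
  storage.mode(x) <- "double"
  rownames(x) <- features$participant_id
  y <- as.integer(features$group == "pd")
  # drop features that are missing for every participant
  keep <- colSums(is.finite(x)) > 0
  list(x = x[, keep, drop = FALSE], y = y)
}
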