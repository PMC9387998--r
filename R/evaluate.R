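#' Tournament leave-pair-out cross-validation
#'
#' Near-unbiased ROC-AUC estimation for small cohorts. For every
#' unordered pair of participants, the model is trained on the remaining
#' n - 2 (all preprocessing nested inside the trainer, so it is naive to
#' the held-out pair) and both held-out participants are scored; the
#' higher-scored one wins the pairing (exact ties give each half a win).
#' Participants are ranked by total wins, an ROC curve is built from that
#' ranking against the true labels, and the AUC equals the Mann-Whitney
#' statistic of the win scores, with ties counting one half. With n
#' participants this performs n(n-1)/2 model fits, each on n - 2
#' participants (1,275 fits of 49 for n = 51).
#'
#' Per-pair trainer seeds are derived deterministically from `seed` and
#' the pair index, so results are reproducible and independent of
#' execution order.
#'
#' @param features feature table: `participant_id`, `group`
#'   (`"pd"` / `"control"`), feature columns.
#' @param trainer a trainer function `(x, y, seed) -> predictor`; see
#'   [logistic_trainer()].
#' @param seed master seed.
#' @return object of class `tlpo_result`: list with `wins` (per
#'   participant), `ranking`, `roc` (curve points), `auc`, `n_fits`,
#'   `train_size_per_fit`, `n_failed`.
#' @export
tlpo_cv <- function(features, trainer, seed = 1L) {
  d <- cohort_matrix(features)
  n <- nrow(d$x)
  if (n < 4) abort("TLPO-CV needs at least 4 participants.",
                   class = "saccadom_domain_error")
  if (length(unique(d$y)) < 2)
    abort("both classes must be present.", class = "saccadom_domain_error")
  pairs <- utils::combn(n, 2)
  wins <- setNames(numeric(n), rownames(d$x))
  n_failed <- 0L
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tr_idx <- setdiff(seq_len(n), c(i, j))
    predictor <- tryCatch(
      trainer(d$x[tr_idx, , drop = FALSE], d$y[tr_idx],
              seed = derive_seed(seed, k)),
      error = function(e) NULL)
    if (is.null(predictor)) {
      n_failed <- n_failed + 1L
      wins[i] <- wins[i] + 0.5; wins[j] <- wins[j] + 0.5
      next
    }
    s <- tryCatch(predictor(d$x[c(i, j), , drop = FALSE]),
                  error = function(e) c(NA_real_, NA_real_))
    if (anyNA(s)) {
      n_failed <- n_failed + 1L
      wins[i] <- wins[i] + 0.5; wins[j] <- wins[j] + 0.5
    } else if (s[1] > s[2]) {
      wins[i] <- wins[i] + 1
    } else if (s[2] > s[1]) {
      wins[j] <- wins[j] + 1
    } else {
      wins[i] <- wins[i] + 0.5; wins[j] <- wins[j] + 0.5
    }
  }
  roc <- roc_from_scores(wins, d$y)
  structure(list(
    wins = tibble(participant_id = rownames(d$x), group = ifelse(d$y == 1, "pd", "control"),
                  wins = unname(wins),
                  rank = rank(-wins, ties.method = "average")),
    roc = roc$curve, auc = roc$auc,
    n_fits = ncol(pairs), train_size_per_fit = n - 2L,
    n_failed = n_failed, seed = seed),
    class = "tlpo_result")
}

#' @export
print.tlpo_result <- function(x, ...) {
  cat("<tlpo_result> AUC:", round(x$auc, 3),
      " fits:", x$n_fits, "x", x$train_size_per_fit, "participants",
      if (x$n_failed) paste0(" (", x$n_failed, " failed pairs)"), "\n")
  invisible(x)
}

#' @rdname tlpo_cv
#' @param x a `tlpo_result`.
#' @param ... unused.
#' @export
tidy.tlpo_result <- function(x, ...) x$wins

#' @rdname tlpo_cv
#' @export
glance.tlpo_result <- function(x, ...) {
  tibble(auc = x$auc, n_fits = x$n_fits,
         train_size_per_fit = x$train_size_per_fit, n_failed = x$n_failed)
}

#' ROC curve and AUC from a participant ranking
#'
#' Builds the ROC over rank thresholds (rank 1 = most case-like) and
#' computes the AUC through the Mann-Whitney identity
#' \eqn{AUC = U / (n_+ n_-)} — the proportion of case-control pairs in
#' which the case outranks the control, ties counting one half. The
#' trapezoidal area under the returned curve equals that identity.
#'
#' @param ranks numeric ranks, smaller = more case-like (ties allowed).
#' @param labels binary labels (1 = case).
#' @return list with `curve` (tibble `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_from_ranking(c(1, 2, 3, 4), c(1, 0, 1, 0))$auc  # 0.75
#' @export
roc_from_ranking <- function(ranks, labels) {
  roc_from_scores(-as.numeric(ranks), labels)
}

# ROC/AUC from scores (larger = more case-like).
roc_from_scores <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2)
    abort("both classes must be present.", class = "saccadom_domain_error")
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yo <- y[ord]
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- tapply(yo == 1, grp, sum)
  fp <- tapply(yo == 0, grp, sum)
  curve <- tibble(fpr = c(0, cumsum(fp) / nn), tpr = c(0, cumsum(tp) / np))
  r <- rank(scores)
  u <- sum(r[y == 1]) - np * (np + 1) / 2
  list(curve = curve, auc = u / (np * nn))
}

# Mann-Whitney AUC of probability scores against labels.
auc_mw <- function(scores, labels) {
  y <- as.numeric(labels)
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' 5x2 cross-validation combined F-test
#'
#' Head-to-head comparison of two classifiers. The data are split into
#' stratified halves five times; in each replication both halves serve
#' once as training set, and the difference in test-set ROC-AUC between
#' the two classifiers gives \eqn{p_{ij}} (replication i, fold j). With
#' per-replication variances \eqn{s_i^2 = (p_{i1}-\bar p_i)^2 +
#' (p_{i2}-\bar p_i)^2}, the combined statistic
#' \deqn{F = \frac{\sum_{ij} p_{ij}^2}{2 \sum_i s_i^2}}
#' follows an F(10, 5) distribution under the null of equal performance.
#' If every difference is exactly zero (e.g. identical classifiers) the
#' result is flagged degenerate and p = 1 is reported.
#'
#' @param features feature table as in [tlpo_cv()].
#' @param trainer_a,trainer_b trainer functions.
#' @param seed master seed for the five splits and the trainers.
#' @return object of class `five_by_two_result`: list with
#'   `differences` (tibble `replication`, `fold`, `auc_a`, `auc_b`,
#'   `diff`), `statistic`, `p.value`, `degenerate`.
#' @export
five_by_two_f_test <- function(features, trainer_a, trainer_b, seed = 1L) {
  d <- cohort_matrix(features)
  n <- nrow(d$x)
  if (n < 8) abort("the 5x2 test needs at least 8 participants.",
                   class = "saccadom_domain_error")
  rows <- list()
  for (i in 1:5) {
    half <- with_seed_(derive_seed(seed, i), {
      h <- rep(2L, n)
      for (cls in unique(d$y)) {
        idx <- sample(which(d$y == cls))
        h[idx[seq_len(ceiling(length(idx) / 2))]] <- 1L
      }
      h
    })
    for (j in 1:2) {
      tr <- half == j
      auc_for <- function(trainer, off) {
        pred <- trainer(d$x[tr, , drop = FALSE], d$y[tr],
                        seed = derive_seed(seed, 100 * i + 10 * j + off))
        auc_mw(pred(d$x[!tr, , drop = FALSE]), d$y[!tr])
      }
      a <- auc_for(trainer_a, 1)
      b <- auc_for(trainer_b, 2)
      rows[[length(rows) + 1]] <- tibble(replication = i, fold = j,
                                         auc_a = a, auc_b = b,
                                         diff = a - b)
    }
  }
  diffs <- bind_rows(rows)
  degenerate <- all(diffs$diff == 0)
  s2 <- diffs %>% group_by(.data$replication) %>%
    summarise(s2 = sum((.data$diff - mean(.data$diff))^2), .groups = "drop")
  if (degenerate || sum(s2$s2) == 0) {
    stat <- NA_real_; p <- 1
    degenerate <- TRUE
  } else {
    stat <- sum(diffs$diff^2) / (2 * sum(s2$s2))
    p <- stats::pf(stat, 10, 5, lower.tail = FALSE)
  }
  structure(list(differences = diffs, statistic = stat, p.value = p,
                 degenerate = degenerate, seed = seed),
            class = "five_by_two_result")
}

#' @export
print.five_by_two_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<five_by_two_result> degenerate (no performance differences); p = 1\n")
  } else {
    cat(sprintf("<five_by_two_result> F(10, 5) = %.3f, p = %.4f\n",
                x$statistic, x$p.value))
  }
  invisible(x)
}

#' @rdname five_by_two_f_test
#' @param x a `five_by_two_result`.
#' @param ... unused.
#' @export
tidy.five_by_two_result <- function(x, ...) x$differences

#' @rdname five_by_two_f_test
#' @export
glance.five_by_two_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         degenerate = x$degenerate)
}
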