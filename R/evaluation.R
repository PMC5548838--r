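#' ROC curve and AUC with the midrank tie convention
#'
#' `roc_curve()` sweeps a descending threshold over the distinct score
#' values and returns the (false positive rate, true positive rate)
#' points, starting at (0, 0) and ending at (1, 1). The AUC is the
#' trapezoidal area under those points, which for tie-grouped points
#' equals the Mann-Whitney statistic with ties counted 1/2
#' (`P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)`).
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels 0/1 (or logical) vector of true labels, same length.
#' @return `roc_curve()`: a tibble of class `lrls_roc` with columns `fpr`,
#'   `tpr`, `threshold` and attribute `auc`. `roc_auc()`: the AUC as a
#'   plain number.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3), c(1, 1, 0))
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("AUC undefined: need at least one positive and one negative label",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group ties so each distinct score contributes one point
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1L - l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / nn),
    tpr = c(0, tp[last] / np)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(pts, auc = auc, class = c("lrls_roc", class(pts)))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, labels) {
  attr(roc_curve(scores, labels), "auc")
}

#' @export
print.lrls_roc <- function(x, ...) {
  cat("ROC curve: ", nrow(x), " points, AUC = ",
      format(attr(x, "auc"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' @method autoplot lrls_roc
#' @export
autoplot.lrls_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.4f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

# return a copy of the network with the given known edges removed
mask_edges <- function(network, idx) {
  Y <- network$Y
  Y[idx] <- 0L
  out <- network
  out$Y <- Y
  out
}

# fit on a masked network, muffling singular-fallback warnings and
# tallying them into the caller's counter environment
quiet_fit_scores <- function(network, params, counter) {
  withCallingHandlers(
    {
      fit <- lrlshmda(network, params)
      counter$n <- counter$n + fit$n_fallback
      fit$scores
    },
    warning = function(w) {
      if (inherits(w, "lrls_singular_fallback")) {
        counter$n <- counter$n + 1L
        invokeRestart("muffleWarning")
      }
    }
  )
}

new_lrls_cv <- function(protocol, auc_mean, auc_sd, n_repeats, seed,
                        detail, roc = NULL, extra = list()) {
  structure(c(list(protocol = protocol, auc_mean = auc_mean,
                   auc_sd = auc_sd, n_repeats = n_repeats, seed = seed,
                   detail = detail, roc = roc), extra),
            class = "lrls_cv")
}

#' Global leave-one-out cross validation
#'
#' Each known association is removed in turn; both GIP kernels are
#' recomputed on the masked network, the model is refit, and the held-out
#' pair's score is recorded. The held-out scores are then ranked against
#' the scores of all unknown microbe-disease pairs across every disease.
#'
#' With `negatives = "full"` (default) the unknown-pair scores come from a
#' single fit on the complete network and one pooled ROC is formed. With
#' `negatives = "per_run"` each held-out positive is compared against the
#' unknown-pair scores of its own masked run and the per-pair concordance
#' fractions (ties counted 1/2) are averaged.
#'
#' @param network An `mda_network` with at least 2 associations.
#' @param params An [lrls_params()].
#' @param negatives Negative-score provenance, `"full"` or `"per_run"`.
#' @return An `lrls_cv` with `auc_mean` (the LOOCV AUC; `auc_sd = 0`,
#'   deterministic), a per-pair detail tibble, and for `"full"` the pooled
#'   `lrls_roc` curve.
#' @export
loocv_global <- function(network, params = lrls_params(),
                         negatives = c("full", "per_run")) {
  negatives <- match.arg(negatives)
  stopifnot(inherits(network, "mda_network"))
  pos_idx <- which(network$Y == 1L, arr.ind = TRUE)
  if (nrow(pos_idx) < 2L) {
    stop("global LOOCV needs a network with at least 2 associations",
         call. = FALSE)
  }
  unknown <- which(network$Y == 0L)
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  full_scores <- quiet_fit_scores(network, params, counter)

  held_out <- numeric(nrow(pos_idx))
  per_run_auc <- numeric(nrow(pos_idx))
  for (e in seq_len(nrow(pos_idx))) {
    sc <- quiet_fit_scores(mask_edges(network, pos_idx[e, , drop = FALSE]),
                           params, counter)
    held_out[e] <- sc[pos_idx[e, 1L], pos_idx[e, 2L]]
    if (negatives == "per_run") {
      neg <- sc[unknown]
      per_run_auc[e] <- (sum(neg < held_out[e]) +
                           0.5 * sum(neg == held_out[e])) / length(neg)
    }
  }
  detail <- tibble::tibble(
    microbe = network$microbe_index[pos_idx[, 1L]],
    disease = network$disease_index[pos_idx[, 2L]],
    score = held_out
  )
  if (negatives == "full") {
    neg <- full_scores[unknown]
    roc <- roc_curve(c(held_out, neg),
                     c(rep(1L, length(held_out)), rep(0L, length(neg))))
    auc <- attr(roc, "auc")
  } else {
    detail$auc <- per_run_auc
    roc <- NULL
    auc <- mean(per_run_auc)
  }
  new_lrls_cv("global-loocv", auc, 0, 1L, NA_integer_, detail, roc,
              extra = list(negatives = negatives,
                           n_fallback = counter$n))
}

#' Local leave-one-out cross validation
#'
#' Identical masking-and-recompute loop to [loocv_global()], but each
#' held-out association is ranked only against the unknown microbes of its
#' own disease: for each pair the tie-corrected rank percentile of the
#' held-out score within its disease column (masked-run scores) is
#' computed, and the percentiles are pooled by averaging into one AUC.
#'
#' @inheritParams loocv_global
#' @return An `lrls_cv` with per-pair percentiles in the detail tibble.
#' @export
loocv_local <- function(network, params = lrls_params()) {
  stopifnot(inherits(network, "mda_network"))
  pos_idx <- which(network$Y == 1L, arr.ind = TRUE)
  if (nrow(pos_idx) < 2L) {
    stop("local LOOCV needs a network with at least 2 associations",
         call. = FALSE)
  }
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  pct <- numeric(nrow(pos_idx))
  n_neg <- integer(nrow(pos_idx))
  for (e in seq_len(nrow(pos_idx))) {
    i <- pos_idx[e, 1L]; j <- pos_idx[e, 2L]
    sc <- quiet_fit_scores(mask_edges(network, pos_idx[e, , drop = FALSE]),
                           params, counter)
    neg <- sc[network$Y[, j] == 0L, j]
    if (length(neg) == 0L) {
      pct[e] <- NA_real_
    } else {
      pct[e] <- (sum(neg < sc[i, j]) + 0.5 * sum(neg == sc[i, j])) /
        length(neg)
    }
    n_neg[e] <- length(neg)
  }
  detail <- tibble::tibble(
    microbe = network$microbe_index[pos_idx[, 1L]],
    disease = network$disease_index[pos_idx[, 2L]],
    percentile = pct, n_candidates = n_neg
  )
  new_lrls_cv("local-loocv", mean(pct, na.rm = TRUE), 0, 1L, NA_integer_,
              detail, NULL, extra = list(n_fallback = counter$n))
}

#' Repeated k-fold cross validation over known associations
#'
#' Per repeat, all known association pairs are split uniformly at random
#' into `k` groups of near-equal size; each group is masked in turn (all
#' its edges removed simultaneously), the kernels recomputed, the model
#' refit, and the group's held-out positives ranked globally against the
#' unknown-pair scores of the same masked run (one ROC per fold); the
#' repeat's AUC is the mean over its folds. Scoring positives and
#' negatives from the same run keeps the two groups comparable: a fold
#' removes many edges at once, so scores of *all* pairs shift together.
#' Reproducible for a fixed seed; each repeat uses a seed derived from the
#' master seed (recorded in the per-repeat detail).
#'
#' @inheritParams loocv_global
#' @param k Number of folds, default 5.
#' @param repeats Number of random repartitions, default 100.
#' @param seed Master seed for the fold assignments.
#' @return An `lrls_cv` with `auc_mean`/`auc_sd` over repeats, per-repeat
#'   and per-fold AUC detail tibbles, and `fold_auc_sd` (the sd over all
#'   `k * repeats` fold-level AUCs).
#' @export
cv_kfold <- function(network, params = lrls_params(), k = 5, repeats = 100,
                     seed = 1) {
  stopifnot(inherits(network, "mda_network"))
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  pos_idx <- which(network$Y == 1L, arr.ind = TRUE)
  n_pos <- nrow(pos_idx)
  if (n_pos < k) {
    stop("k-fold CV needs at least k = ", k, " known associations",
         call. = FALSE)
  }
  unknown <- which(network$Y == 0L)
  counter <- new.env(parent = emptyenv()); counter$n <- 0L

  repeat_seeds <- (as.integer(seed) + 7919L * seq_len(repeats)) %%
    .Machine$integer.max
  repeat_auc <- numeric(repeats)
  fold_rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- withr::with_seed(repeat_seeds[r],
                              sample(rep_len(seq_len(k), n_pos)))
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      in_fold <- folds == f
      sc <- quiet_fit_scores(
        mask_edges(network, pos_idx[in_fold, , drop = FALSE]),
        params, counter)
      pos <- sc[pos_idx[in_fold, , drop = FALSE]]
      neg <- sc[unknown]
      fold_auc[f] <- roc_auc(c(pos, neg),
                             c(rep(1L, length(pos)), rep(0L, length(neg))))
    }
    repeat_auc[r] <- mean(fold_auc)
    fold_rows[[r]] <- tibble::tibble(repeat_id = r, fold = seq_len(k),
                                     auc = fold_auc)
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  detail <- tibble::tibble(repeat_id = seq_len(repeats),
                           seed = repeat_seeds, auc = repeat_auc)
  new_lrls_cv("kfold", mean(repeat_auc),
              if (repeats > 1L) stats::sd(repeat_auc) else 0,
              as.integer(repeats), as.integer(seed), detail,
              extra = list(
                per_fold = per_fold, k = as.integer(k),
                fold_auc_sd = stats::sd(per_fold$auc),
                n_fallback = counter$n))
}

#' @export
print.lrls_cv <- function(x, ...) {
  cat("Cross-validation result (", x$protocol, ")\n",
      "  AUC: ", format(x$auc_mean, digits = 4),
      if (x$n_repeats > 1L)
        paste0(" +/- ", format(x$auc_sd, digits = 3), " over ",
               x$n_repeats, " repeats"),
      "\n", sep = "")
  invisible(x)
}

#' Tidy and summarize cross-validation results
#'
#' `tidy()` returns the per-unit detail (per held-out pair for the LOOCV
#' protocols, per repeat for k-fold); `glance()` a one-row summary.
#'
#' @param x An `lrls_cv`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lrls_cv
#' @export
tidy.lrls_cv <- function(x, ...) {
  x$detail
}

#' @rdname tidy.lrls_cv
#' @method glance lrls_cv
#' @export
glance.lrls_cv <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol,
    auc_mean = x$auc_mean,
    auc_sd = x$auc_sd,
    n_repeats = x$n_repeats,
    seed = x$seed,
    n_fallback = if (is.null(x$n_fallback)) NA_integer_ else x$n_fallback
  )
}

#' @method autoplot lrls_cv
#' @export
autoplot.lrls_cv <- function(object, ...) {
  if (!is.null(object$roc)) return(autoplot.lrls_roc(object$roc))
  if (identical(object$protocol, "kfold")) {
    return(
      ggplot2::ggplot(object$detail, ggplot2::aes(x = .data$auc)) +
        ggplot2::geom_histogram(bins = 20, fill = "grey40") +
        ggplot2::labs(x = "AUC per repeat", y = "count",
                      title = sprintf("%d-fold CV, %d repeats: AUC %.4f +/- %.4f",
                                      object$k, object$n_repeats,
                                      object$auc_mean, object$auc_sd)) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$detail, ggplot2::aes(x = .data$percentile)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40") +
    ggplot2::labs(x = "within-disease rank percentile", y = "count",
                  title = sprintf("Local LOOCV: pooled AUC %.4f",
                                  object$auc_mean)) +
    ggplot2::theme_minimal()
}
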