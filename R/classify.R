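# Correlation-based feature selection (CFS), leave-one-out random-forest
# classification, and confusion-matrix metrics.

# feature-class (point-biserial) and feature-feature (Pearson) absolute
# correlations; zero-variance features correlate 0 by convention
cfs_correlations <- function(x, y) {
  y01 <- as.numeric(y)
  const <- vapply(x, function(v) sd(v) == 0 || !is.finite(sd(v)),
                  logical(1))
  if (any(const)) {
    warning("zero-variance feature(s) treated as uncorrelated: ",
            paste(utils::head(names(x)[const], 5), collapse = ", "))
  }
  xm <- as.matrix(x)
  xm[, const] <- 0
  rcf <- suppressWarnings(abs(as.vector(cor(xm, y01))))
  rcf[!is.finite(rcf)] <- 0
  rff <- suppressWarnings(abs(cor(xm)))
  rff[!is.finite(rff)] <- 0
  diag(rff) <- 1
  list(rcf = setNames(rcf, names(x)), rff = rff)
}

#' CFS merit from summary correlations
#'
#' The closed-form merit of a subset of `k` features with mean absolute
#' feature-class correlation `r_cf` and mean absolute pairwise
#' feature-feature correlation `r_ff`:
#' \eqn{k r_{cf} / \sqrt{k + k (k - 1) r_{ff}}}. For `k = 1` this
#' reduces to `r_cf`; perfectly redundant pairs (`r_ff = 1`) gain
#' nothing over a single feature.
#'
#' @param k Subset size.
#' @param r_cf Mean absolute feature-class correlation.
#' @param r_ff Mean absolute feature-feature correlation.
#' @return Merit (unitless scalar).
#' @export
cfs_merit_formula <- function(k, r_cf, r_ff) {
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

#' CFS merit of a feature subset
#'
#' The correlation-based feature selection heuristic
#' \deqn{M_S = \frac{k \bar r_{cf}}{\sqrt{k + k (k-1) \bar r_{ff}}}}
#' where \eqn{k} is the subset size, \eqn{\bar r_{cf}} the mean
#' absolute feature-class correlation (point-biserial: Pearson against
#' the 0/1 label) and \eqn{\bar r_{ff}} the mean absolute pairwise
#' feature-feature Pearson correlation. High merit rewards subsets that
#' predict the class while being mutually non-redundant.
#'
#' @param subset Character vector of feature names (non-empty).
#' @param x Data frame of numeric features (columns named as in
#'   `subset`).
#' @param y Binary class labels (logical or 0/1).
#' @return Merit (unitless scalar).
#' @export
cfs_merit <- function(subset, x, y) {
  if (length(subset) == 0) stop("subset must be non-empty")
  stopifnot(all(subset %in% names(x)))
  co <- cfs_correlations(x[subset], y)
  k <- length(subset)
  r_cf <- mean(co$rcf)
  r_ff <- if (k > 1) mean(co$rff[upper.tri(co$rff)]) else 0
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

#' Correlation-based feature selection by best-first search
#'
#' Forward best-first search over feature subsets maximizing the CFS
#' merit: starting from the best singleton, the highest-merit
#' unexpanded subset is expanded by every remaining feature; the search
#' stops after `max_stall` consecutive expansions that fail to improve
#' the best merit found. Deterministic given the data (ties break on
#' registry order). All-constant data yields an empty selection with a
#' warning.
#'
#' @param x Data frame of numeric features.
#' @param y Binary class labels.
#' @param max_stall Consecutive non-improving expansions before
#'   stopping (default 5).
#' @return A `cfs_result`: list with `selected` (feature names),
#'   `merit`, and `trace` (one row per expansion).
#' @export
cfs_select <- function(x, y, max_stall = 5L) {
  if (ncol(x) < 1) stop("need at least one feature")
  co <- cfs_correlations(x, y)
  rcf <- co$rcf
  rff <- co$rff
  merit_of <- function(idx, sum_rcf, sum_rff) {
    k <- length(idx)
    rbar_ff <- if (k > 1) sum_rff / (k * (k - 1) / 2) else 0
    k * (sum_rcf / k) / sqrt(k + k * (k - 1) * rbar_ff)
  }
  d <- ncol(x)
  if (all(rcf == 0)) {
    warning("all features uncorrelated with the class; empty selection")
    return(structure(list(selected = character(0), merit = 0,
                          trace = data.frame()), class = "cfs_result"))
  }
  # nodes: list(idx, sum_rcf, sum_rff, merit); seed with singletons
  nodes <- lapply(seq_len(d), function(j) {
    list(idx = j, sum_rcf = rcf[j], sum_rff = 0,
         merit = merit_of(j, rcf[j], 0))
  })
  merits <- vapply(nodes, `[[`, 0, "merit")
  expanded <- rep(FALSE, length(nodes))
  seen <- new.env(hash = TRUE)
  for (j in seq_len(d)) assign(as.character(j), TRUE, envir = seen)
  best_i <- which.max(merits)
  best_merit <- merits[best_i]
  stall <- 0L
  trace <- list()
  while (stall < max_stall) {
    open <- which(!expanded)
    if (length(open) == 0) break
    cur_i <- open[which.max(merits[open])]
    expanded[cur_i] <- TRUE
    cur <- nodes[[cur_i]]
    improved <- FALSE
    for (j in setdiff(seq_len(d), cur$idx)) {
      idx <- sort(c(cur$idx, j))
      key <- paste(idx, collapse = ",")
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      node <- list(idx = idx,
                   sum_rcf = cur$sum_rcf + rcf[j],
                   sum_rff = cur$sum_rff + sum(rff[j, cur$idx]))
      node$merit <- merit_of(idx, node$sum_rcf, node$sum_rff)
      nodes[[length(nodes) + 1L]] <- node
      merits <- c(merits, node$merit)
      expanded <- c(expanded, FALSE)
      if (node$merit > best_merit + 1e-12) {
        best_merit <- node$merit
        best_i <- length(nodes)
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
    trace[[length(trace) + 1L]] <- data.frame(
      expanded_size = length(cur$idx),
      expanded_merit = cur$merit,
      best_merit = best_merit)
  }
  structure(list(selected = names(x)[nodes[[best_i]]$idx],
                 merit = unname(best_merit),
                 trace = do.call(rbind, trace)),
            class = "cfs_result")
}

#' @export
print.cfs_result <- function(x, ...) {
  cat(sprintf("<cfs_result> %d feature(s), merit %.4f\n",
              length(x$selected), x$merit))
  invisible(x)
}

#' Confusion matrix
#'
#' Counts laid out with actual class in rows (no fall risk, fall risk)
#' and predicted class in columns; fall risk is the positive class.
#'
#' @param tn,fp True/false counts for the no-fall-risk row.
#' @param fn,tp False/true counts for the fall-risk row.
#' @return A named integer vector of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  m <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(m < 0)) stop("confusion counts must be non-negative")
  structure(as.integer(m), names = names(m), class = "confusion_matrix")
}

#' Confusion-matrix metrics
#'
#' Accuracy \eqn{(tn + tp) / n}, sensitivity \eqn{tp / (tp + fn)} and
#' specificity \eqn{tn / (tn + fp)}, with fall risk as the positive
#' class. Computed in exact arithmetic; the `*_pct` fields are the
#' percentages rounded to one decimal.
#'
#' @param m A [confusion_matrix()] (or named vector with `tn`, `fp`,
#'   `fn`, `tp`).
#' @return List with `accuracy`, `sensitivity`, `specificity`
#'   (proportions, `NA` when a margin is empty) and their `*_pct`
#'   counterparts.
#' @export
confusion_metrics <- function(m) {
  tn <- m[["tn"]]; fp <- m[["fp"]]; fn <- m[["fn"]]; tp <- m[["tp"]]
  total <- tn + fp + fn + tp
  if (total <= 0) stop("empty confusion matrix")
  acc <- (tn + tp) / total
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       accuracy_pct = round(100 * acc, 1),
       sensitivity_pct = round(100 * sens, 1),
       specificity_pct = round(100 * spec, 1))
}

#' Leave-one-out random-forest fall-risk classification
#'
#' For each participant in turn: run CFS on the remaining participants
#' only (leakage-safe), train a random forest (majority vote over
#' `num_trees` trees, `sqrt(d)` candidate features per split) on the
#' selected features, and predict the held-out participant. The n
#' predictions accumulate into the confusion matrix.
#'
#' @param participants Cohort table from [bind_participants()]:
#'   `participant_id`, `fall_risk`, then feature columns.
#' @param num_trees Trees per forest (default 100).
#' @param seed Integer seed; each fold re-seeds deterministically.
#' @param use_cfs Run per-fold CFS (default `TRUE`); otherwise all
#'   features enter the forest.
#' @return A `classification_report`: confusion matrix, metrics,
#'   per-fold selected features, seed and configuration.
#' @export
loocv_random_forest <- function(participants, num_trees = 100L,
                                seed = 1L, use_cfs = TRUE) {
  y <- factor(ifelse(participants$fall_risk, "fall_risk",
                     "no_fall_risk"),
              levels = c("no_fall_risk", "fall_risk"))
  if (any(table(y) < 2)) {
    stop("need at least 2 participants in each class")
  }
  feat_cols <- setdiff(names(participants),
                       c("participant_id", "fall_risk"))
  x <- participants[feat_cols]
  n <- nrow(x)
  pred <- factor(rep(NA, n), levels = levels(y))
  fold_features <- vector("list", n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    sel <- feat_cols
    if (use_cfs) {
      res <- suppressWarnings(cfs_select(xtr, ytr == "fall_risk"))
      if (length(res$selected) > 0) sel <- res$selected
    }
    fold_features[[i]] <- sel
    set.seed(as.integer(seed) + i)
    rf <- randomForest::randomForest(
      x = xtr[, sel, drop = FALSE], y = ytr,
      ntree = num_trees, mtry = max(1L, floor(sqrt(length(sel)))))
    pred[i] <- predict(rf, x[i, sel, drop = FALSE])
  }
  cm <- confusion_matrix(
    tn = sum(y == "no_fall_risk" & pred == "no_fall_risk"),
    fp = sum(y == "no_fall_risk" & pred == "fall_risk"),
    fn = sum(y == "fall_risk" & pred == "no_fall_risk"),
    tp = sum(y == "fall_risk" & pred == "fall_risk"))
  met <- confusion_metrics(cm)
  structure(list(
    confusion = cm,
    accuracy = met$accuracy, sensitivity = met$sensitivity,
    specificity = met$specificity,
    accuracy_pct = met$accuracy_pct,
    sensitivity_pct = met$sensitivity_pct,
    specificity_pct = met$specificity_pct,
    predictions = as.character(pred),
    fold_features = fold_features,
    seed = as.integer(seed),
    config = list(num_trees = as.integer(num_trees), use_cfs = use_cfs)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cm <- x$confusion
  cat("<classification_report>\n")
  cat(sprintf("  confusion (rows actual, cols predicted):\n"))
  cat(sprintf("                 no_fall_risk fall_risk\n"))
  cat(sprintf("  no_fall_risk   %12d %9d\n", cm[["tn"]], cm[["fp"]]))
  cat(sprintf("  fall_risk      %12d %9d\n", cm[["fn"]], cm[["tp"]]))
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$accuracy_pct, x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}
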