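#' Feature-subsampling rule: half the square root of N
#'
#' Number of candidate features tried at each tree split: `max(1,
#' round(0.5 * sqrt(N)))` with halves rounded away from zero, where `N` is the
#' number of features currently in play.
#'
#' @param n Number of features (must be >= 1).
#' @return Integer mtry value, clamped to `[1, n]`.
#' @examples
#' mtry_rule(10000) # 50
#' @export
mtry_rule <- function(n) {
  if (any(!is.finite(n)) || any(n < 1)) abort("`n` must be >= 1.")
  as.integer(pmin(n, pmax(1, round_half_away(0.5 * sqrt(n)))))
}

#' Random-forest configuration
#'
#' Hyperparameters of each forest in the reduction: 5000 trees, mtry of half
#' the square root of the current feature count, nodes split down to a minimum
#' of two samples (trees grown essentially to purity), and the smaller class
#' upweighted to the size of the larger one.
#'
#' @param n_trees Trees per forest.
#' @param mtry Function mapping feature count to mtry (default [mtry_rule()]).
#' @param min_samples_split Minimum samples an internal node needs to split.
#' @param importance Split-importance measure: `"impurity"` (mean decrease in
#'   Gini impurity; deterministic given the forest) or `"permutation"`.
#' @param seed Integer seed making fits reproducible.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 5000, mtry = mtry_rule, min_samples_split = 2,
                      importance = c("impurity", "permutation"), seed = 1) {
  if (n_trees < 1) abort("`n_trees` must be >= 1.")
  if (min_samples_split < 2) abort("`min_samples_split` must be >= 2.")
  structure(
    list(n_trees = as.integer(n_trees), mtry = mtry,
         min_samples_split = as.integer(min_samples_split),
         importance = match.arg(importance), seed = as.integer(seed)),
    class = "rf_config"
  )
}

# long intensity tibble -> samples x features matrix + aligned class labels.
# Residual missing values are imputed with the peptide's within-cohort median
# (falling back to the overall median); all-missing features are dropped.
build_feature_matrix <- function(data, design) {
  stopifnot(all(c("peptide_id", "sample_id", "value") %in% names(data)))
  sdesign <- subject_design(design)
  data <- data |> inner_join(sdesign, by = "sample_id")
  if (length(unique(data$class_label)) < 2) {
    abort("both classes must be present in the data.")
  }
  data$feature <- if ("channel" %in% names(data)) {
    paste(data$peptide_id, data$channel, sep = "|")
  } else {
    data$peptide_id
  }
  med_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else median(x)
  }
  data <- data |>
    mutate(cohort_med = med_na(.data$value), .by = c("feature", "class_label")) |>
    mutate(all_med = med_na(.data$value), .by = "feature") |>
    mutate(value = coalesce(.data$value, .data$cohort_med, .data$all_med)) |>
    filter(!is.na(.data$value))
  wide <- data |>
    select("sample_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  x <- as.matrix(wide[, -1, drop = FALSE])
  rownames(x) <- wide$sample_id
  keep <- colSums(is.na(x)) == 0
  x <- x[, keep, drop = FALSE]
  y <- factor(sdesign$class_label[match(rownames(x), sdesign$sample_id)],
              levels = c("control", "case"))
  if (any(is.na(y))) abort("some samples in the matrix are absent from the design.")
  list(x = x, y = y)
}

#' Fit one random forest with OOB evaluation
#'
#' Grows `config$n_trees` classification trees on bootstrap resamples (with
#' replacement) of the samples, with per-sample weights upweighting the smaller
#' class to the size of the larger, and evaluates by out-of-bag prediction.
#' The forest itself is fitted with \pkg{ranger}.
#'
#' @param data Long intensity tibble (`peptide_id`, optional `channel`,
#'   `sample_id`, `value`), typically the output of [preprocess_scans()].
#' @param design Cohort design labelling every sample.
#' @param config An [rf_config()].
#' @return An object of class `ims_rf`: list with `importance` (tibble
#'   `feature`, `peptide_id`, `channel`, `importance`, sorted decreasing, ties
#'   broken by feature id), `oob` (tibble `sample_id`, `actual`, `predicted`),
#'   `oob_score` (overall percent correct on OOB predictions), `n_features`,
#'   `config`.
#' @export
fit_rf <- function(data, design, config = rf_config()) {
  fm <- build_feature_matrix(data, design)
  fit_rf_matrix(fm$x, fm$y, config)
}

fit_rf_matrix <- function(x, y, config) {
  stopifnot(inherits(config, "rf_config"))
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present.")
  tab <- table(y)
  wts <- as.numeric(max(tab) / tab[y])
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    mtry = config$mtry(ncol(x)),
    min.node.size = config$min_samples_split - 1L,
    importance = config$importance,
    case.weights = wts,
    replace = TRUE,
    seed = config$seed,
    num.threads = 1
  )
  imp <- fit$variable.importance
  imp_tbl <- tibble(feature = names(imp), importance = as.numeric(imp)) |>
    arrange(desc(.data$importance), .data$feature) |>
    mutate(
      peptide_id = sub("\\|[^|]*$", "", .data$feature),
      channel = ifelse(grepl("|", .data$feature, fixed = TRUE),
                       sub("^.*\\|", "", .data$feature), NA_character_)
    ) |>
    select("feature", "peptide_id", "channel", "importance")
  pred <- fit$predictions
  ok <- !is.na(pred)
  oob <- tibble(sample_id = rownames(x), actual = as.character(y),
                predicted = as.character(pred))
  structure(
    list(
      importance = imp_tbl,
      oob = oob,
      oob_score = 100 * mean(pred[ok] == y[ok]),
      n_features = ncol(x),
      config = config
    ),
    class = "ims_rf"
  )
}

#' Progressive random-forest reduction to a peptide signature
#'
#' Reduces the feature set in the fixed schedule: fit on all features and keep
#' the top 30% by importance; refit and keep the top 40% of those; then iterate,
#' each round removing the least-important `drop_fraction` of features (at
#' least one) and refitting, until the OOB score has not improved for
#' `patience` consecutive rounds. The returned signature is the smallest
#' feature set that achieved the best OOB score anywhere in the trace.
#' Retention counts are `ceiling(fraction * current N)`.
#'
#' @param data,design,config As in [fit_rf()].
#' @param keep_fractions Fractions kept by the first screening steps
#'   (default `c(0.30, 0.40)`).
#' @param drop_fraction Fraction removed per iteration in the final phase.
#' @param patience Consecutive non-improving iterations tolerated before
#'   stopping.
#' @return An object of class `ims_signature`: list with `selected` (tibble of
#'   the signature's features with `raw_importance` and `relative_importance`,
#'   top feature scaled to 100), `oob`, `oob_score`, `confusion` (2x2 actual x
#'   predicted count matrix), `metrics` (see [confusion_metrics()]), `trace`
#'   (tibble `iteration`, `phase`, `n_features`, `oob_score`), `config`.
#' @export
stepwise_reduce <- function(data, design, config = rf_config(),
                            keep_fractions = c(0.30, 0.40),
                            drop_fraction = 0.10, patience = 3) {
  if (any(keep_fractions <= 0 | keep_fractions > 1)) {
    abort("`keep_fractions` must lie in (0, 1].")
  }
  if (drop_fraction <= 0 || drop_fraction > 1) {
    abort("`drop_fraction` must lie in (0, 1].")
  }
  fm <- build_feature_matrix(data, design)
  x <- fm$x
  y <- fm$y

  fits <- list()
  trace <- list()
  features <- colnames(x)
  iter <- 0L
  phases <- c(sprintf("screen_%d", seq_along(keep_fractions)))

  fit_current <- function(features, phase) {
    iter <<- iter + 1L
    cfg <- config
    cfg$seed <- config$seed + iter - 1L
    fit <- fit_rf_matrix(x[, features, drop = FALSE], y, cfg)
    fits[[iter]] <<- fit
    trace[[iter]] <<- tibble(iteration = iter, phase = phase,
                             n_features = length(features),
                             oob_score = fit$oob_score)
    fit
  }

  fit <- fit_current(features, "initial")
  for (k in seq_along(keep_fractions)) {
    n_keep <- ceiling(keep_fractions[k] * length(features))
    features <- fit$importance$feature[seq_len(n_keep)]
    fit <- fit_current(features, phases[k])
  }

  best <- max(vapply(trace, function(t) t$oob_score, 0))
  stall <- 0L
  while (stall < patience && length(features) > 1) {
    n_drop <- max(1L, floor(drop_fraction * length(features)))
    features <- fit$importance$feature[seq_len(length(features) - n_drop)]
    fit <- fit_current(features, "iterative")
    if (fit$oob_score > best) {
      best <- fit$oob_score
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }

  trace <- bind_rows(trace)
  best_score <- max(trace$oob_score)
  pick <- trace |>
    filter(.data$oob_score == best_score) |>
    slice_min(.data$n_features, n = 1, with_ties = FALSE)
  chosen <- fits[[pick$iteration]]

  selected <- chosen$importance |>
    mutate(raw_importance = .data$importance,
           relative_importance = relative_importance(.data$importance)) |>
    select("feature", "peptide_id", "channel", "raw_importance",
           "relative_importance")
  confusion <- confusion_counts(chosen$oob$actual, chosen$oob$predicted)
  structure(
    list(
      selected = selected,
      oob = chosen$oob,
      oob_score = chosen$oob_score,
      confusion = confusion,
      metrics = confusion_metrics(confusion),
      trace = trace,
      config = config
    ),
    class = "ims_signature"
  )
}

#' Scale importances relative to the top feature
#'
#' The most important feature is assigned 100 and the rest are scaled
#' proportionally: `100 * raw / max(raw)`.
#'
#' @param raw Non-negative importance values, not all zero.
#' @return Numeric vector with maximum 100.
#' @export
relative_importance <- function(raw) {
  if (length(raw) == 0) abort("`raw` must be nonempty.")
  m <- max(raw, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) abort("all importances are zero; cannot scale.")
  100 * raw / m
}

# 2x2 actual x predicted count matrix with fixed class order
confusion_counts <- function(actual, predicted,
                             levels = c("control", "case")) {
  ok <- !is.na(predicted)
  table(
    actual = factor(actual[ok], levels = levels),
    predicted = factor(predicted[ok], levels = levels)
  )
}

#' Classification metric panel from a confusion table
#'
#' Computes the immunosignature reporting panel: per-class percent correct,
#' their average, overall percent correct, and specificity / sensitivity
#' (recall) / precision / F1 for the chosen positive class. The default
#' positive class is `"control"`, the convention under which a published
#' 41/1-vs-3/39 confusion table yields specificity 92.86, recall 97.62,
#' precision 93.18 and F1 95.35 simultaneously.
#'
#' @param x Either a 2x2 matrix/table of counts (rows = actual, columns =
#'   predicted, with class dimnames) or a data frame with `actual` and
#'   `predicted` columns.
#' @param positive_class Class treated as positive for recall/precision/F1.
#' @return A one-row tibble: `positive_class`, `n`, `overall_pct`,
#'   `average_class_pct`, `sensitivity_pct`, `specificity_pct`,
#'   `precision_pct`, `f1_pct`, and `per_class_pct` (named-list column of
#'   per-class percent correct). All values are percents in [0, 100].
#' @examples
#' m <- matrix(c(41, 3, 1, 39), 2,
#'             dimnames = list(c("control", "case"), c("control", "case")))
#' confusion_metrics(m)
#' @export
confusion_metrics <- function(x, positive_class = "control") {
  if (is.data.frame(x)) {
    stopifnot(all(c("actual", "predicted") %in% names(x)))
    lv <- unique(c(positive_class, sort(unique(as.character(x$actual)))))
    x <- confusion_counts(x$actual, x$predicted, levels = lv)
  }
  x <- as.matrix(x)
  if (nrow(x) != 2 || ncol(x) != 2) abort("confusion table must be 2x2.")
  classes <- rownames(x)
  if (is.null(classes) || !identical(sort(classes), sort(colnames(x)))) {
    abort("confusion table needs matching actual/predicted class dimnames.")
  }
  x <- x[, classes, drop = FALSE]
  if (!positive_class %in% classes) {
    abort(sprintf("positive_class '%s' not among classes (%s).",
                  positive_class, paste(classes, collapse = ", ")))
  }
  total <- sum(x)
  if (total <= 0) abort("confusion table is empty.")
  row_sums <- rowSums(x)
  if (any(row_sums == 0)) {
    abort(sprintf("class '%s' has no observations; metrics undefined.",
                  classes[which(row_sums == 0)[1]]))
  }
  per_class <- 100 * diag(x) / row_sums
  pos <- positive_class
  neg <- setdiff(classes, pos)
  tp <- x[pos, pos]
  fn <- x[pos, neg]
  fp <- x[neg, pos]
  tn <- x[neg, neg]
  recall <- 100 * tp / (tp + fn)
  precision <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  specificity <- 100 * tn / (tn + fp)
  f1 <- if (is.na(precision) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(
    positive_class = pos,
    n = as.integer(total),
    overall_pct = 100 * sum(diag(x)) / total,
    average_class_pct = mean(per_class),
    sensitivity_pct = recall,
    specificity_pct = specificity,
    precision_pct = precision,
    f1_pct = f1,
    per_class_pct = list(setNames(as.numeric(per_class), classes))
  )
}

#' @export
print.ims_signature <- function(x, ...) {
  cat(sprintf("Immunosignature: %d features (%d peptides), OOB overall %.2f%%\n",
              nrow(x$selected), length(unique(x$selected$peptide_id)),
              x$oob_score))
  cat(sprintf("Reduction trace: %d fits, %d -> %d features\n",
              nrow(x$trace), x$trace$n_features[1],
              nrow(x$selected)))
  m <- x$metrics
  cat(sprintf(
    "Specificity %.2f%% | Sensitivity %.2f%% | Precision %.2f%% | F1 %.2f%%\n",
    m$specificity_pct, m$sensitivity_pct, m$precision_pct, m$f1_pct))
  invisible(x)
}

#' @export
tidy.ims_signature <- function(x, ...) x$selected

#' @export
glance.ims_signature <- function(x, ...) {
  bind_cols(
    tibble(n_features = nrow(x$selected),
           n_peptides = length(unique(x$selected$peptide_id)),
           oob_score = x$oob_score,
           n_fits = nrow(x$trace)),
    x$metrics |> select(-"per_class_pct", -"n")
  )
}

#' @export
tidy.ims_rf <- function(x, ...) x$importance

#' @export
glance.ims_rf <- function(x, ...) {
  tibble(n_features = x$n_features, oob_score = x$oob_score,
         n_trees = x$config$n_trees)
}

#' Plot a fitted signature
#'
#' `type = "importance"` draws the relative-importance bar panel of the
#' signature's top features (top feature = 100); `type = "trace"` draws the
#' OOB score along the reduction trace against the number of features kept.
#'
#' @param object An `ims_signature`.
#' @param type Plot type.
#' @param top_n Features shown in the importance panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ims_signature <- function(object, type = c("importance", "trace"),
                                   top_n = 25, ...) {
  type <- match.arg(type)
  if (type == "importance") {
    d <- object$selected |>
      slice_head(n = top_n) |>
      mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$relative_importance,
                                    y = .data$feature)) +
      ggplot2::geom_col(fill = "grey30") +
      ggplot2::labs(x = "Relative importance (top feature = 100)",
                    y = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$trace,
                    ggplot2::aes(x = .data$n_features, y = .data$oob_score)) +
      ggplot2::geom_line(colour = "grey55") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$phase)) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "Features kept (log scale)",
                    y = "OOB overall % correct", colour = "Phase") +
      ggplot2::theme_minimal()
  }
}
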