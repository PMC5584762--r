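#' Stratified cross-validation fold assignment
#'
#' Assigns samples to `n_folds` folds preserving the class ratio: within each
#' class, a seeded shuffle is dealt round-robin across folds, so per-fold
#' class counts differ by at most one from an even split. The assignment is
#' deterministic for a fixed seed and is meant to be reused across every
#' feature-subset evaluation of an IFS sweep, so all points on the IFS curve
#' are measured on the same partition.
#'
#' @param labels Label vector (factor/character/logical) or a label tibble
#'   with a `label` column.
#' @param n_folds Number of folds; default 10.
#' @param seed Integer seed for the shuffle.
#' @return An integer vector of fold indices in `1..n_folds` with attributes
#'   `seed` and `n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1) {
  if (is.data.frame(labels)) labels <- labels$label
  y <- as.character(labels)
  counts <- table(y)
  if (any(counts < n_folds)) {
    abort(paste0(
      "class \"", names(counts)[which.min(counts)], "\" has fewer members (",
      min(counts), ") than folds (", n_folds, ")"
    ))
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(fold, seed = seed, n_folds = n_folds)
}

#' Classifier specification
#'
#' A pluggable contract for the classifier driven by cross-validation and
#' IFS: `fit(X, y)` trains on a numeric matrix and two-level factor, and
#' `predict(fit, X)` returns a list with `label` (factor) and `decision`
#' (numeric score, larger meaning more positive). When `standardize` is TRUE
#' the caller standardizes columns to zero mean / unit variance using training
#' data only before `fit` and `predict` see them.
#'
#' @param name Identifier for printing.
#' @param fit,predict Functions implementing the contract.
#' @param standardize Should features be standardized on training folds?
#' @return An `ess_classifier` list.
#' @export
classifier_spec <- function(name, fit, predict, standardize = TRUE) {
  structure(
    list(name = name, fit = fit, predict = predict,
         standardize = standardize),
    class = "ess_classifier"
  )
}

#' Linear support-vector machine classifier (default)
#'
#' Emulates an SMO-trained SVM run with default parameters: linear kernel,
#' complexity constant `cost = 1`, and features standardized to zero mean and
#' unit variance on the training folds (the normalisation such default
#' configurations apply). Backed by [e1071::svm()] (libsvm, an SMO-family
#' decomposition solver).
#'
#' @param cost Soft-margin complexity constant.
#' @param standardize Standardize features on training folds (default TRUE).
#' @return An `ess_classifier` for use with [cross_validate()], [run_ifs()]
#'   and [train_final()].
#' @export
svm_linear_spec <- function(cost = 1, standardize = TRUE) {
  classifier_spec(
    name = sprintf("svm_linear(cost=%g)", cost),
    fit = function(X, y) {
      e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
    },
    predict = function(fit, X) {
      pr <- predict(fit, X, decision.values = TRUE)
      dec <- drop(attr(pr, "decision.values"))
      # libsvm orients the decision value toward the first training class;
      # flip so larger always means "positive"
      if (!grepl("^positive", colnames(attr(pr, "decision.values"))[1])) {
        dec <- -dec
      }
      list(label = pr, decision = dec)
    },
    standardize = standardize
  )
}

#' @export
print.ess_classifier <- function(x, ...) {
  cat("<ess_classifier>", x$name,
      if (x$standardize) "(standardized)" else "", "\n")
  invisible(x)
}

# Column-wise center/scale estimated on training rows; zero-variance columns
# get unit scale so they pass through as constant zeros.
scale_params <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_scale <- function(X, p) {
  sweep(sweep(X, 2, p$center, "-"), 2, p$scale, "/")
}

#' Cross-validated evaluation of a feature subset
#'
#' Trains the classifier on each training split and pools the held-out
#' confusion counts over all folds (micro-averaging), yielding a single
#' SN/SP/ACC/MCC per feature subset. Standardization parameters are estimated
#' on the training folds only. A training fold containing a single class is a
#' hard error, since the classifier contract is then void.
#'
#' @param features Feature tibble from [encode_genes()].
#' @param labels Labels (vector or label tibble joined on `gene`).
#' @param feature_subset Character vector of term ids (or integer column
#'   indices) naming the features to use; non-empty.
#' @param classifier An `ess_classifier`; default [svm_linear_spec()].
#' @param folds Fold assignment from [stratified_folds()]; default a 10-fold
#'   stratified split with `seed`.
#' @param seed Seed used only when `folds` is NULL.
#' @return A one-row tibble with pooled `TP`, `TN`, `FP`, `FN` and the derived
#'   `SN`, `SP`, `ACC`, `MCC`, `mcc_defined`.
#' @export
cross_validate <- function(features, labels, feature_subset,
                           classifier = svm_linear_spec(), folds = NULL,
                           seed = 1) {
  y <- factor(as.character(align_labels(features, labels)),
              levels = c("negative", "positive"))
  X <- feature_columns(features)
  X <- subset_columns(X, feature_subset)
  if (is.null(folds)) folds <- stratified_folds(y, seed = seed)
  pred <- cv_predict(X, y, classifier, folds)
  cc <- confusion_counts(y, pred$label, positive = "positive")
  compute_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
}

subset_columns <- function(X, feature_subset) {
  if (length(feature_subset) == 0L) abort("feature_subset must be non-empty")
  if (is.character(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(X))
    if (length(missing) > 0L) {
      abort(paste0("unknown feature: ", missing[1]))
    }
  }
  X[, feature_subset, drop = FALSE]
}

# Held-out predictions for every sample under a fixed fold assignment.
cv_predict <- function(X, y, classifier, folds) {
  n_folds <- max(folds)
  label <- factor(rep(NA_character_, length(y)), levels = levels(y))
  decision <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L) {
      abort(paste0("degenerate training split for fold ", f,
                   ": a single class remains"))
    }
    Xte <- X[test, , drop = FALSE]
    if (isTRUE(classifier$standardize)) {
      p <- scale_params(Xtr)
      Xtr <- apply_scale(Xtr, p)
      Xte <- apply_scale(Xte, p)
    }
    fit <- classifier$fit(Xtr, ytr)
    out <- classifier$predict(fit, Xte)
    label[test] <- out$label
    decision[test] <- out$decision
  }
  list(label = label, decision = decision)
}

#' Incremental feature selection over an mRMR ranking
#'
#' Evaluates nested prefixes of the mRMR feature list: for every `k` in
#' `seq(k_min, k_max, by = step)` the top-`k` features are assessed by
#' cross-validation with the supplied classifier, all prefixes sharing one
#' stratified fold assignment. The optimal feature count is the smallest `k`
#' attaining the maximum MCC across the sweep (parsimony on ties). At the
#' defaults `k = 5..500` in steps of 1, the sweep produces 496 records.
#'
#' @inheritParams cross_validate
#' @param ranking An `ess_mrmr` from [mrmr_rank()] (or a character vector of
#'   term ids already in rank order).
#' @param k_min,k_max,step Prefix sweep; `k_max` must not exceed the number
#'   of ranked features.
#' @return An `ess_ifs` object: list with `records` (tibble `k`, `TP`, `TN`,
#'   `FP`, `FN`, `SN`, `SP`, `ACC`, `MCC`, `mcc_defined`), `optimal_k`,
#'   `folds`, `classifier`, `feature_order`. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
run_ifs <- function(features, labels, ranking, k_min = 5, k_max = 500,
                    step = 1, classifier = svm_linear_spec(), folds = NULL,
                    seed = 1) {
  order_ids <- if (inherits(ranking, "ess_mrmr")) {
    ranking$ranking$term_id
  } else {
    as.character(ranking)
  }
  if (k_max > length(order_ids)) {
    abort(paste0("k_max (", k_max, ") exceeds the number of ranked features (",
                 length(order_ids), ")"))
  }
  if (k_min < 1L) abort("k_min must be >= 1")
  ks <- seq.int(k_min, k_max, by = step)
  if (length(ks) == 0L) abort("empty feature-count range")

  y <- factor(as.character(align_labels(features, labels)),
              levels = c("negative", "positive"))
  X <- feature_columns(features)
  X <- X[, order_ids[seq_len(k_max)], drop = FALSE]
  if (is.null(folds)) folds <- stratified_folds(y, seed = seed)
  n_folds <- max(folds)

  # Pre-standardize per fold on the k_max-column block once: column-wise
  # parameters are independent, so subsetting columns afterwards is identical
  # to standardizing each prefix separately.
  splits <- lapply(seq_len(n_folds), function(f) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L) {
      abort(paste0("degenerate training split for fold ", f))
    }
    Xte <- X[test, , drop = FALSE]
    if (isTRUE(classifier$standardize)) {
      p <- scale_params(Xtr)
      Xtr <- apply_scale(Xtr, p)
      Xte <- apply_scale(Xte, p)
    }
    list(Xtr = Xtr, ytr = ytr, Xte = Xte, test = which(test))
  })

  records <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (sp in splits) {
      fit <- classifier$fit(sp$Xtr[, seq_len(k), drop = FALSE], sp$ytr)
      out <- classifier$predict(fit, sp$Xte[, seq_len(k), drop = FALSE])
      pred[sp$test] <- out$label
    }
    cc <- confusion_counts(y, pred, positive = "positive")
    records[[i]] <- dplyr::bind_cols(
      tibble(k = k),
      compute_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
    )
  }
  records <- dplyr::bind_rows(records)
  optimal_k <- records$k[which.max(records$MCC)]  # first max = smallest k
  structure(
    list(
      records = records,
      optimal_k = optimal_k,
      folds = folds,
      classifier = classifier,
      feature_order = order_ids
    ),
    class = "ess_ifs"
  )
}

#' @export
print.ess_ifs <- function(x, ...) {
  best <- x$records[x$records$k == x$optimal_k, ]
  cat("<ess_ifs> ", nrow(x$records), " feature-count records; optimal k = ",
      x$optimal_k, " (MCC = ", sprintf("%.3f", best$MCC), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.ess_ifs <- function(x, ...) x$records

#' @export
glance.ess_ifs <- function(x, ...) {
  best <- x$records[x$records$k == x$optimal_k, ]
  tibble(
    n_records = nrow(x$records),
    optimal_k = x$optimal_k,
    SN = best$SN, SP = best$SP, ACC = best$ACC, MCC = best$MCC
  )
}

#' IFS curve
#'
#' Plots cross-validated performance against the number of top-ranked
#' features — the curve used to locate the optimal feature count; the
#' maximum-MCC point is marked.
#'
#' @param object An `ess_ifs`.
#' @param metrics Which metrics to draw; MCC only by default.
#' @param ... Unused.
#' @export
autoplot.ess_ifs <- function(object, metrics = "MCC", ...) {
  metrics <- match.arg(metrics, c("MCC", "SN", "SP", "ACC"),
                       several.ok = TRUE)
  df <- object$records %>%
    select("k", dplyr::all_of(metrics)) %>%
    tidyr::pivot_longer(-"k", names_to = "metric", values_to = "value")
  best <- object$records[object$records$k == object$optimal_k, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = best$k, y = best$MCC,
                      colour = "red", size = 2) +
    ggplot2::labs(
      x = "number of top mRMR features",
      y = "cross-validated value",
      colour = NULL,
      title = sprintf("IFS curve (optimal k = %d, MCC = %.3f)",
                      object$optimal_k, best$MCC)
    ) +
    ggplot2::theme_minimal()
}

#' Train the final prediction model on all labeled genes
#'
#' Fits the classifier on every labeled sample using a chosen feature subset
#' (typically the first `optimal_k` features of the IFS result), storing the
#' feature list and the full-data standardization parameters so unlabeled
#' genes can be encoded and scored identically later.
#'
#' @inheritParams cross_validate
#' @param feature_subset Character vector of term ids (e.g.
#'   `head(ifs$feature_order, ifs$optimal_k)`).
#' @return An `ess_model`: list with `fit`, `features`, `center`, `scale`,
#'   `classifier`, `n_pos`, `n_neg`.
#' @export
train_final <- function(features, labels, feature_subset,
                        classifier = svm_linear_spec()) {
  y <- factor(as.character(align_labels(features, labels)),
              levels = c("negative", "positive"))
  X <- feature_columns(features)
  X <- subset_columns(X, feature_subset)
  p <- if (isTRUE(classifier$standardize)) scale_params(X) else {
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  }
  fit <- classifier$fit(apply_scale(X, p), y)
  structure(
    list(
      fit = fit,
      features = colnames(X),
      center = p$center,
      scale = p$scale,
      classifier = classifier,
      n_pos = sum(y == "positive"),
      n_neg = sum(y == "negative")
    ),
    class = "ess_model"
  )
}

#' @export
print.ess_model <- function(x, ...) {
  cat("<ess_model> ", x$classifier$name, " on ", length(x$features),
      " features (", x$n_pos, " positive / ", x$n_neg,
      " negative training genes)\n", sep = "")
  invisible(x)
}

#' Predict labels for encoded genes
#'
#' Scores genes encoded with [encode_genes()] against the same annotation;
#' the model's stored feature order and standardization are applied, so the
#' new matrix must contain every model feature column.
#'
#' @param object An `ess_model` from [train_final()].
#' @param new_features Feature tibble of the genes to score.
#' @param ... Unused.
#' @return A tibble `gene`, `label` (factor `negative`/`positive`),
#'   `decision` (signed decision value, larger = more essential-like);
#'   zero rows for an empty input.
#' @export
predict.ess_model <- function(object, new_features, ...) {
  genes <- if ("gene" %in% names(new_features)) new_features$gene else {
    as.character(seq_len(nrow(new_features)))
  }
  if (nrow(new_features) == 0L) {
    return(tibble(
      gene = character(),
      label = factor(character(), levels = c("negative", "positive")),
      decision = numeric()
    ))
  }
  X <- feature_columns(new_features)
  missing <- setdiff(object$features, colnames(X))
  if (length(missing) > 0L) {
    abort(paste0("new data lacks model feature ", missing[1]))
  }
  X <- X[, object$features, drop = FALSE]
  X <- apply_scale(X, list(center = object$center, scale = object$scale))
  out <- object$classifier$predict(object$fit, X)
  tibble(gene = genes, label = out$label, decision = out$decision)
}

#' @export
glance.ess_model <- function(x, ...) {
  tibble(
    classifier = x$classifier$name,
    n_features = length(x$features),
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}
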