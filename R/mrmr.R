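#' Discretize a numeric feature into three level codes
#'
#' mRMR's mutual-information estimates are computed on discretized features,
#' following the three-state convention of the mRMR literature: values are cut
#' at mean - sigma and mean + sigma (population standard deviation). Values at
#' or below the lower edge code 0, values at or above the upper edge code 2,
#' and strictly interior values code 1, so a symmetric two-valued feature
#' keeps its two states rather than collapsing. A constant feature (sigma = 0)
#' maps to all-1 codes.
#'
#' @param values Non-empty numeric vector.
#' @return Integer vector of codes in `{0, 1, 2}` with attribute `edges`
#'   (the numeric cut points `c(low, high)`).
#' @export
discretize_feature <- function(values) {
  stopifnot(length(values) > 0L, is.numeric(values))
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    codes <- rep(1L, length(values))
    return(structure(codes, edges = c(mu, mu)))
  }
  lo <- mu - sigma
  hi <- mu + sigma
  codes <- rep(1L, length(values))
  codes[values <= lo] <- 0L
  codes[values >= hi] <- 2L
  structure(codes, edges = c(lo, hi))
}

#' Mutual information of two discrete variables
#'
#' Plug-in estimator on the empirical joint distribution:
#' `I(x, y) = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )`, with the convention
#' `0 log 0 = 0`. Inputs may be integer codes, factors, or any discrete
#' vectors of equal length; the result is in bits and non-negative.
#'
#' @param a,b Equal-length discrete vectors.
#' @param base Logarithm base; 2 (bits) by default. Rankings built on MI are
#'   invariant to the base since it rescales all values by one constant.
#' @return Non-negative mutual information.
#' @export
mutual_information <- function(a, b, base = 2) {
  if (length(a) != length(b)) abort("length mismatch between a and b")
  tab <- table(a, b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  expected <- outer(px, py)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / expected[nz], base = base))
  max(mi, 0)
}

# MI (bits) between one code vector `s` and every column of the code matrix
# `codes` (n x p integers in 0..2), vectorised: the 3x3 joint counts for all p
# features come from 9 vector-matrix products against the level indicators.
mi_vs_all <- function(s, ind, col_counts, n) {
  # ind: list of 3 indicator matrices (n x p) for codes 0,1,2
  # col_counts: 3 x p marginal counts of the columns
  mi <- numeric(ncol(ind[[1]]))
  for (x in 0:2) {
    vx <- as.numeric(s == x)
    nx <- sum(vx)
    if (nx == 0) next
    for (y in 1:3) {
      cxy <- as.numeric(vx %*% ind[[y]])       # joint counts, length p
      ny <- col_counts[y, ]
      pos <- cxy > 0
      mi[pos] <- mi[pos] +
        (cxy[pos] / n) * log2(cxy[pos] * n / (nx * ny[pos]))
    }
  }
  pmax(mi, 0)
}

#' Rank features by maximum relevance, minimum redundancy (mRMR)
#'
#' Greedy mutual-information feature ranking. Relevance of a feature is its MI
#' with the class label, `D = I(f, c)`; redundancy is its mean MI with the
#' already-selected features, `R = mean I(f, f_i)` (zero while none are
#' selected). At every step the unselected feature maximising `D - R` is
#' appended, so the first pick is the most relevant feature, and iterating to
#' exhaustion yields the mRMR list — a permutation of all features. The MaxRel
#' list, features sorted by decreasing `D` alone, is returned alongside. Ties
#' break toward the lower feature index, making both lists deterministic.
#'
#' Features are discretized with [discretize_feature()] before MI estimation;
#' the binary class label is used raw.
#'
#' @param features Feature tibble from [encode_genes()] (or any data frame of
#'   numeric feature columns, with an optional `gene` identifier column).
#' @param labels Class labels: a factor/character/logical vector aligned with
#'   the rows, or a label tibble with `gene` and `label` columns to be joined
#'   on `gene`. Exactly two classes must be present.
#' @return An `ess_mrmr` object: list with `ranking` (tibble `rank`,
#'   `feature`, `term_id`, `namespace`, `relevance`, `redundancy`, `score`
#'   where `score = relevance - redundancy` at selection time), `maxrel`
#'   (tibble `rank`, `feature`, `term_id`, `relevance`), `n_features`,
#'   `n_samples`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
mrmr_rank <- function(features, labels) {
  info <- if (inherits(features, "ess_features")) feature_info(features) else NULL
  y <- align_labels(features, labels)
  X <- feature_columns(features)
  p <- ncol(X)
  n <- nrow(X)
  if (p < 1L) abort("no feature columns")
  if (n < 2L) abort("need at least two samples")
  if (length(unique(y)) != 2L) {
    abort("labels must contain exactly two classes")
  }

  codes <- matrix(0L, n, p)
  for (j in seq_len(p)) codes[, j] <- discretize_feature(X[, j])
  cls <- as.integer(factor(y)) - 1L

  ind <- lapply(0:2, function(v) (codes == v) * 1)
  col_counts <- rbind(colSums(ind[[1]]), colSums(ind[[2]]), colSums(ind[[3]]))

  relevance <- mi_vs_all(cls, ind, col_counts, n)

  selected <- integer(p)
  rel_sel <- red_sel <- numeric(p)
  sum_red <- numeric(p)       # running sum of MI to selected features
  remaining <- rep(TRUE, p)
  for (step in seq_len(p)) {
    r <- if (step == 1L) numeric(p) else sum_red / (step - 1L)
    score <- relevance - r
    score[!remaining] <- -Inf
    pick <- which.max(score)  # which.max takes the lowest index on ties
    selected[step] <- pick
    rel_sel[step] <- relevance[pick]
    red_sel[step] <- if (step == 1L) 0 else r[pick]
    remaining[pick] <- FALSE
    if (step < p) {
      sum_red <- sum_red + mi_vs_all(codes[, pick], ind, col_counts, n)
    }
  }

  term_ids <- colnames(X)
  ns <- if (!is.null(info)) info$namespace[match(term_ids, info$term_id)] else {
    rep(NA_character_, p)
  }
  maxrel_order <- order(-relevance, seq_len(p))
  structure(
    list(
      ranking = tibble(
        rank = seq_len(p),
        feature = selected,
        term_id = term_ids[selected],
        namespace = ns[selected],
        relevance = rel_sel,
        redundancy = red_sel,
        score = rel_sel - red_sel
      ),
      maxrel = tibble(
        rank = seq_len(p),
        feature = maxrel_order,
        term_id = term_ids[maxrel_order],
        namespace = ns[maxrel_order],
        relevance = relevance[maxrel_order]
      ),
      n_features = p,
      n_samples = n
    ),
    class = "ess_mrmr"
  )
}

# Resolve labels into a vector aligned with the rows of `features`.
align_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    if (!"gene" %in% names(features)) {
      abort("features lack a `gene` column to join labels on")
    }
    idx <- match(features$gene, labels$gene)
    if (anyNA(idx)) {
      abort(paste0(
        "no label for gene ", features$gene[which(is.na(idx))[1]]
      ))
    }
    labels$label[idx]
  } else {
    if (length(labels) != nrow(features)) {
      abort("labels length does not match the number of rows")
    }
    labels
  }
}

# Numeric feature matrix (drops the `gene` id column).
feature_columns <- function(features) {
  df <- as.data.frame(features, check.names = FALSE)
  df$gene <- NULL
  as.matrix(df)
}

#' @export
print.ess_mrmr <- function(x, ...) {
  cat("<ess_mrmr> ", x$n_features, " features ranked on ",
      x$n_samples, " samples\n", sep = "")
  print(head(x$ranking, 5))
  invisible(x)
}

#' @export
tidy.ess_mrmr <- function(x, list = c("mrmr", "maxrel"), ...) {
  list <- arg_match(list)
  if (list == "mrmr") x$ranking else x$maxrel
}

#' @export
glance.ess_mrmr <- function(x, ...) {
  tibble(
    n_features = x$n_features,
    n_samples = x$n_samples,
    top_term = x$ranking$term_id[1],
    max_relevance = x$maxrel$relevance[1]
  )
}

#' @export
autoplot.ess_mrmr <- function(object, top = 50, ...) {
  df <- head(object$maxrel, top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$relevance)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(
      x = "MaxRel rank",
      y = "relevance I(f, class) [bits]",
      title = "Feature relevance (MaxRel list)"
    ) +
    ggplot2::theme_minimal()
}
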