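# Independent brute-force oracles used to pin the package's numerical
# routines. These re-derive every quantity from first principles (explicit
# enumeration, naive loops) and share no code with the implementation.

# Upper-tail hypergeometric probability by explicit enumeration of the sum
# p = sum_{k=m}^{n} C(M,k) C(N-M, n-k) / C(N,n); infeasible k contribute 0.
enum_hyper_tail <- function(m, M, n, N) {
  total <- choose(N, n)
  p <- 0
  for (k in seq.int(m, n)) {
    if (k > M) next
    if (n - k > N - M) next
    p <- p + choose(M, k) * choose(N - M, n - k) / total
  }
  p
}

# Naive plug-in mutual information over explicit level pairs.
naive_mi <- function(a, b, base = 2) {
  n <- length(a)
  mi <- 0
  for (x in unique(a)) {
    for (y in unique(b)) {
      pxy <- sum(a == x & b == y) / n
      if (pxy == 0) next
      px <- sum(a == x) / n
      py <- sum(b == y) / n
      mi <- mi + pxy * log(pxy / (px * py), base = base)
    }
  }
  mi
}

# The package's published discretization convention, restated independently:
# three states cut at mean +/- population sigma, boundaries to the outer
# states, constant vectors all-middle.
oracle_discretize <- function(x) {
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) return(rep(1L, length(x)))
  out <- rep(1L, length(x))
  out[x <= mu - sigma] <- 0L
  out[x >= mu + sigma] <- 2L
  out
}

# Brute-force mRMR: at every step re-derive D and R for every remaining
# feature from scratch with naive_mi and pick argmax(D - R), lowest index on
# ties. Returns the selection order and the MaxRel order.
brute_mrmr <- function(X, labels, base = 2) {
  p <- ncol(X)
  codes <- apply(X, 2, oracle_discretize)
  cls <- as.integer(factor(labels))
  D <- vapply(seq_len(p), function(j) naive_mi(codes[, j], cls, base), 0)
  selected <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining) > 0) {
    score <- vapply(remaining, function(j) {
      r <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) {
          naive_mi(codes[, j], codes[, s], base)
        }, 0))
      }
      D[j] - r
    }, 0)
    best <- remaining[which(score >= max(score) - 1e-12)]
    pick <- min(best)  # deterministic tie-break: lowest feature index
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  maxrel <- order(-D, seq_len(p))
  list(mrmr = selected, maxrel = maxrel, relevance = D)
}

# Step-by-step audit of an mRMR result against the naive oracle: at every
# greedy step, re-derive D and R from scratch for all remaining features and
# require the implementation's pick to attain the maximum D - R (up to fp
# noise; tie resolution between exactly equal scores is index-based and
# checked only through the reported diagnostics). Returns TRUE or a message.
check_mrmr_against_oracle <- function(rk, X, labels, tol = 1e-9) {
  p <- ncol(X)
  codes <- apply(X, 2, oracle_discretize)
  cls <- as.integer(factor(labels))
  D <- vapply(seq_len(p), function(j) naive_mi(codes[, j], cls), 0)
  # MaxRel: descending D, and reported relevance values correct
  if (max(abs(rk$maxrel$relevance - D[rk$maxrel$feature])) > tol) {
    return("maxrel relevance mismatch")
  }
  if (any(diff(D[rk$maxrel$feature]) > tol)) {
    return("maxrel order not descending in oracle relevance")
  }
  sel <- rk$ranking$feature
  for (t in seq_len(p)) {
    remaining <- setdiff(seq_len(p), sel[seq_len(t - 1)])
    score <- vapply(remaining, function(j) {
      r <- if (t == 1) 0 else {
        mean(vapply(sel[seq_len(t - 1)], function(s) {
          naive_mi(codes[, j], codes[, s])
        }, 0))
      }
      D[j] - r
    }, 0)
    pick_score <- score[match(sel[t], remaining)]
    if (pick_score < max(score) - tol) {
      return(sprintf("step %d pick is not an argmax of D - R", t))
    }
    if (abs(rk$ranking$score[t] - pick_score) > tol) {
      return(sprintf("step %d reported D - R mismatch", t))
    }
    if (abs(rk$ranking$relevance[t] - D[sel[t]]) > tol) {
      return(sprintf("step %d reported relevance mismatch", t))
    }
  }
  TRUE
}

# Small synthetic configuration reused by pipeline-level tests: large enough
# to carry recoverable signal, small enough to keep IFS sweeps fast.
small_config <- function(seed = 1, p_signal = 0.5) {
  synthetic_config(
    n_genes = 250, n_pos = 50, n_neg = 200,
    n_go_terms = 40, n_kegg_terms = 10,
    term_size_range = c(8, 16),
    n_informative_terms = 8,
    p_signal = p_signal, p_background = 0.01,
    seed = seed
  )
}

# Tiny deterministic network fixture used across io / enrichment tests.
tiny_network <- function() {
  as_network(tibble::tibble(
    from = c("gA", "gA", "gB", "gC"),
    to   = c("gB", "gC", "gC", "gD")
  ), nodes = c("gA", "gB", "gC", "gD", "gE"))
}
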