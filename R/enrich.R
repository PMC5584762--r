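#' Define the background gene universe
#'
#' The hypergeometric enrichment score draws without replacement from a finite
#' background of `N` genes. By default the universe is the union of the
#' network's nodes and every annotation member, which is the largest set on
#' which both neighbourhoods and term memberships are defined; `size` lets the
#' caller override `N` with an explicit total (e.g. an estimate of the number
#' of human genes) while the universe membership is still used to intersect
#' gene sets.
#'
#' @param network An `ess_network`.
#' @param gene_sets A gene-set tibble from [read_gene_sets()] (may be `NULL`).
#' @param size Optional integer override for `N`; must be at least the number
#'   of genes in the universe.
#' @return An `ess_background`: list with `universe` (character) and `N`.
#' @export
make_background <- function(network = NULL, gene_sets = NULL, size = NULL) {
  universe <- character()
  if (!is.null(network)) universe <- c(universe, network$nodes)
  if (!is.null(gene_sets) && nrow(gene_sets) > 0L) {
    universe <- c(universe, unlist(gene_sets$members, use.names = FALSE))
  }
  universe <- sort(unique(universe))
  N <- length(universe)
  if (!is.null(size)) {
    size <- as.integer(size)
    if (size < N) {
      abort(paste0(
        "background size (", size, ") smaller than the observed universe (",
        N, ")"
      ))
    }
    N <- size
  }
  if (N < 1L) abort("background universe is empty")
  structure(list(universe = universe, N = N), class = "ess_background")
}

#' @export
print.ess_background <- function(x, ...) {
  cat("<ess_background> N =", x$N,
      "(", length(x$universe), "named genes )\n")
  invisible(x)
}

#' Network neighbourhood of a gene
#'
#' The neighbourhood `G(g)` is the gene itself plus its direct interaction
#' partners, intersected with the background universe. A gene absent from the
#' network is its own (singleton) neighbourhood.
#'
#' @param network An `ess_network`.
#' @param gene A single gene identifier; must belong to the background.
#' @param background An `ess_background` from [make_background()].
#' @return Character vector of neighbourhood members (always contains `gene`).
#' @export
gene_neighborhood <- function(network, gene, background) {
  stopifnot(length(gene) == 1L)
  if (!gene %in% background$universe) {
    abort(paste0("gene ", gene, " is not in the background universe"))
  }
  if (gene %in% network$nodes) {
    nb <- names(igraph::neighbors(network$graph, gene))
  } else {
    nb <- character()
  }
  members <- intersect(unique(c(gene, nb)), background$universe)
  # gene itself is in the universe by the guard above
  members
}

# -log10 upper-tail hypergeometric probability, vectorised over terms.
# m = overlap, M = term size, n = neighbourhood size, N = universe size.
# p = P(X >= m) with X ~ Hypergeometric(N, M, n); m = 0 gives p = 1, score 0.
hyper_score <- function(m, M, n, N, cap = 320) {
  if (any(n > N) || any(M > N)) {
    abort("inconsistent background: neighbourhood or term larger than N")
  }
  p <- phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  s <- -log10(p)
  s[m == 0] <- 0          # full tail sums to 1 exactly
  pmin(pmax(s, 0), cap)   # clamp -0 and p-underflow
}

#' Hypergeometric enrichment score of a neighbourhood against a gene set
#'
#' Computes `-log10` of the upper-tail hypergeometric probability of observing
#' at least the realised overlap `m` between a gene's neighbourhood (size `n`)
#' and an annotation gene set (size `M`) in a universe of `N` genes:
#' `p = sum_{k=m}^{n} C(M,k) C(N-M, n-k) / C(N,n)`. The score is a feature
#' value, not a significance test: no multiple-testing adjustment is applied.
#' When `p` underflows to zero the score is clamped at `cap`.
#'
#' @param neighborhood Character vector of neighbourhood members (from
#'   [gene_neighborhood()]).
#' @param members Character vector of annotation-set members.
#' @param background An `ess_background`.
#' @param cap Upper clamp for the score; default 320, about the largest
#'   `-log10` representable in double precision.
#' @return A single non-negative score.
#' @examples
#' bg <- structure(list(universe = letters[1:10], N = 10L),
#'                 class = "ess_background")
#' enrichment_score(c("a", "b", "c"), c("a", "b", "d", "e"), bg)
#' # -log10(1/3) = 0.4771...
#' @export
enrichment_score <- function(neighborhood, members, background, cap = 320) {
  nbhd <- intersect(neighborhood, background$universe)
  mem <- intersect(members, background$universe)
  n <- length(nbhd)
  if (n < 1L) abort("empty neighbourhood")
  m <- length(intersect(nbhd, mem))
  hyper_score(m, length(mem), n, background$N, cap = cap)
}

new_features <- function(df, feature_info = NULL) {
  if (anyNA(df[-1])) {
    abort("feature matrix contains missing scores (row/header mismatch?)")
  }
  if (is.null(feature_info)) {
    feature_info <- tibble(
      term_id = setdiff(names(df), "gene"),
      term_name = NA_character_,
      namespace = NA_character_
    )
  } else {
    feature_info <- as_tibble(feature_info)[, c("term_id", "term_name", "namespace")]
    missing_terms <- setdiff(setdiff(names(df), "gene"), feature_info$term_id)
    if (length(missing_terms) > 0L) {
      abort(paste0("feature_info lacks term ", missing_terms[1]))
    }
    feature_info <- feature_info[
      match(setdiff(names(df), "gene"), feature_info$term_id), ]
  }
  structure(df, feature_info = feature_info,
            class = c("ess_features", class(tibble())))
}

#' Feature metadata of an encoded matrix
#'
#' @param x A feature tibble from [encode_genes()] or [read_matrix()].
#' @return Tibble with `term_id`, `term_name`, `namespace`, one row per
#'   feature column, in column order.
#' @export
feature_info <- function(x) {
  info <- attr(x, "feature_info")
  if (is.null(info)) {
    info <- tibble(
      term_id = setdiff(names(x), "gene"),
      term_name = NA_character_,
      namespace = NA_character_
    )
  }
  info
}

#' Encode genes as neighbourhood enrichment score vectors
#'
#' For every gene, computes the enrichment score of its network neighbourhood
#' against every annotation set, producing the genes-by-terms feature matrix.
#' Feature columns are ordered with all GO terms first and all KEGG pathways
#' last (the GO block keeps the input order of `gene_sets`), so a matrix over
#' the full annotation carries `n_GO + n_KEGG` columns per gene.
#'
#' @param network An `ess_network`.
#' @param genes Character vector of gene identifiers (rows, order preserved),
#'   or a label tibble with a `gene` column.
#' @param gene_sets Annotation tibble from [read_gene_sets()] (GO and KEGG
#'   sets may be concatenated with [dplyr::bind_rows()]).
#' @param background An `ess_background`; defaults to
#'   `make_background(network, gene_sets)`.
#' @param cap Score clamp passed to [enrichment_score()].
#' @return A feature tibble (class `ess_features`): column `gene` then one
#'   non-negative numeric column per term, with [feature_info()] attached.
#' @export
encode_genes <- function(network, genes, gene_sets, background = NULL,
                         cap = 320) {
  if (is.data.frame(genes)) genes <- genes$gene
  genes <- as.character(genes)
  if (anyDuplicated(genes)) abort("duplicate gene identifiers")
  if (is.null(background)) background <- make_background(network, gene_sets)

  # GO block first, then KEGG (feature-vector ordering contract)
  ns_order <- order(match(gene_sets$namespace,
                          c("GO-BP", "GO-CC", "GO-MF", "KEGG")))
  gene_sets <- gene_sets[ns_order, ]

  universe <- background$universe
  idx_of <- function(g) match(g, universe)
  p <- nrow(gene_sets)
  n_genes <- length(genes)

  # term membership as an index list over the universe
  term_idx <- lapply(gene_sets$members, function(m) {
    sort(idx_of(intersect(m, universe)))
  })
  M <- lengths(term_idx)
  # membership indicator matrix (universe x terms), sparse via logical list
  in_term <- matrix(FALSE, nrow = length(universe), ncol = p)
  for (j in seq_len(p)) in_term[term_idx[[j]], j] <- TRUE

  scores <- matrix(0, nrow = n_genes, ncol = p)
  for (i in seq_len(n_genes)) {
    nbhd <- gene_neighborhood(network, genes[i], background)
    rows <- idx_of(nbhd)
    n <- length(rows)
    m <- if (n == 1L) as.integer(in_term[rows, ]) else colSums(in_term[rows, , drop = FALSE])
    scores[i, ] <- hyper_score(m, M, n, background$N, cap = cap)
  }
  colnames(scores) <- gene_sets$term_id
  df <- as_tibble(as.data.frame(scores, check.names = FALSE))
  df <- dplyr::bind_cols(tibble(gene = genes), df)
  new_features(
    df,
    feature_info = gene_sets[, c("term_id", "term_name", "namespace")]
  )
}

#' Drop genes whose enrichment encoding is unavailable
#'
#' A labeled gene is kept only if it can be encoded: by default this means it
#' is present in the interaction network's node set (an isolated-but-present
#' gene still has a well-defined, if uninformative, singleton neighbourhood).
#' With `mode = "all_zero"` the stricter rule is applied: genes whose entire
#' encoded score row is zero are also dropped, which requires passing the
#' encoded `features`.
#'
#' @param labels A label tibble from [read_labels()].
#' @param network An `ess_network`.
#' @param mode `"absent"` (default) drops genes missing from the network;
#'   `"all_zero"` additionally drops genes with an all-zero feature row.
#' @param features Feature tibble, required for `mode = "all_zero"`.
#' @return List with `kept` (label tibble, input order preserved) and
#'   `dropped` (tibble `gene`, `label`, `reason`).
#' @export
filter_unencodable <- function(labels, network, mode = c("absent", "all_zero"),
                               features = NULL) {
  mode <- arg_match(mode)
  absent <- !labels$gene %in% network$nodes
  reason <- ifelse(absent, "absent_from_network", NA_character_)
  if (mode == "all_zero") {
    if (is.null(features)) {
      abort("mode = \"all_zero\" requires the encoded `features`")
    }
    mat <- as.matrix(features[, setdiff(names(features), "gene")])
    zero_genes <- features$gene[rowSums(mat != 0) == 0L]
    is_zero <- labels$gene %in% zero_genes & !absent
    reason[is_zero] <- "all_zero_scores"
  }
  drop <- !is.na(reason)
  if (any(drop)) {
    inform(paste0(
      "dropped ", sum(drop), " gene(s) without available enrichment scores: ",
      paste(head(labels$gene[drop], 5), collapse = ", "),
      if (sum(drop) > 5) ", ..." else ""
    ))
  }
  list(
    kept = labels[!drop, , drop = FALSE],
    dropped = dplyr::bind_cols(
      labels[drop, , drop = FALSE],
      tibble(reason = reason[drop])
    )
  )
}
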