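#' Read annotation gene sets from a GMT file
#'
#' Parses the tab-separated GMT dialect used by MSigDB-style exports: one gene
#' set per line, with the term identifier in column 1, a term name or
#' description in column 2, and member gene symbols in columns 3 onward.
#' Because KEGG identifiers (e.g. `hsa03013`) carry no recognisable prefix,
#' the annotation namespace is supplied per file rather than parsed from the
#' term identifier.
#'
#' @param path Path to a GMT file.
#' @param namespace One of `"GO-BP"`, `"GO-CC"`, `"GO-MF"`, `"KEGG"`, recorded
#'   for every set in the file.
#' @return A tibble with one row per gene set and columns `term_id`,
#'   `term_name`, `namespace`, `members` (a list-column of character vectors)
#'   and `size`.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("GO:0032991\tmacromolecular complex\tA\tB\tC", gmt)
#' read_gene_sets(gmt, "GO-CC")
#' @export
read_gene_sets <- function(path, namespace = c("GO-BP", "GO-CC", "GO-MF", "KEGG")) {
  namespace <- arg_match(namespace)
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(
      term_id = character(), term_name = character(),
      namespace = character(), members = list(), size = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    abort(paste0(
      "GMT line ", which(short)[1], " has fewer than 3 tab-separated columns"
    ))
  }
  term_id <- vapply(fields, `[[`, character(1), 1L)
  dup <- duplicated(term_id)
  if (any(dup)) {
    abort(paste0("duplicate term_id in GMT file: ", term_id[dup][1]))
  }
  members <- lapply(seq_along(fields), function(i) {
    m <- fields[[i]][-(1:2)]
    m <- m[nzchar(m)]
    if (anyDuplicated(m)) {
      warn(paste0(
        "duplicate member symbols in gene set ", term_id[i], "; deduplicated"
      ))
      m <- unique(m)
    }
    m
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    abort(paste0("gene set ", term_id[empty][1], " has no members"))
  }
  tibble(
    term_id = term_id,
    term_name = vapply(fields, `[[`, character(1), 2L),
    namespace = namespace,
    members = members,
    size = lengths(members)
  )
}

#' Read an interaction network from a TSV edge list
#'
#' Reads a STRING-style export with columns `geneA`, `geneB` and optionally
#' `combined_score` (any header names are accepted positionally). The graph is
#' undirected: reciprocal and repeated rows collapse to a single edge,
#' self-loop rows are dropped with a warning, and edges scoring below
#' `min_score` are removed when a threshold is given.
#'
#' @param path Path to a 2- or 3-column TSV edge list, with or without header.
#' @param min_score Optional numeric confidence threshold; edges with
#'   `score < min_score` are dropped. Default `NULL` keeps every edge.
#' @return An `ess_network` object; see [as_network()].
#' @export
read_network <- function(path, min_score = NULL) {
  if (!file.exists(path)) {
    abort(paste0("network file not found: ", path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("gene|protein|node|score", tolower(first))
  df <- readr::read_tsv(
    path,
    col_names = has_header,
    show_col_types = FALSE,
    progress = FALSE
  )
  if (ncol(df) < 2L) {
    abort("edge list must have at least two columns (geneA, geneB)")
  }
  edges <- tibble(
    from = as.character(df[[1]]),
    to = as.character(df[[2]])
  )
  if (ncol(df) >= 3L) {
    score <- suppressWarnings(as.numeric(df[[3]]))
    if (anyNA(score) && !anyNA(df[[3]])) {
      abort("non-numeric values in the edge score column")
    }
    edges$score <- score
  }
  if (anyNA(edges$from) || anyNA(edges$to)) {
    abort("malformed edge row: missing gene identifier")
  }
  as_network(edges, min_score = min_score)
}

#' Build an undirected gene network from an edge table
#'
#' @param edges A data frame whose first two columns are gene identifiers and
#'   whose optional `score` column holds edge confidences in \[0, 1000\].
#' @param min_score Optional score threshold, as in [read_network()].
#' @param nodes Optional character vector of node identifiers to include even
#'   when isolated; edge endpoints are always included.
#' @return An `ess_network`: a list with `nodes` (character), `edges` (a tibble
#'   `from`/`to`\[/`score`\] with `from < to`), and `graph` (an
#'   [igraph::graph] used for neighbour lookup).
#' @export
as_network <- function(edges, min_score = NULL, nodes = NULL) {
  edges <- as_tibble(edges)
  stopifnot(ncol(edges) >= 2L)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  endpoint_nodes <- unique(c(edges$from, edges$to))

  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(paste0("dropped ", sum(loops), " self-loop edge row(s)"))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (!is.null(min_score) && "score" %in% names(edges)) {
    edges <- edges[edges$score >= min_score, , drop = FALSE]
  }
  # canonical orientation, then collapse duplicates (keep max score)
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  if ("score" %in% names(edges) && nrow(edges) > 0L) {
    edges <- edges %>%
      group_by(.data$from, .data$to) %>%
      summarise(score = max(.data$score), .groups = "drop")
  } else {
    edges <- distinct(edges, .data$from, .data$to)
  }
  edges <- arrange(edges, .data$from, .data$to)
  all_nodes <- sort(unique(c(endpoint_nodes, nodes)))
  graph <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = all_nodes
  )
  structure(
    list(nodes = all_nodes, edges = edges, graph = graph),
    class = "ess_network"
  )
}

#' @export
print.ess_network <- function(x, ...) {
  cat(
    "<ess_network> ", length(x$nodes), " nodes, ",
    nrow(x$edges), " undirected edges\n",
    sep = ""
  )
  invisible(x)
}

#' Read labeled gene lists
#'
#' Reads the positive (essential) and negative (non-essential) gene lists, one
#' symbol per line; lines beginning `#` are comments. A gene appearing in both
#' files is a hard error since the label would be contradictory.
#'
#' @param pos_path,neg_path Paths to plain-text gene lists.
#' @return A tibble with columns `gene` and `label` (factor with levels
#'   `negative`, `positive`), positives first, input order preserved.
#' @export
read_labels <- function(pos_path, neg_path) {
  read_list <- function(p) {
    if (!file.exists(p)) abort(paste0("gene list not found: ", p))
    x <- trimws(readLines(p, warn = FALSE))
    x <- x[nzchar(x) & !startsWith(x, "#")]
    if (anyDuplicated(x)) {
      abort(paste0("duplicate gene in ", p, ": ", x[duplicated(x)][1]))
    }
    x
  }
  pos <- read_list(pos_path)
  neg <- read_list(neg_path)
  both <- intersect(pos, neg)
  if (length(both) > 0L) {
    abort(paste0(
      "gene(s) present in both label files: ",
      paste(head(both, 5), collapse = ", ")
    ))
  }
  tibble(
    gene = c(pos, neg),
    label = factor(
      rep(c("positive", "negative"), c(length(pos), length(neg))),
      levels = c("negative", "positive")
    )
  )
}

#' Write / read a feature matrix as TSV
#'
#' The on-disk format is a TSV whose header row holds `gene` followed by the
#' term identifiers and whose first column holds gene identifiers; scores are
#' written with 6 significant digits, so a write/read round trip reproduces
#' the matrix to that precision. Term names and namespaces are not part of the
#' file; pass `feature_info` to [read_matrix()] to restore them.
#'
#' @param x A feature tibble as returned by [encode_genes()] (column `gene`
#'   plus one numeric column per term).
#' @param path Output / input path.
#' @param feature_info Optional tibble (`term_id`, `term_name`, `namespace`)
#'   re-attached to the matrix on read.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   a feature tibble.
#' @export
write_matrix <- function(x, path) {
  stopifnot(is.data.frame(x), names(x)[1] == "gene")
  out <- x
  for (j in seq_along(out)[-1]) {
    out[[j]] <- signif(out[[j]], 6)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, feature_info = NULL) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene") {
    abort("feature matrix TSV must have 'gene' as its first column")
  }
  if (nrow(df) == 0L) {
    # header-only file: column types are indeterminate, declare them
    df[-1] <- lapply(df[-1], as.numeric)
    df$gene <- as.character(df$gene)
  }
  bad <- !vapply(df[-1], is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric score column: ", names(df[-1])[bad][1]))
  }
  new_features(as_tibble(df), feature_info = feature_info)
}
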