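#' Configuration for the synthetic essentiality benchmark
#'
#' Describes a generated dataset: a background interaction network with
#' Erdős–Rényi wiring, a collection of GO-like and KEGG-like annotation sets,
#' and labeled genes in which the positive (essential-like) class carries a
#' planted neighbourhood signal — each positive gene is preferentially wired
#' to the members of a few designated "informative" terms, so its
#' neighbourhood is genuinely hypergeometrically enriched in those terms. The
#' defaults echo the roughly 1:4 class imbalance of curated essentiality
#' gold standards.
#'
#' @param n_genes Total genes in the universe.
#' @param n_pos,n_neg Positive / negative labeled genes
#'   (`n_pos + n_neg <= n_genes`).
#' @param n_go_terms,n_kegg_terms Annotation sets per namespace.
#' @param term_size_range Inclusive `(min, max)` gene-set size.
#' @param n_informative_terms Number of terms carrying planted signal.
#' @param p_signal Probability that a positive gene links to each member of
#'   one of its informative terms; must exceed `p_background` for a signal.
#' @param p_background Baseline edge probability between any gene pair.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated `ess_synth_config` list.
#' @export
synthetic_config <- function(n_genes = 1000, n_pos = 200, n_neg = 800,
                             n_go_terms = 500, n_kegg_terms = 50,
                             term_size_range = c(10, 40),
                             n_informative_terms = 20,
                             p_signal = 0.5, p_background = 0.005,
                             seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_pos = as.integer(n_pos),
    n_neg = as.integer(n_neg),
    n_go_terms = as.integer(n_go_terms),
    n_kegg_terms = as.integer(n_kegg_terms),
    term_size_range = as.integer(term_size_range),
    n_informative_terms = as.integer(n_informative_terms),
    p_signal = p_signal,
    p_background = p_background,
    seed = as.integer(seed)
  )
  if (cfg$n_pos + cfg$n_neg > cfg$n_genes) {
    abort("n_pos + n_neg exceeds n_genes")
  }
  if (cfg$n_informative_terms > cfg$n_go_terms + cfg$n_kegg_terms) {
    abort("more informative terms than terms")
  }
  if (any(c(cfg$p_signal, cfg$p_background) < 0) ||
      any(c(cfg$p_signal, cfg$p_background) > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (length(cfg$term_size_range) != 2L ||
      cfg$term_size_range[1] > cfg$term_size_range[2]) {
    abort("term_size_range must be (min, max) with min <= max")
  }
  # members are drawn from non-positive genes only (see generate_dataset)
  if (cfg$term_size_range[2] > cfg$n_genes - cfg$n_pos) {
    abort("term size exceeds the pool of non-positive genes")
  }
  structure(cfg, class = "ess_synth_config")
}

#' Generate a synthetic essentiality dataset
#'
#' Builds, deterministically for the config seed: (i) annotation sets with
#' sizes uniform in `term_size_range`, members drawn from the non-positive
#' genes so the planted signal is purely neighbourhood-mediated — informative
#' terms take pairwise-disjoint member sets from a reserved slice of the pool
#' and the remaining terms draw from its complement, keeping the planted
#' truth identifiable; (ii) an Erdős–Rényi background network at
#' `p_background`; (iii) for each positive gene, 1–3 informative terms chosen
#' and an edge to each of their members added with probability `p_signal`;
#' negatives receive background wiring only.
#'
#' @param config An `ess_synth_config` from [synthetic_config()].
#' @return An `ess_synth_dataset`: list with `network` (`ess_network`),
#'   `gene_sets` (tibble as from [read_gene_sets()]), `labels` (tibble as
#'   from [read_labels()]), and `truth` (list: `informative_terms`,
#'   `assignments` tibble mapping positive genes to their planted terms,
#'   `config`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "ess_synth_config"))
  with_seed(config$seed, {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    labeled <- sample(genes, config$n_pos + config$n_neg)
    pos <- labeled[seq_len(config$n_pos)]
    neg <- labeled[config$n_pos + seq_len(config$n_neg)]
    nonpos <- setdiff(genes, pos)

    n_terms <- config$n_go_terms + config$n_kegg_terms
    term_id <- c(
      sprintf("GO:%07d", seq_len(config$n_go_terms)),
      sprintf("hsa%05d", seq_len(config$n_kegg_terms))
    )
    namespace <- c(
      sample(c("GO-BP", "GO-CC", "GO-MF"), config$n_go_terms, replace = TRUE),
      rep("KEGG", config$n_kegg_terms)
    )
    sizes <- sample(
      seq.int(config$term_size_range[1], config$term_size_range[2]),
      n_terms, replace = TRUE
    )
    informative <- sort(sample(term_id, config$n_informative_terms))
    info_idx <- match(informative, term_id)

    # Informative terms draw pairwise-disjoint member sets from a reserved
    # slice of the non-positive pool; the remaining terms draw from the
    # complement. Keeping the planted memberships unshared makes the ground
    # truth identifiable: no unplanted term can proxy the class signal
    # through shared members. (Realistic term overlap is out of scope here.)
    pool <- sample(nonpos)
    reserved <- sum(sizes[info_idx])
    rest_pool <- pool[seq.int(reserved + 1, length.out = length(pool) - reserved)]
    if (reserved + max(sizes) > length(pool)) {
      abort("infeasible config: informative terms exhaust the member pool")
    }
    members <- vector("list", n_terms)
    off <- 0
    for (j in info_idx) {
      members[[j]] <- sort(pool[off + seq_len(sizes[j])])
      off <- off + sizes[j]
    }
    for (j in setdiff(seq_len(n_terms), info_idx)) {
      members[[j]] <- sort(sample(rest_pool, sizes[j]))
    }
    gene_sets <- tibble(
      term_id = term_id,
      term_name = paste0("synthetic term ", seq_len(n_terms)),
      namespace = namespace,
      members = members,
      size = lengths(members)
    )

    # background: Erdős–Rényi over all gene pairs
    n <- config$n_genes
    pair_hit <- which(runif(n * (n - 1) / 2) < config$p_background)
    # unrank the flat upper-triangle index into (i, j), i < j
    if (length(pair_hit) > 0) {
      idx <- pair_hit - 1
      i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
      offset <- function(i) i * n - i * (i + 1) / 2
      # guard against sqrt round-off at block boundaries
      i <- i - (offset(i) > idx) + (offset(i + 1) <= idx)
      j <- idx - offset(i) + i + 1
      bg_edges <- tibble(from = genes[i + 1], to = genes[j + 1])
    } else {
      bg_edges <- tibble(from = character(), to = character())
    }

    # planted signal: positives wired into their informative terms
    assign_list <- vector("list", config$n_pos)
    sig_from <- sig_to <- vector("list", config$n_pos)
    for (k in seq_len(config$n_pos)) {
      g <- pos[k]
      terms_k <- sample(informative, sample.int(3L, 1L))
      assign_list[[k]] <- tibble(gene = g, term_id = terms_k)
      targets <- unique(unlist(
        members[match(terms_k, term_id)], use.names = FALSE
      ))
      hit <- targets[runif(length(targets)) < config$p_signal]
      sig_from[[k]] <- rep(g, length(hit))
      sig_to[[k]] <- hit
    }
    sig_edges <- tibble(
      from = unlist(sig_from, use.names = FALSE),
      to = unlist(sig_to, use.names = FALSE)
    )

    edges <- dplyr::bind_rows(bg_edges, sig_edges)
    edges$score <- round(runif(nrow(edges), 400, 999))
    network <- as_network(edges, nodes = genes)

    labels <- tibble(
      gene = c(pos, neg),
      label = factor(
        rep(c("positive", "negative"), c(length(pos), length(neg))),
        levels = c("negative", "positive")
      )
    )
    structure(
      list(
        network = network,
        gene_sets = gene_sets,
        labels = labels,
        truth = list(
          informative_terms = informative,
          assignments = dplyr::bind_rows(assign_list),
          config = config
        )
      ),
      class = "ess_synth_dataset"
    )
  })
}

#' @export
print.ess_synth_dataset <- function(x, ...) {
  cat("<ess_synth_dataset> ", length(x$network$nodes), " genes, ",
      nrow(x$network$edges), " edges, ", nrow(x$gene_sets), " terms (",
      length(x$truth$informative_terms), " informative), ",
      sum(x$labels$label == "positive"), " positive / ",
      sum(x$labels$label == "negative"), " negative labels\n", sep = "")
  invisible(x)
}

#' Export a synthetic dataset to standard on-disk formats
#'
#' Writes `net.tsv` (TSV edge list with scores), `go.gmt` and `kegg.gmt`
#' (GMT gene sets), `pos.txt` / `neg.txt` (one gene per line) and
#' `truth.json` (informative terms, gene-term assignments and the generating
#' config) to `dir`, in the formats the reader functions accept, so an export
#' → read round trip reproduces the dataset.
#'
#' @param dataset An `ess_synth_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ess_synth_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  ed <- dataset$network$edges
  readr::write_tsv(
    tibble(geneA = ed$from, geneB = ed$to, combined_score = ed$score),
    file.path(dir, "net.tsv"), progress = FALSE
  )
  write_gmt <- function(sets, path) {
    lines <- purrr::pmap_chr(
      sets[, c("term_id", "term_name", "members")],
      function(term_id, term_name, members) {
        paste(c(term_id, term_name, members), collapse = "\t")
      }
    )
    writeLines(lines, path)
  }
  go <- dataset$gene_sets[dataset$gene_sets$namespace != "KEGG", ]
  kegg <- dataset$gene_sets[dataset$gene_sets$namespace == "KEGG", ]
  write_gmt(go, file.path(dir, "go.gmt"))
  write_gmt(kegg, file.path(dir, "kegg.gmt"))

  pos <- dataset$labels$gene[dataset$labels$label == "positive"]
  neg <- dataset$labels$gene[dataset$labels$label == "negative"]
  writeLines(pos, file.path(dir, "pos.txt"))
  writeLines(neg, file.path(dir, "neg.txt"))

  jsonlite::write_json(
    list(
      informative_terms = dataset$truth$informative_terms,
      assignments = dataset$truth$assignments,
      config = unclass(dataset$truth$config)
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
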