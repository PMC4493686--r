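#' Construct a weighted gene network
#'
#' A network is an edge tibble (`gene1`, `gene2`, `weight`) with the pair
#' stored in canonical order (`gene1 < gene2`), plus a gene universe and a
#' data-type tag carried as attributes. `complete = TRUE` marks networks in
#' which every universe pair is scored (co-expression networks); sparse
#' evidence networks (physical, regulatory) leave unobserved pairs unscored.
#'
#' @param edges Data frame with columns `gene1`, `gene2`, `weight`.
#' @param universe Character vector of gene ids; defaults to the genes seen
#'   in `edges`.
#' @param net_type One of `"coexpression"`, `"physical"`, `"regulatory"`,
#'   `"functional"`.
#' @param dataset_id Optional dataset identifier.
#' @param complete Is every universe pair scored?
#' @param report_threshold Default reporting threshold stored for writers.
#' @return A `gene_network` tibble.
#' @export
gene_network <- function(edges, universe = NULL,
                         net_type = c("coexpression", "physical",
                                      "regulatory", "functional"),
                         dataset_id = NA_character_, complete = FALSE,
                         report_threshold = 2) {
  net_type <- match.arg(net_type)
  edges <- as_tibble(edges)[, c("gene1", "gene2", "weight")]
  if (nrow(edges)) {
    if (any(edges$gene1 == edges$gene2)) abort("Self-edges are not allowed.")
    if (any(!is.finite(edges$weight))) abort("Edge weights must be finite.")
    flip <- edges$gene1 > edges$gene2
    tmp <- edges$gene1[flip]
    edges$gene1[flip] <- edges$gene2[flip]
    edges$gene2[flip] <- tmp
    edges <- arrange(edges, .data$gene1, .data$gene2)
    if (anyDuplicated(paste(edges$gene1, edges$gene2))) {
      abort("Duplicate edges for the same gene pair.")
    }
  }
  universe <- sort(unique(c(universe, edges$gene1, edges$gene2)))
  if (nrow(edges) && !all(c(edges$gene1, edges$gene2) %in% universe)) {
    abort("Edge endpoints outside the gene universe.")
  }
  structure(edges,
            class = c("gene_network", class(tibble())),
            universe = universe, net_type = net_type,
            dataset_id = dataset_id, complete = complete,
            report_threshold = report_threshold)
}

net_universe <- function(net) attr(net, "universe")
net_type <- function(net) attr(net, "net_type")
net_complete <- function(net) isTRUE(attr(net, "complete"))

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> type=%s dataset=%s genes=%d edges=%d complete=%s\n",
              attr(x, "net_type"), attr(x, "dataset_id"),
              length(attr(x, "universe")), nrow(x), attr(x, "complete")))
  NextMethod()
}

#' Read a weighted edge list
#'
#' @param path TSV with columns gene1, gene2, weight (header optional,
#'   detected by a non-numeric third field); `#` comment lines allowed.
#' @inheritParams gene_network
#' @return A `gene_network`.
#' @export
read_network <- function(path, net_type = "functional",
                         dataset_id = NA_character_, universe = NULL,
                         complete = FALSE) {
  if (!file.exists(path)) abort(sprintf("Network file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort(sprintf("Network file %s has no edges.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    abort(sprintf("Malformed edge row at line %d of %s.",
                  which(lengths(parts) != 3)[1], path))
  }
  tab <- tibble(gene1 = map_chr(parts, 1), gene2 = map_chr(parts, 2),
                w = map_chr(parts, 3))
  if (is.na(suppressWarnings(as.numeric(tab$w[1])))) tab <- tab[-1, ]
  weight <- suppressWarnings(as.numeric(tab$w))
  if (anyNA(weight)) abort(sprintf("Non-numeric weight in %s.", path))
  gene_network(tibble(gene1 = tab$gene1, gene2 = tab$gene2, weight = weight),
               universe = universe, net_type = net_type,
               dataset_id = dataset_id, complete = complete)
}

#' Write a network edge list
#'
#' One undirected edge per line (`gene1 < gene2` lexicographically), rows
#' sorted, deterministic formatting. With `threshold` set, only edges whose
#' `|weight|` (or signed weight when `signed = TRUE`) exceeds it are emitted
#' — the high-confidence reporting convention.
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @param threshold Optional reporting threshold; `TRUE` uses the network's
#'   stored `report_threshold`.
#' @param signed Threshold on the signed weight instead of `|weight|`.
#' @param overwrite Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, threshold = NULL, signed = FALSE,
                          overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    abort(sprintf("Refusing to overwrite existing file: %s", path))
  }
  edges <- as_tibble(net)
  if (isTRUE(threshold)) threshold <- attr(net, "report_threshold")
  if (!is.null(threshold) && !isFALSE(threshold)) {
    keep <- if (signed) edges$weight > threshold else abs(edges$weight) > threshold
    edges <- edges[keep, ]
  }
  write_tsv_plain(edges, path)
}

#' Standardize edge weights onto a common z-score scale
#'
#' Continuous networks (>= 2 distinct weights) have their edge weights
#' z-standardized across the network (mean 0, sd 1). Binary networks — all
#' weights equal, typical of physical or regulatory edge lists — get every
#' present edge assigned a fixed confidence constant on the z scale (default
#' 2, the conventional high-confidence cutoff); absent pairs stay unscored.
#'
#' @param net A `gene_network` with >= 1 edge.
#' @param binary_confidence Constant assigned to binary-network edges.
#' @return A `gene_network` with standardized weights.
#' @export
standardize_edge_weights <- function(net, binary_confidence = 2) {
  if (nrow(net) == 0) abort("Cannot standardize an empty network.")
  w <- net$weight
  if (length(unique(w)) < 2) {
    net$weight <- rep(binary_confidence, length(w))
  } else {
    net$weight <- (w - mean(w)) / sd(w)
  }
  net
}

#' Integrate networks by averaging z-score edge weights
#'
#' Builds a single functional network over the union of the input universes.
#' A pair is scoreable in a network if that network scores it explicitly (or
#' is complete with both endpoints in its universe — complete networks store
#' every pair explicitly). The integrated weight is the arithmetic mean over
#' the networks that score the pair; pairs scoreable nowhere are absent, so
#' sparse physical evidence is not diluted by implicit zeros. Set
#' `average_mode = "all"` to divide by the number of networks whose universe
#' covers the pair instead.
#'
#' @param nets List of standardized `gene_network` objects.
#' @param average_mode `"scoreable"` (default) or `"all"`.
#' @return A `gene_network` tagged `functional`, `complete = FALSE`.
#' @export
integrate_networks <- function(nets, average_mode = c("scoreable", "all")) {
  average_mode <- match.arg(average_mode)
  if (!length(nets)) abort("Need at least one network to integrate.")
  universe <- sort(unique(unlist(lapply(nets, net_universe))))
  all_edges <- bind_rows(lapply(seq_along(nets), function(i) {
    e <- as_tibble(nets[[i]])
    e$.net <- i
    e
  }))
  if (!nrow(all_edges)) abort("All networks are empty.")
  pooled <- all_edges |>
    group_by(.data$gene1, .data$gene2) |>
    summarise(total = sum(.data$weight), n_scored = dplyr::n(),
              .groups = "drop")
  if (average_mode == "scoreable") {
    pooled$weight <- pooled$total / pooled$n_scored
  } else {
    cover <- function(g1, g2) {
      sum(vapply(nets, function(n) {
        u <- net_universe(n)
        g1 %in% u && g2 %in% u
      }, logical(1)))
    }
    denom <- map2(pooled$gene1, pooled$gene2, cover)
    pooled$weight <- pooled$total / pmax(unlist(denom), 1)
  }
  gene_network(pooled[, c("gene1", "gene2", "weight")], universe = universe,
               net_type = "functional", complete = FALSE)
}

#' Extract a high-confidence subgraph around query genes
#'
#' Greedy seed expansion: starting from the query genes present in the
#' network, repeat `k` times — score every candidate gene by the sum of its
#' edge weights to the current subgraph (unscored pairs contribute 0) and add
#' the top scorer, breaking ties by lexicographic gene id. By default the
#' expansion never stops early, so exactly `min(k, |V| - |seeds|)` genes are
#' added and the printed subgraph size is `|seeds| + k` whenever candidates
#' abound; set `early_stop = TRUE` to halt once all remaining candidates
#' score <= 0.
#'
#' @param net A `gene_network`.
#' @param query_genes Character vector of query (seed) gene ids.
#' @param k Number of additional neighbours to add (>= 0).
#' @param early_stop Stop when no candidate has positive connectivity?
#'   Default `FALSE`.
#' @return A `subgraph` object: list with `nodes` (tibble: `node`, `role`,
#'   `add_rank`, `add_score`), `edges` (induced weighted edges), `seed_nodes`,
#'   `added_nodes`.
#' @export
extract_subgraph <- function(net, query_genes, k, early_stop = FALSE) {
  if (!length(query_genes)) abort("Query gene set is empty.")
  if (anyDuplicated(query_genes)) query_genes <- unique(query_genes)
  if (k < 0) abort("`k` must be >= 0.")
  universe <- net_universe(net)
  missing <- setdiff(query_genes, universe)
  if (length(missing) == length(query_genes)) {
    abort(sprintf("No query gene present in the network: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(missing)) {
    warn(sprintf("Dropping %d query gene(s) absent from the network: %s",
                 length(missing), paste(missing, collapse = ", ")))
  }
  seeds <- intersect(query_genes, universe)

  # adjacency as a named running score: score[v] = sum of w(u, v) over u in S
  edges <- as_tibble(net)
  nbr <- split(
    tibble(other = c(edges$gene2, edges$gene1),
           w = c(edges$weight, edges$weight)),
    c(edges$gene1, edges$gene2))
  score <- setNames(numeric(length(universe)), universe)
  in_set <- setNames(logical(length(universe)), universe)
  add_edge_scores <- function(v) {
    nb <- nbr[[v]]
    if (!is.null(nb)) score[nb$other] <<- score[nb$other] + nb$w
  }
  for (s in seeds) in_set[s] <- TRUE
  for (s in seeds) add_edge_scores(s)

  added <- character(0)
  add_scores <- numeric(0)
  n_add <- min(k, length(universe) - length(seeds))
  while (length(added) < n_add) {
    cand <- universe[!in_set[universe]]
    if (!length(cand)) break
    sc <- score[cand]
    if (early_stop && max(sc) <= 0) break
    best <- cand[sc == max(sc)]
    v <- sort(best)[1]
    added <- c(added, v)
    add_scores <- c(add_scores, unname(score[v]))
    in_set[v] <- TRUE
    add_edge_scores(v)
  }

  nodes_all <- c(seeds, added)
  induced <- edges[edges$gene1 %in% nodes_all & edges$gene2 %in% nodes_all, ]
  nodes <- tibble(
    node = nodes_all,
    role = c(rep("seed", length(seeds)), rep("added", length(added))),
    add_rank = c(rep(NA_integer_, length(seeds)), seq_along(added)),
    add_score = c(rep(NA_real_, length(seeds)), add_scores))
  structure(list(nodes = nodes, edges = induced, seed_nodes = seeds,
                 added_nodes = added, k = k),
            class = "subgraph")
}

#' @export
print.subgraph <- function(x, ...) {
  cat(sprintf("<subgraph> %d nodes (%d seeds + %d added), %d induced edges\n",
              nrow(x$nodes), length(x$seed_nodes), length(x$added_nodes),
              nrow(x$edges)))
  invisible(x)
}

#' @rdname extract_subgraph
#' @param x A `subgraph`.
#' @param ... Unused.
#' @method tidy subgraph
#' @export
tidy.subgraph <- function(x, ...) x$nodes

#' @rdname extract_subgraph
#' @method glance subgraph
#' @export
glance.subgraph <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_seeds = length(x$seed_nodes),
         n_added = length(x$added_nodes), n_edges = nrow(x$edges), k = x$k)
}

#' Write a subgraph as a node table and an induced edge list
#'
#' @param sg A `subgraph`.
#' @param dir Output directory; writes `nodes.tsv` and `edges.tsv`.
#' @param overwrite Overwrite existing files?
#' @return `dir`, invisibly.
#' @export
write_subgraph <- function(sg, dir, overwrite = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  if (!overwrite && (file.exists(np) || file.exists(ep))) {
    abort(sprintf("Refusing to overwrite existing subgraph files in %s", dir))
  }
  write_tsv_plain(sg$nodes, np)
  write_tsv_plain(arrange(sg$edges, .data$gene1, .data$gene2), ep)
  invisible(dir)
}
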