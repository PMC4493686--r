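#' Parse a processing-recipe string
#'
#' Recipes are ordered step strings like `"log2::zscore::knn10::coexpr"`,
#' the compact notation used in pipeline configuration to pick and
#' parameterize the normalization chain. Vocabulary: `log2` (optional,
#' first), `zscore`, `knn<k>` (k-nearest-neighbour imputation with the given
#' neighbour count), `coexpr` (co-expression network construction). Steps
#' must appear in that canonical order, each at most once, and `knn` /
#' `coexpr` require `zscore` before them (imputation and correlation both
#' assume standardized rows).
#'
#' @param s Recipe string.
#' @return Tibble with columns `step` and `k` (NA except for `knn`).
#' @export
parse_recipe <- function(s) {
  if (!is.character(s) || length(s) != 1 || !nzchar(s)) {
    abort("Recipe must be a single non-empty string.")
  }
  toks <- strsplit(s, "::", fixed = TRUE)[[1]]
  order_of <- function(tok) {
    if (tok == "log2") return(1L)
    if (tok == "zscore") return(2L)
    if (grepl("^knn[0-9]+$", tok)) return(3L)
    if (tok == "coexpr") return(4L)
    abort(sprintf("Unknown recipe step '%s'.", tok))
  }
  ranks <- vapply(toks, order_of, integer(1))
  if (any(diff(ranks) <= 0)) {
    i <- which(diff(ranks) <= 0)[1]
    abort(sprintf("Recipe steps out of order: '%s' cannot follow '%s'.",
                  toks[i + 1], toks[i]))
  }
  if (any(ranks >= 3) && !any(ranks == 2)) {
    abort("Steps 'knn'/'coexpr' require 'zscore' earlier in the recipe.")
  }
  k <- rep(NA_integer_, length(toks))
  k[ranks == 3L] <- as.integer(sub("^knn", "", toks[ranks == 3L]))
  tibble(step = c("log2", "zscore", "knn", "coexpr")[ranks], k = k)
}

#' Assemble a validated pipeline configuration
#'
#' @param target_namespace Label of the shared gene namespace.
#' @param recipe Processing recipe string; see [parse_recipe()].
#' @param taxa Optional taxonomy ids restricting dataset selection.
#' @param selection Optional list of [select_datasets()] criteria
#'   (`include_ids`, `exclude_ids`, `patterns`, `min_samples`).
#' @param integration List: `binary_confidence` (default 2) and
#'   `average_mode` (`"scoreable"` or `"all"`).
#' @param query Optional list `list(genes=, k=)` enabling subgraph
#'   extraction from the integrated network.
#' @param meta Optional list enabling meta-analysis: `method`
#'   (`"REML"`/`"DL"`), `B` permutations, `fdr`, optional `gmt` path.
#' @param seed Integer seed for stochastic stages (permutation enrichment).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_namespace = "genes",
                            recipe = "zscore::knn10::coexpr",
                            taxa = NULL, selection = list(),
                            integration = list(), query = NULL,
                            meta = NULL, seed = 1) {
  parse_recipe(recipe)  # validates
  integration <- modifyList(
    list(binary_confidence = 2, average_mode = "scoreable"), integration)
  if (!is.null(query)) {
    if (is.null(query$genes) || is.null(query$k)) {
      abort("`query` needs `genes` and `k`.")
    }
  }
  if (!is.null(meta)) {
    meta <- modifyList(list(method = "REML", B = 1000, fdr = 0.05,
                            gmt = NULL), meta)
    if (!meta$method %in% c("REML", "DL")) abort("meta$method must be REML or DL.")
  }
  structure(list(target_namespace = target_namespace, recipe = recipe,
                 taxa = taxa, selection = selection,
                 integration = integration, query = query, meta = meta,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path Configuration file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("target_namespace", "recipe", "taxa", "selection", "integration",
             "query", "meta", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s. Known keys: %s.",
                  paste(unknown, collapse = ", "), paste(known, collapse = ", ")))
  }
  do.call(pipeline_config, cfg)
}
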