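# Dependency-driven pipeline: a checksum planner decides which stage
# instances are stale (input changed, config changed, or output missing) and
# the runner executes exactly those, in topological order, recording MD5
# provenance per node. New data are generated only when an upstream element
# changed.

prov_dir <- function(ws) file.path(ws, ".provenance")
prov_path <- function(ws, id) file.path(prov_dir(ws), paste0(id, ".json"))

read_registry <- function(ws) {
  p <- file.path(prov_dir(ws), "registry.json")
  if (!file.exists(p)) return(character(0))
  unlist(jsonlite::read_json(p, simplifyVector = TRUE))
}

add_registry <- function(ws, paths) {
  reg <- sort(unique(c(read_registry(ws), paths)))
  dir.create(prov_dir(ws), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.list(reg), file.path(prov_dir(ws), "registry.json"))
  invisible(reg)
}

# Guarded write target: refuse to clobber a file the pipeline did not create.
guard_output <- function(ws, rel) {
  abs <- file.path(ws, rel)
  if (file.exists(abs) && !(rel %in% read_registry(ws))) {
    abort(sprintf(
      "Path collision: %s exists but was not produced by the pipeline.", rel))
  }
  dir.create(dirname(abs), recursive = TRUE, showWarnings = FALSE)
  abs
}

# Discover datasets as data/<source>/<dataset_id>/ holding raw.tsv +
# metadata.json; returns merged (auto + curated) metadata records.
discover_datasets <- function(ws) {
  data_dir <- file.path(ws, "data")
  rows <- list()
  for (src in sort(list.dirs(data_dir, recursive = FALSE, full.names = FALSE))) {
    for (id in sort(list.dirs(file.path(data_dir, src), recursive = FALSE,
                              full.names = FALSE))) {
      ddir <- file.path(data_dir, src, id)
      if (!file.exists(file.path(ddir, "raw.tsv")) ||
          !file.exists(file.path(ddir, "metadata.json"))) next
      auto <- read_metadata(file.path(ddir, "metadata.json"))
      cur_path <- file.path(ws, "etc", "manual_curation", paste0(id, ".json"))
      rec <- if (file.exists(cur_path)) {
        merge_metadata(auto, read_metadata(cur_path))
      } else auto
      rows[[length(rows) + 1]] <- list(
        dataset_id = id, source = src, record = rec,
        curated_path = if (file.exists(cur_path)) cur_path else NULL)
    }
  }
  rows
}

node <- function(id, stage, inputs, outputs, parents, config,
                 dataset_id = NA_character_, source = NA_character_) {
  list(id = id, stage = stage, inputs = inputs, outputs = outputs,
       parents = parents, config_hash = md5_obj(config),
       dataset_id = dataset_id, source = source)
}

build_nodes <- function(cfg, ws) {
  found <- discover_datasets(ws)
  if (!length(found)) abort(sprintf("No datasets found under %s/data.", ws))
  records <- lapply(found, `[[`, "record")
  sel_args <- c(list(records = records, taxa = cfg$taxa), cfg$selection)
  selected <- do.call(select_datasets, sel_args)
  found <- keep(found, ~ .x$dataset_id %in% selected)
  if (!length(found)) abort("Dataset selection matched nothing.")
  recipe <- parse_recipe(cfg$recipe)
  has_coexpr <- "coexpr" %in% recipe$step

  nodes <- list()
  coexpr_outputs <- character(0)
  mapped_outputs <- character(0)
  meta_json <- character(0)
  net_inputs <- character(0)
  per_ds_chain <- list()
  for (f in found) {
    id <- f$dataset_id
    src <- f$source
    base <- file.path("data", src, id)
    map_in <- c(file.path(base, "raw.tsv"), file.path("maps", paste0(src, ".tsv")),
                file.path(base, "metadata.json"))
    cur_rel <- file.path("etc", "manual_curation", paste0(id, ".json"))
    if (file.exists(file.path(ws, cur_rel))) map_in <- c(map_in, cur_rel)
    n_map <- node(paste0("map:", id), "map", map_in,
                  c(file.path(base, "mapped.tsv"),
                    file.path(base, "metadata.merged.json")),
                  character(0), list(ns = cfg$target_namespace),
                  dataset_id = id, source = src)
    n_norm <- node(paste0("normalize:", id), "normalize",
                   file.path(base, "mapped.tsv"),
                   file.path(base, "normalized.tsv"),
                   n_map$id, list(recipe = cfg$recipe),
                   dataset_id = id, source = src)
    nodes <- c(nodes, list(n_map, n_norm))
    mapped_outputs <- c(mapped_outputs, file.path(base, "mapped.tsv"))
    meta_json <- c(meta_json, file.path(base, "metadata.merged.json"))
    last_id <- n_norm$id
    if (has_coexpr) {
      n_cx <- node(paste0("coexpr:", id), "coexpr",
                   file.path(base, "normalized.tsv"),
                   file.path(base, "coexpr.tsv"),
                   n_norm$id, list(recipe = cfg$recipe),
                   dataset_id = id, source = src)
      nodes <- c(nodes, list(n_cx))
      coexpr_outputs <- c(coexpr_outputs, file.path(base, "coexpr.tsv"))
      last_id <- n_cx$id
    }
    per_ds_chain[[id]] <- last_id
    net_rel <- file.path("networks", src, paste0(id, ".tsv"))
    if (file.exists(file.path(ws, net_rel))) {
      net_inputs <- c(net_inputs,
                      net_rel, file.path("maps", paste0(src, ".tsv")))
    }
  }

  if (has_coexpr) {
    n_int <- node("integrate", "integrate",
                  c(coexpr_outputs, unique(net_inputs)),
                  file.path("integrated", "functional.tsv"),
                  unlist(per_ds_chain, use.names = FALSE),
                  cfg$integration)
    nodes <- c(nodes, list(n_int))
    if (!is.null(cfg$query)) {
      nodes <- c(nodes, list(node(
        "query", "query", file.path("integrated", "functional.tsv"),
        c(file.path("query", "nodes.tsv"), file.path("query", "edges.tsv")),
        "integrate", cfg$query)))
    }
  }
  if (!is.null(cfg$meta)) {
    meta_out <- c(file.path("meta", "meta_results.tsv"),
                  file.path("meta", "effects.tsv"))
    meta_in <- c(mapped_outputs, meta_json)
    if (!is.null(cfg$meta$gmt)) {
      meta_in <- c(meta_in, cfg$meta$gmt)
      meta_out <- c(meta_out, file.path("meta", "enrichment.tsv"))
    }
    nodes <- c(nodes, list(node(
      "meta", "meta", meta_in, meta_out,
      paste0("map:", vapply(found, `[[`, character(1), "dataset_id")),
      c(cfg$meta, list(seed = cfg$seed)))))
  }
  nodes
}

#' Plan an incremental pipeline build
#'
#' Pure planning, no execution: compares the provenance recorded by earlier
#' runs (MD5 input digests + configuration hashes) against the current
#' workspace state and marks the minimal stale node set together with its
#' downstream closure. A node is stale iff at least one reason holds:
#' `missing-output` (no recorded provenance, or an output file is gone),
#' `config-changed`, or `input-changed` (an input digest differs, or an
#' upstream node is itself stale).
#'
#' @param cfg A `pipeline_config`.
#' @param workspace Workspace directory (see [gen_mock_repository()] for the
#'   expected input layout).
#' @return A tibble with one row per stage instance: `id`, `stage`,
#'   `dataset_id`, `status` (`"fresh"`/`"stale"`), list-column `reasons`;
#'   the full node list rides along as attribute `"nodes"`.
#' @export
plan_build <- function(cfg, workspace) {
  nodes <- build_nodes(cfg, workspace)
  status <- setNames(vector("list", length(nodes)),
                     vapply(nodes, `[[`, character(1), "id"))
  stale_ids <- character(0)
  rows <- lapply(nodes, function(n) {
    reasons <- character(0)
    pp <- prov_path(workspace, gsub("[:/]", "_", n$id))
    if (!file.exists(pp) ||
        !all(file.exists(file.path(workspace, n$outputs)))) {
      reasons <- c(reasons, "missing-output")
    } else {
      prov <- tryCatch(jsonlite::read_json(pp, simplifyVector = TRUE),
                       error = function(e) NULL)
      if (is.null(prov)) {
        reasons <- c(reasons, "missing-output")
      } else {
        if (!identical(prov$config_hash, n$config_hash)) {
          reasons <- c(reasons, "config-changed")
        }
        cur <- vapply(file.path(workspace, n$inputs), md5_file, character(1))
        names(cur) <- n$inputs
        old <- unlist(prov$input_checksums)
        same <- identical(sort(names(old)), sort(names(cur))) &&
          !anyNA(cur) && all(old[names(cur)] == cur)
        if (!same) reasons <- c(reasons, "input-changed")
      }
    }
    if (any(n$parents %in% stale_ids) && !"input-changed" %in% reasons) {
      reasons <- c(reasons, "input-changed")
    }
    if (length(reasons)) stale_ids <<- c(stale_ids, n$id)
    tibble(id = n$id, stage = n$stage, dataset_id = n$dataset_id,
           status = if (length(reasons)) "stale" else "fresh",
           reasons = list(reasons))
  })
  out <- bind_rows(rows)
  attr(out, "nodes") <- nodes
  out
}

# ---- stage executors --------------------------------------------------------

exec_map <- function(n, cfg, ws) {
  raw <- parse_expression_table(file.path(ws, n$inputs[1]))
  gm <- parse_gene_map(file.path(ws, n$inputs[2]),
                       target_namespace = cfg$target_namespace)
  res <- map_expression(raw, gm)
  write_expression_table(res$mapped, guard_output(ws, n$outputs[1]),
                         overwrite = TRUE)
  auto <- read_metadata(file.path(ws, n$inputs[3]))
  rec <- if (length(n$inputs) >= 4) {
    merge_metadata(auto, read_metadata(file.path(ws, n$inputs[4])))
  } else auto
  rec$pairs$mapping <- as.list(res$report[1, ])
  write_metadata(rec, guard_output(ws, n$outputs[2]))
}

exec_normalize <- function(n, cfg, ws) {
  recipe <- parse_recipe(cfg$recipe)
  x <- parse_expression_table(file.path(ws, n$inputs[1]))
  for (i in seq_len(nrow(recipe))) {
    step <- recipe$step[i]
    if (step == "log2") x <- transform_log2(x)
    if (step == "zscore") x <- zscore_rows(x)$zscores
    if (step == "knn") x <- impute_knn(x, k_impute = recipe$k[i])$imputed
  }
  write_expression_table(x, guard_output(ws, n$outputs[1]), overwrite = TRUE)
}

exec_coexpr <- function(n, cfg, ws) {
  x <- parse_expression_table(file.path(ws, n$inputs[1]))
  net <- build_coexpression_network(x, dataset_id = n$dataset_id)
  write_network(net, guard_output(ws, n$outputs[1]), overwrite = TRUE)
}

exec_integrate <- function(n, cfg, ws) {
  nets <- list()
  for (rel in n$inputs) {
    if (grepl("coexpr\\.tsv$", rel)) {
      nets[[length(nets) + 1]] <- standardize_edge_weights(
        read_network(file.path(ws, rel), net_type = "coexpression",
                     complete = TRUE),
        binary_confidence = cfg$integration$binary_confidence)
    } else if (startsWith(rel, "networks/") || startsWith(rel, "networks\\")) {
      src <- basename(dirname(rel))
      gm <- parse_gene_map(file.path(ws, "maps", paste0(src, ".tsv")))
      raw_net <- read_network(file.path(ws, rel), net_type = "physical")
      nets[[length(nets) + 1]] <- standardize_edge_weights(
        map_network(raw_net, gm)$mapped,
        binary_confidence = cfg$integration$binary_confidence)
    }
  }
  combined <- integrate_networks(nets, average_mode = cfg$integration$average_mode)
  write_network(combined, guard_output(ws, n$outputs[1]), overwrite = TRUE)
}

exec_query <- function(n, cfg, ws) {
  net <- read_network(file.path(ws, n$inputs[1]), net_type = "functional")
  sg <- extract_subgraph(net, cfg$query$genes, cfg$query$k)
  guard_output(ws, n$outputs[1])
  guard_output(ws, n$outputs[2])
  write_subgraph(sg, file.path(ws, "query"), overwrite = TRUE)
}

exec_meta <- function(n, cfg, ws) {
  mapped <- n$inputs[grepl("mapped\\.tsv$", n$inputs)]
  recipe <- parse_recipe(cfg$recipe)
  effects <- bind_rows(lapply(mapped, function(rel) {
    ds <- basename(dirname(rel))
    x <- parse_expression_table(file.path(ws, rel))
    if ("log2" %in% recipe$step) x <- transform_log2(x)
    rec <- read_metadata(file.path(ws, dirname(rel), "metadata.merged.json"))
    cond <- unlist(rec$pairs$sample_conditions)
    if (is.null(cond)) {
      abort(sprintf("Dataset %s has no sample_conditions metadata.", ds))
    }
    per_dataset_effects(x, cond, dataset_id = ds)
  }))
  meta <- meta_analyze(effects, method = cfg$meta$method)
  write_tsv_plain(meta, guard_output(ws, n$outputs[1]))
  forest <- effects |>
    select("gene", "dataset_id", "y", "ci_low", "ci_high") |>
    arrange(.data$gene, .data$dataset_id)
  write_tsv_plain(forest, guard_output(ws, n$outputs[2]))
  if (!is.null(cfg$meta$gmt)) {
    sets <- read_gmt(file.path(ws, cfg$meta$gmt))
    enr <- enrich_gene_sets(meta, sets, B = cfg$meta$B, seed = cfg$seed)
    write_tsv_plain(enr, guard_output(ws, n$outputs[3]))
  }
}

#' Run the pipeline, executing only stale stages
#'
#' Executes the stale nodes of [plan_build()] in topological order:
#' selection and gene mapping, the recipe-driven normalization chain,
#' co-expression network construction, integration, and (when configured)
#' subgraph query, meta-analysis and enrichment. Each executed node appends
#' MD5 provenance; a failing node halts only its downstream subtree. A
#' second invocation on an unchanged workspace executes nothing.
#'
#' @param cfg A `pipeline_config`.
#' @param workspace Workspace directory.
#' @param force Re-execute every node regardless of staleness.
#' @return A run-report tibble: `id`, `stage`, `status`
#'   (`executed`/`fresh`/`failed`/`skipped`), `detail`.
#' @export
run_pipeline <- function(cfg, workspace, force = FALSE) {
  plan <- plan_build(cfg, workspace)
  nodes <- attr(plan, "nodes")
  exec <- list(map = exec_map, normalize = exec_normalize,
               coexpr = exec_coexpr, integrate = exec_integrate,
               query = exec_query, meta = exec_meta)
  failed <- character(0)
  rows <- list()
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]
    stale <- force || plan$status[plan$id == n$id] == "stale"
    if (any(n$parents %in% failed)) {
      failed <- c(failed, n$id)
      rows[[i]] <- tibble(id = n$id, stage = n$stage, status = "skipped",
                          detail = "upstream failure")
      next
    }
    if (!stale) {
      rows[[i]] <- tibble(id = n$id, stage = n$stage, status = "fresh",
                          detail = "")
      next
    }
    res <- tryCatch({
      exec[[n$stage]](n, cfg, workspace)
      digests <- vapply(file.path(workspace, n$inputs), md5_file, character(1))
      names(digests) <- n$inputs
      dir.create(prov_dir(workspace), recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        list(id = n$id, stage = n$stage, config_hash = n$config_hash,
             tool_version = as.character(utils::packageVersion("funcnet")),
             input_checksums = as.list(digests), outputs = n$outputs),
        prov_path(workspace, gsub("[:/]", "_", n$id)), auto_unbox = TRUE)
      add_registry(workspace, n$outputs)
      tibble(id = n$id, stage = n$stage, status = "executed", detail = "")
    }, error = function(e) {
      failed <<- c(failed, n$id)
      tibble(id = n$id, stage = n$stage, status = "failed",
             detail = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  bind_rows(rows)
}

#' Write a pipeline artifact to disk
#'
#' Dispatches on artifact type: expression tibbles, `gene_network`s,
#' `subgraph`s and plain result tables all serialize to deterministic,
#' lexicographically sorted, LF-terminated TSV.
#'
#' @param artifact Expression tibble, `gene_network`, `subgraph`, or data
#'   frame.
#' @param path Output file (or directory, for subgraphs).
#' @param overwrite Overwrite existing files?
#' @return `path`, invisibly.
#' @export
write_outputs <- function(artifact, path, overwrite = FALSE) {
  if (inherits(artifact, "gene_network")) {
    write_network(artifact, path, overwrite = overwrite)
  } else if (inherits(artifact, "subgraph")) {
    write_subgraph(artifact, path, overwrite = overwrite)
  } else if (is.data.frame(artifact) && identical(names(artifact)[1], "gene") &&
             all(vapply(artifact[-1], is.numeric, logical(1)))) {
    write_expression_table(artifact, path, overwrite = overwrite)
  } else if (is.data.frame(artifact)) {
    if (file.exists(path) && !overwrite) {
      abort(sprintf("Refusing to overwrite existing file: %s", path))
    }
    write_tsv_plain(artifact, path)
  } else {
    abort("Unsupported artifact type.")
  }
  invisible(path)
}
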