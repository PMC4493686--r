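#' Parse a two-column gene identifier map
#'
#' Reads a tab-delimited `source -> target` mapping table (probe ids to a
#' shared namespace such as a UniRef90-style label). Comment lines starting
#' with `#` are skipped; duplicate identical rows are deduplicated; a source
#' id mapped to two different targets is an error — ambiguous probes must be
#' resolved upstream rather than guessed at.
#'
#' @param path Path to the TSV file.
#' @param target_namespace Label for the target namespace (default the file
#'   base name).
#' @return A `gene_map`: tibble with columns `source_id`, `target_id` and a
#'   `target_namespace` attribute.
#' @export
parse_gene_map <- function(path, target_namespace = NULL) {
  if (!file.exists(path)) abort(sprintf("Gene map not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(parts)) abort(sprintf("Gene map %s is empty.", path))
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(sprintf("Malformed gene-map row at line %d of %s (expected 2 columns).",
                  lineno[bad[1]], path))
  }
  tab <- distinct(tibble(source_id = map_chr(parts, 1),
                         target_id = map_chr(parts, 2)))
  if (any(!nzchar(tab$source_id)) || any(!nzchar(tab$target_id))) {
    abort(sprintf("Empty identifier in gene map %s.", path))
  }
  dup <- tab$source_id[duplicated(tab$source_id)]
  if (length(dup)) {
    abort(sprintf("Conflicting targets for source id(s) in %s: %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  structure(tab, class = c("gene_map", class(tibble())),
            target_namespace = target_namespace %||%
              sub("\\.[^.]*$", "", basename(path)))
}

new_mapping_report <- function(n_input, n_mapped, n_merged_groups,
                               threshold = 0.5) {
  tibble(n_input = n_input, n_mapped = n_mapped,
         n_unmapped = n_input - n_mapped, n_merged_groups = n_merged_groups,
         success = n_mapped / n_input >= threshold)
}

#' Map expression rows onto a target gene namespace
#'
#' Rows whose id has no map entry are dropped and counted unmapped; rows
#' mapping to the same target gene are merged by element-wise mean over
#' non-missing values (a merged cell is missing only when missing in every
#' contributing row). Output rows are sorted by target id.
#'
#' @param x Expression tibble (row ids in the source namespace).
#' @param gm A `gene_map` from [parse_gene_map()].
#' @param success_threshold Mapped fraction at or above which the mapping is
#'   recorded as successful (default 0.5).
#' @return A list with `mapped` (expression tibble in the target namespace)
#'   and `report` (n_input / n_mapped / n_unmapped / n_merged_groups /
#'   success).
#' @export
map_expression <- function(x, gm, success_threshold = 0.5) {
  check_expr(x)
  m <- expr_to_matrix(x)
  tgt <- gm$target_id[match(rownames(m), gm$source_id)]
  mapped <- !is.na(tgt)
  if (!any(mapped)) abort("no rows mapped")
  mm <- m[mapped, , drop = FALSE]
  grp <- tgt[mapped]
  ug <- sort(unique(grp))
  gi <- match(grp, ug)
  cnt <- rowsum(1 * !is.na(mm), gi)
  tot <- rowsum(ifelse(is.na(mm), 0, mm), gi)
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  rownames(out) <- ug
  report <- new_mapping_report(
    n_input = nrow(m), n_mapped = sum(mapped),
    n_merged_groups = sum(table(gi) > 1), threshold = success_threshold)
  list(mapped = matrix_to_expr(out), report = report)
}

#' Map network endpoints onto a target gene namespace
#'
#' Edges with either endpoint absent from the map are dropped and counted
#' unmapped. Parallel edges created by many-to-one mapping collapse to a
#' single edge carrying the maximum weight (the strongest evidence);
#' self-edges created by merging are dropped.
#'
#' @param net A `gene_network` in the source namespace.
#' @param gm A `gene_map`.
#' @param success_threshold As in [map_expression()], over edges.
#' @return A list with `mapped` (remapped `gene_network`) and `report`.
#' @export
map_network <- function(net, gm, success_threshold = 0.5) {
  if (nrow(net) == 0) abort("Network has no edges.")
  e <- as_tibble(net)
  t1 <- gm$target_id[match(e$gene1, gm$source_id)]
  t2 <- gm$target_id[match(e$gene2, gm$source_id)]
  ok <- !is.na(t1) & !is.na(t2)
  n_mapped <- sum(ok)
  e <- tibble(gene1 = t1[ok], gene2 = t2[ok], weight = e$weight[ok])
  e <- e[e$gene1 != e$gene2, ]
  flip <- e$gene1 > e$gene2
  tmp <- e$gene1[flip]; e$gene1[flip] <- e$gene2[flip]; e$gene2[flip] <- tmp
  collapsed <- e |>
    group_by(.data$gene1, .data$gene2) |>
    summarise(weight = max(.data$weight), n = dplyr::n(), .groups = "drop")
  if (!nrow(collapsed)) abort("Mapped network is empty.")
  uni_map <- gm$target_id[match(net_universe(net), gm$source_id)]
  report <- new_mapping_report(
    n_input = nrow(net), n_mapped = n_mapped,
    n_merged_groups = sum(collapsed$n > 1), threshold = success_threshold)
  list(
    mapped = gene_network(collapsed[, c("gene1", "gene2", "weight")],
                          universe = sort(unique(uni_map[!is.na(uni_map)])),
                          net_type = net_type(net),
                          dataset_id = attr(net, "dataset_id"),
                          complete = FALSE),
    report = report)
}
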