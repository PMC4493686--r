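#' Create a metadata record
#'
#' Datasets are annotated by an unordered collection of nested key-value
#' pairs: scalars, lists, or further nested mappings, with conventional keys
#' (`taxonomy_id`, `platform`, `title`, `n_samples`, ...) used when known.
#'
#' @param dataset_id Non-empty dataset identifier.
#' @param source Logical repository name the dataset came from.
#' @param pairs Named list of (possibly nested) annotations.
#' @return A `metadata_record`.
#' @export
metadata_record <- function(dataset_id, source = NA_character_, pairs = list()) {
  if (!is.character(dataset_id) || length(dataset_id) != 1 || !nzchar(dataset_id)) {
    abort("`dataset_id` must be a non-empty string.")
  }
  check_pairs <- function(p, path = "pairs") {
    if (!is.list(p)) return(invisible())
    nm <- names(p)
    if (length(p) && (is.null(nm) || any(!nzchar(nm)))) {
      abort(sprintf("All keys under `%s` must be non-empty strings.", path))
    }
    for (k in nm) if (is.list(p[[k]]) && !is.null(names(p[[k]]))) {
      check_pairs(p[[k]], paste0(path, ".", k))
    }
  }
  check_pairs(pairs)
  structure(list(dataset_id = dataset_id, source = source, pairs = pairs),
            class = "metadata_record")
}

#' Merge curated metadata over automatic metadata
#'
#' Computes the recursive union of the two records' pairs. On a key
#' conflict the curated value wins at the deepest level: nested mappings are
#' merged key-wise, while scalars and lists are replaced whole. The merged
#' record carries the reserved key `_curation_applied = TRUE`.
#'
#' @param auto Automatically derived `metadata_record`.
#' @param curated Curated override `metadata_record` for the same dataset.
#' @return The merged `metadata_record`.
#' @export
merge_metadata <- function(auto, curated) {
  if (!identical(auto$dataset_id, curated$dataset_id)) {
    abort(sprintf("dataset_id mismatch: auto '%s' vs curated '%s'.",
                  auto$dataset_id, curated$dataset_id))
  }
  deep <- function(a, c) {
    for (k in names(c)) {
      if (k %in% names(a) && is.list(a[[k]]) && !is.null(names(a[[k]])) &&
          is.list(c[[k]]) && !is.null(names(c[[k]]))) {
        a[[k]] <- deep(a[[k]], c[[k]])
      } else {
        a[[k]] <- c[[k]]
      }
    }
    a
  }
  pairs <- deep(auto$pairs, curated$pairs)
  pairs[["_curation_applied"]] <- TRUE
  metadata_record(auto$dataset_id,
                  source = curated$source %||% auto$source, pairs = pairs)
}

# Fetch a (possibly dotted) key path from nested pairs; NULL when absent.
pairs_get <- function(pairs, key_path) {
  keys <- strsplit(key_path, ".", fixed = TRUE)[[1]]
  cur <- pairs
  for (k in keys) {
    if (!is.list(cur) || is.null(cur[[k]])) return(NULL)
    cur <- cur[[k]]
  }
  cur
}

#' Select datasets matching screening criteria
#'
#' Filters a collection of metadata records the way repository screens are
#' phrased: restrict to NCBI taxonomy ids, honour include/exclude lists,
#' require a minimum sample count, and require every case-insensitive regex
#' pattern to match the value at its (dotted) key path. A missing key path
#' simply fails that pattern; non-string values are matched against their
#' canonical decimal rendering.
#'
#' @param records List of `metadata_record`s.
#' @param taxa Optional vector of taxonomy ids to keep.
#' @param include_ids,exclude_ids Optional id whitelist / blacklist
#'   (must be disjoint).
#' @param patterns Optional list of `list(key_path=, regex=)` entries that
#'   must all match.
#' @param min_samples Optional minimum `n_samples`.
#' @return Character vector of matching dataset ids, in input order.
#' @export
select_datasets <- function(records, taxa = NULL, include_ids = NULL,
                            exclude_ids = NULL, patterns = list(),
                            min_samples = NULL) {
  if (!length(records)) abort("`records` must be non-empty.")
  if (length(intersect(include_ids, exclude_ids))) {
    abort("`include_ids` and `exclude_ids` must be disjoint.")
  }
  for (p in patterns) {
    ok <- tryCatch({grepl(p$regex, "x", ignore.case = TRUE, perl = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("Invalid regex in pattern for key '%s': %s",
                           p$key_path, p$regex))
  }
  keep <- vapply(records, function(r) {
    if (!is.null(taxa)) {
      tx <- pairs_get(r$pairs, "taxonomy_id")
      if (is.null(tx) || !(as.numeric(tx) %in% as.numeric(taxa))) return(FALSE)
    }
    if (r$dataset_id %in% exclude_ids) return(FALSE)
    if (!is.null(include_ids) && !(r$dataset_id %in% include_ids)) return(FALSE)
    if (!is.null(min_samples)) {
      ns <- pairs_get(r$pairs, "n_samples")
      if (is.null(ns) || as.numeric(ns) < min_samples) return(FALSE)
    }
    for (p in patterns) {
      v <- pairs_get(r$pairs, p$key_path)
      if (is.null(v) || is.list(v)) return(FALSE)
      v <- if (is.character(v)) v else fmt_num(as.numeric(v))
      if (!any(grepl(p$regex, v, ignore.case = TRUE, perl = TRUE))) return(FALSE)
    }
    TRUE
  }, logical(1))
  vapply(records[keep], `[[`, character(1), "dataset_id")
}

#' Write / read metadata records as JSON
#'
#' One UTF-8 JSON object per dataset with reserved top-level keys
#' `dataset_id`, `source`, `pairs` (and optionally `provenance`); the nested
#' pairs round-trip losslessly.
#'
#' @param record A `metadata_record`.
#' @param path File path.
#' @return `path` (write) or a `metadata_record` (read).
#' @export
write_metadata <- function(record, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(dataset_id = record$dataset_id, source = record$source,
         pairs = record$pairs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  simplify <- function(x) {
    if (!is.list(x)) return(x)
    if (is.null(names(x))) {
      # plain array: collapse to an atomic vector when homogeneous scalars
      if (all(vapply(x, function(e) !is.list(e) && length(e) == 1, logical(1)))) {
        return(unlist(x))
      }
      return(lapply(x, simplify))
    }
    lapply(x, simplify)
  }
  metadata_record(obj$dataset_id,
                  source = if (is.null(obj$source)) NA_character_ else obj$source,
                  pairs = simplify(obj$pairs %||% list()))
}

#' Create an empty provenance log
#'
#' Provenance is an append-only list of processing steps, each recording the
#' command run, the running tool version, and MD5 checksums of every input
#' file, sufficient to decide later whether an output is stale.
#'
#' @return A `provenance_log` with no steps.
#' @export
provenance_log <- function() {
  structure(list(steps = list()), class = "provenance_log")
}

#' Append a processing step to a provenance log
#'
#' Computes fresh MD5 digests of all input paths. An unreadable path yields a
#' step appended with `status = "failed"` and the offending path in
#' `detail`. Value semantics: the input log is never modified.
#'
#' @param log A `provenance_log`.
#' @param step_name Short step identifier.
#' @param command Human-readable command string.
#' @param input_paths Character vector of input file paths.
#' @param status Step status; default `"ok"` (forced to `"failed"` on an
#'   unreadable input).
#' @param detail Free-text detail, e.g. a gene-mapping success status.
#' @return The extended `provenance_log`.
#' @export
record_step <- function(log, step_name, command, input_paths = character(0),
                        status = "ok", detail = "") {
  digests <- vapply(input_paths, md5_file, character(1))
  if (anyNA(digests)) {
    status <- "failed"
    detail <- sprintf("unreadable input(s): %s; %s",
                      paste(input_paths[is.na(digests)], collapse = ", "),
                      detail)
  }
  step <- list(step_name = step_name,
               tool_version = as.character(utils::packageVersion("funcnet")),
               command = command,
               input_checksums = as.list(digests),
               status = status, detail = detail)
  log$steps <- c(log$steps, list(step))
  log
}

#' @rdname provenance_log
#' @param x A `provenance_log`.
#' @param ... Unused.
#' @method tidy provenance_log
#' @export
tidy.provenance_log <- function(x, ...) {
  if (!length(x$steps)) {
    return(tibble(step_name = character(), tool_version = character(),
                  command = character(), status = character(),
                  detail = character(), input_checksums = list()))
  }
  bind_rows(lapply(x$steps, function(s) {
    tibble(step_name = s$step_name, tool_version = s$tool_version,
           command = s$command, status = s$status, detail = s$detail,
           input_checksums = list(s$input_checksums))
  }))
}

#' @export
print.provenance_log <- function(x, ...) {
  cat(sprintf("<provenance_log> %d step(s)\n", length(x$steps)))
  print(tidy(x))
  invisible(x)
}
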