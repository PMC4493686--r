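# Internal helpers shared across modules.

# MD5 digest of a file; NA_character_ when unreadable.
md5_file <- function(path) {
  if (!file.exists(path) || dir.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

# MD5 digest of an arbitrary R object via its canonical JSON rendering.
md5_obj <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(as.character(json), tmp, sep = "")
  unname(tools::md5sum(tmp))
}

# Canonical decimal rendering used for text output and pattern stringification:
# locale-independent '.' separator, no scientific notation surprises.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.10g", v)
  }, character(1))
  out
}

# Deterministic TSV writer: LF endings, trailing newline, no quoting.
write_tsv_plain <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(unname(df), sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# Validate that `x` looks like an expression tibble: `gene` column first,
# numeric sample columns after it.
check_expr <- function(x, arg = "x") {
  if (!is.data.frame(x) || !"gene" %in% names(x) || names(x)[1] != "gene") {
    abort(sprintf("`%s` must be a data frame whose first column is `gene`.", arg))
  }
  samp <- setdiff(names(x), "gene")
  if (length(samp) == 0) abort(sprintf("`%s` has no sample columns.", arg))
  bad <- samp[!vapply(x[samp], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("Non-numeric sample column(s) in `%s`: %s", arg,
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(x$gene)) {
    abort(sprintf("Duplicate gene ids in `%s`: %s", arg,
                  paste(unique(x$gene[duplicated(x$gene)]), collapse = ", ")))
  }
  invisible(x)
}

# Expression tibble -> numeric matrix (genes x samples) and back.
expr_to_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene
  m
}

matrix_to_expr <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  tibble(gene = rownames(m)) |> dplyr::bind_cols(out)
}
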