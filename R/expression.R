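#' Read a gene-by-sample expression table
#'
#' Parses a tab-delimited expression matrix: a header row of sample ids, one
#' row per gene with the gene id in the first column. Empty cells and `"NA"`
#' are treated as missing. Duplicate gene ids are rejected — merging of
#' duplicate entries happens only through identifier mapping
#' ([map_expression()]), never silently at parse time.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `gene` followed by one numeric
#'   column per sample.
#' @export
parse_expression_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Expression file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort(sprintf("Expression table %s has no data rows.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("Duplicate sample ids in %s", path))
  }
  rows <- fields[-1]
  widths <- lengths(rows)
  # A trailing empty cell is dropped by strsplit; pad rows one short.
  rows <- lapply(rows, function(r) c(r, rep("", max(0, n_col - length(r)))))
  bad <- which(widths > n_col | widths < n_col - 1)
  if (length(bad)) {
    abort(sprintf("Ragged row at line %d of %s: %d fields where %d expected.",
                  bad[1] + 1L, path, widths[bad[1]], n_col))
  }
  gene_ids <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("Duplicate gene id '%s' at line %d of %s.",
                  gene_ids[duplicated(gene_ids)][1],
                  which(duplicated(gene_ids))[1] + 1L, path))
  }
  cells <- t(vapply(rows, function(r) r[-1], character(n_col - 1L)))
  if (n_col == 2L) cells <- matrix(vapply(rows, function(r) r[2], character(1)), ncol = 1)
  miss <- cells == "" | cells == "NA"
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad_cell <- which(is.na(vals) & !miss, arr.ind = TRUE)
  if (nrow(bad_cell)) {
    abort(sprintf("Non-numeric cell '%s' at line %d, column %s of %s.",
                  cells[bad_cell[1, 1], bad_cell[1, 2]],
                  bad_cell[1, 1] + 1L, sample_ids[bad_cell[1, 2]], path))
  }
  vals[miss] <- NA_real_
  colnames(vals) <- sample_ids
  rownames(vals) <- gene_ids
  matrix_to_expr(vals)
}

#' Write an expression tibble as TSV
#'
#' Deterministic output: rows sorted by gene id, `.` decimal separator, LF
#' line endings, missing values written as empty cells.
#'
#' @param x Expression tibble (`gene` column + numeric sample columns).
#' @param path Output path.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, overwrite = FALSE) {
  check_expr(x)
  if (file.exists(path) && !overwrite) {
    abort(sprintf("Refusing to overwrite existing file: %s", path))
  }
  x <- arrange(x, .data$gene)
  df <- as.data.frame(x)
  for (j in seq(2, ncol(df))) {
    v <- fmt_num(df[[j]])
    v[v == "NA"] <- ""
    df[[j]] <- v
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Log2-transform expression values
#'
#' Applies `x -> log2(x + shift)` elementwise, preserving missing values.
#' Used when raw intensities arrive on a linear scale.
#'
#' @param x Expression tibble.
#' @param shift Pseudo-count added before the logarithm (default 1).
#' @return Transformed expression tibble.
#' @export
transform_log2 <- function(x, shift = 1) {
  check_expr(x)
  m <- expr_to_matrix(x)
  bad <- which(!is.na(m) & m + shift <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    loc <- apply(head(bad, 5), 1, function(i) {
      sprintf("%s/%s", rownames(m)[i[1]], colnames(m)[i[2]])
    })
    abort(sprintf(
      "log2 undefined for %d cell(s) with value + shift <= 0 (e.g. %s).",
      nrow(bad), paste(loc, collapse = ", ")))
  }
  matrix_to_expr(log2(m + shift))
}

#' Per-gene z-score normalization
#'
#' Centers and scales each gene's expression vector to mean 0 and standard
#' deviation 1 across its observed samples (n-1 denominator). Genes with
#' fewer than 3 observed values are dropped and counted; constant genes
#' (sd = 0) are set to all zeros and flagged rather than dropped.
#'
#' @param x Expression tibble.
#' @return A list with elements:
#'   * `zscores` — the standardized expression tibble (missing preserved);
#'   * `stats` — per-gene tibble of `mean`, `sd`, `n_observed`, `constant`;
#'   * `dropped` — character vector of genes with < 3 observed values.
#' @export
zscore_rows <- function(x) {
  check_expr(x)
  m <- expr_to_matrix(x)
  if (ncol(m) < 2) abort("z-scoring requires at least 2 samples.")
  n_obs <- rowSums(!is.na(m))
  dropped <- rownames(m)[n_obs < 3]
  m <- m[n_obs >= 3, , drop = FALSE]
  if (nrow(m) == 0) abort("No gene has >= 3 observed values.")
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, sd, na.rm = TRUE)
  constant <- sdv == 0
  z <- (m - mu) / ifelse(constant, 1, sdv)
  if (any(constant)) {
    zc <- m[constant, , drop = FALSE]
    zc[!is.na(zc)] <- 0
    z[constant, ] <- zc
  }
  stats <- tibble(
    gene = rownames(m), mean = unname(mu), sd = unname(sdv),
    n_observed = rowSums(!is.na(m)), constant = unname(constant))
  list(zscores = matrix_to_expr(z), stats = stats, dropped = dropped)
}

#' Impute missing values from k nearest neighbour genes
#'
#' For each missing cell the candidate neighbours are other genes observed in
#' that sample that share at least `min_shared` observed samples with the
#' target gene. Distance is root-mean-square difference over the shared
#' observed samples (the per-column normalization makes genes with different
#' missingness comparable); the `k_impute` nearest candidates contribute a
#' weighted average with weights proportional to `1 / (distance + epsilon)`.
#' With no candidates the gene's observed mean is used and flagged as a
#' fallback. Expects row-standardized input ([zscore_rows()]).
#'
#' @param x Row-standardized expression tibble.
#' @param k_impute Neighbour count (default 10).
#' @param epsilon Regularizer added to distances (default 1e-6).
#' @param min_shared Minimum shared observed samples for a neighbour
#'   (default 3).
#' @return A list with `imputed` (complete expression tibble; observed cells
#'   untouched) and `report` (one row per imputed cell: `gene`, `sample`,
#'   list-columns `neighbors`, `distances`, `weights`, and `fallback_used`).
#' @export
impute_knn <- function(x, k_impute = 10, epsilon = 1e-6, min_shared = 3) {
  check_expr(x)
  if (k_impute < 1) abort("`k_impute` must be >= 1.")
  if (epsilon <= 0) abort("`epsilon` must be > 0.")
  m <- expr_to_matrix(x)
  obs <- !is.na(m)
  if (any(rowSums(obs) == 0)) {
    abort(sprintf("Gene(s) with no observed values (drop upstream): %s",
                  paste(rownames(m)[rowSums(obs) == 0], collapse = ", ")))
  }
  miss_idx <- which(!obs, arr.ind = TRUE)
  out <- m
  rep_rows <- vector("list", nrow(miss_idx))
  if (nrow(miss_idx)) {
    genes_missing <- unique(miss_idx[, 1])
    m0 <- m
    m0[!obs] <- 0
    row_means <- rowSums(m0) / rowSums(obs)
    for (g in genes_missing) {
      # RMS distance from gene g to every other gene over shared observed cols
      shared <- obs %*% obs[g, ]                       # m_gh per gene
      diff <- sweep(m0, 2, m0[g, ])
      diff[!obs | !matrix(obs[g, ], nrow(m), ncol(m), byrow = TRUE)] <- 0
      d2 <- rowSums(diff^2) / ifelse(shared > 0, shared, NA)
      d <- sqrt(d2)
      cols <- miss_idx[miss_idx[, 1] == g, 2]
      for (j in cols) {
        cand <- which(obs[, j] & shared >= min_shared & seq_len(nrow(m)) != g &
                        is.finite(d))
        ri <- which(miss_idx[, 1] == g & miss_idx[, 2] == j)
        if (length(cand) == 0) {
          out[g, j] <- row_means[g]
          rep_rows[[ri]] <- tibble(
            gene = rownames(m)[g], sample = colnames(m)[j],
            neighbors = list(character(0)), distances = list(numeric(0)),
            weights = list(numeric(0)), fallback_used = TRUE)
          next
        }
        ord <- cand[order(d[cand], rownames(m)[cand])]
        nb <- head(ord, k_impute)
        w <- 1 / (d[nb] + epsilon)
        w <- w / sum(w)
        out[g, j] <- sum(w * m[nb, j])
        rep_rows[[ri]] <- tibble(
          gene = rownames(m)[g], sample = colnames(m)[j],
          neighbors = list(rownames(m)[nb]), distances = list(unname(d[nb])),
          weights = list(unname(w)), fallback_used = FALSE)
      }
    }
  }
  report <- if (length(rep_rows)) bind_rows(rep_rows) else
    tibble(gene = character(), sample = character(), neighbors = list(),
           distances = list(), weights = list(), fallback_used = logical())
  list(imputed = matrix_to_expr(out), report = report)
}

#' Build a co-expression network from a complete expression matrix
#'
#' Computes Pearson correlation for every unordered gene pair across all
#' samples, applies the Fisher z transform `atanh(r)` (with `|r|` clamped
#' below 1), and standardizes the transformed values across all pairs within
#' the dataset to mean 0 and sd 1 — these standardized values are the
#' normalized co-expression z-scores that downstream integration averages.
#' The returned network is complete (every pair scored).
#'
#' @param x Complete (post-imputation) expression tibble with >= 3 genes and
#'   >= 4 samples.
#' @param dataset_id Identifier stored on the network (default `NA`).
#' @param report_threshold Default `|z|` threshold applied when the network
#'   is written with `threshold = TRUE`; stored as an attribute (default 2).
#' @return A `gene_network` edge tibble (`gene1`, `gene2`, `weight`) with
#'   `net_type = "coexpression"` and `complete = TRUE`.
#' @export
build_coexpression_network <- function(x, dataset_id = NA_character_,
                                       report_threshold = 2) {
  check_expr(x)
  m <- expr_to_matrix(x)
  if (anyNA(m)) abort("Matrix has missing values; impute before building the network.")
  if (nrow(m) < 3) abort("Need >= 3 genes.")
  if (ncol(m) < 4) abort("Need >= 4 samples.")
  sdv <- apply(m, 1, sd)
  if (any(sdv == 0)) {
    abort(sprintf("Zero-variance gene(s) %s: z-score the matrix upstream.",
                  paste(rownames(m)[sdv == 0], collapse = ", ")))
  }
  r <- cor(t(m))
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  fz <- atanh(r)
  ut <- upper.tri(fz)
  vals <- fz[ut]
  z <- (vals - mean(vals)) / sd(vals)
  idx <- which(ut, arr.ind = TRUE)
  edges <- tibble(gene1 = rownames(m)[idx[, 1]], gene2 = rownames(m)[idx[, 2]],
                  weight = z)
  gene_network(edges, universe = rownames(m), net_type = "coexpression",
               dataset_id = dataset_id, complete = TRUE,
               report_threshold = report_threshold)
}

#' Quality-control summary of an expression matrix
#'
#' Pure report, no mutation: per-sample mean, sd and missing fraction, and
#' per-gene missing fraction.
#'
#' @param x Expression tibble.
#' @return A list of two tibbles, `samples` and `genes`.
#' @export
qc_summary <- function(x) {
  check_expr(x)
  m <- expr_to_matrix(x)
  list(
    samples = tibble(
      sample = colnames(m),
      mean = unname(colMeans(m, na.rm = TRUE)),
      sd = unname(apply(m, 2, sd, na.rm = TRUE)),
      missing_frac = unname(colMeans(is.na(m)))),
    genes = tibble(
      gene = rownames(m),
      missing_frac = unname(rowMeans(is.na(m)))))
}
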