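test_that("expression tables parse with missing cells and strict validation", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "e.tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\tNA\t4", "g3\t5\t"), f)
  x <- parse_expression_table(f)
  expect_equal(dim(x), c(3, 3))
  expect_true(is.na(x$s1[x$gene == "g2"]))
  expect_true(is.na(x$s2[x$gene == "g3"]))
  expect_equal(x$s2[x$gene == "g2"], 4)

  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(parse_expression_table(f), "Duplicate gene id")
  writeLines(c("gene\ts1\ts2", "g1\t1\toops"), f)
  expect_error(parse_expression_table(f), "Non-numeric")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2\t3\t4"), f)
  expect_error(parse_expression_table(f), "Ragged")
})

test_that("expression tables round-trip through the writer", {
  x <- rand_expr(15, 6, seed = 3, missing_rate = 0.15)
  f <- file.path(withr::local_tempdir(), "rt.tsv")
  write_expression_table(x, f)
  back <- parse_expression_table(f)
  expect_equal(back, dplyr::arrange(x, gene), tolerance = 1e-9)
  expect_error(write_expression_table(x, f), "Refusing")
})

test_that("log2 transform shifts then logs, preserving missing", {
  x <- tibble::tibble(gene = c("g1", "g2", "g3"),
                      s1 = c(1, 0, 7), s2 = c(NA, 3, 15))
  y <- transform_log2(x)
  expect_equal(y$s1, c(1, 0, 3))              # log2(2), log2(1), log2(8)
  expect_true(is.na(y$s2[1]))
  expect_equal(y$s2[3], 4)
  expect_error(transform_log2(tibble::tibble(gene = "g", s1 = -2, s2 = 0)),
               "log2 undefined")
})

test_that("z-scoring standardizes observed entries and handles degeneracy", {
  x <- tibble::tibble(gene = c("rowA", "const", "gaps"),
                      s1 = c(1, 5, 2), s2 = c(2, 5, NA),
                      s3 = c(3, 5, 4), s4 = c(NA, 5, 6))
  z <- zscore_rows(x)
  za <- unlist(z$zscores[z$zscores$gene == "rowA", -1])
  expect_equal(unname(za[1:3]), c(-1, 0, 1))  # mean 2, sd (n-1) = 1
  zc <- unlist(z$zscores[z$zscores$gene == "const", -1])
  expect_equal(unname(zc), c(0, 0, 0, 0))
  expect_true(z$stats$constant[z$stats$gene == "const"])
  # observed subset (2, 4, 6): mean 4, sd 2
  zg <- unlist(z$zscores[z$zscores$gene == "gaps", -1])
  expect_equal(unname(zg), c(-1, NA, 0, 1))

  # genes with < 3 observed values are dropped and reported
  x2 <- dplyr::bind_rows(x, tibble::tibble(gene = "thin", s1 = 1, s2 = 2,
                                           s3 = NA, s4 = NA))
  z2 <- zscore_rows(x2)
  expect_false("thin" %in% z2$zscores$gene)
  expect_equal(z2$dropped, "thin")
})

test_that("z-scored rows have mean 0 and sd 1 over observed entries", {
  x <- rand_expr(60, 15, seed = 11, missing_rate = 0.1)
  z <- zscore_rows(x)$zscores
  m <- expr_mat(z)
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, sd, na.rm = TRUE)
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(sdv - 1) < 1e-9))
})

test_that("kNN imputation reproduces a zero-distance duplicate and leaves observed cells intact", {
  base <- zscore_rows(rand_expr(8, 10, seed = 5))$zscores
  m <- expr_mat(base)
  m["g002", ] <- m["g001", ]                 # exact duplicate pair (d = 0)
  m["g001", 4] <- NA
  x <- tibble::as_tibble(cbind(tibble::tibble(gene = rownames(m)),
                               as.data.frame(m)))
  res <- impute_knn(x, k_impute = 1)
  mi <- expr_mat(res$imputed)
  mz <- expr_mat(x)
  expect_lt(abs(mi["g001", 4] - mz["g002", 4]), 1e-4)
  # observed cells bit-identical
  obs <- !is.na(mz)
  expect_identical(mi[obs], mz[obs])
  expect_equal(sum(is.na(mi)), 0)
  expect_equal(res$report$gene, "g001")
  expect_false(res$report$fallback_used)
  expect_equal(sum(unlist(res$report$weights)), 1)
})

test_that("a complete matrix passes through imputation unchanged", {
  x <- zscore_rows(rand_expr(10, 8, seed = 9))$zscores
  res <- impute_knn(x)
  expect_equal(res$imputed, x)
  expect_equal(nrow(res$report), 0)
})

test_that("imputed values match the brute-force inverse-distance oracle", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      x <- zscore_rows(rand_expr(12, 9, seed = 100 + rep,
                                 missing_rate = 0.12))$zscores
      m <- expr_mat(x)
      res <- impute_knn(x, k_impute = 2, min_shared = 3)
      mi <- expr_mat(res$imputed)
      holes <- which(is.na(m), arr.ind = TRUE)
      for (r in seq_len(nrow(holes))) {
        g <- holes[r, 1]; j <- holes[r, 2]
        expected <- brute_impute_cell(m, g, j, k = 2)
        if (!is.na(expected)) {
          expect_equal(mi[g, j], expected, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("co-expression weights derive from Pearson r matching a textbook oracle", {
  x <- gen_expression_dataset(n_genes = 4, n_samples = 6, n_modules = 1,
                              module_size = 2, rho = 0.8, missing_rate = 0,
                              seed = 17)$matrix
  m <- expr_mat(x)
  net <- build_coexpression_network(x)
  # recompute the chain: brute-force r -> atanh -> standardize over pairs
  pairs <- t(combn(rownames(m), 2))
  r <- apply(pairs, 1, function(p) brute_pearson(m[p[1], ], m[p[2], ]))
  t_vals <- atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
  z <- (t_vals - mean(t_vals)) / sd(t_vals)
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  net_key <- paste(net$gene1, net$gene2)
  expect_equal(net$weight, z[match(net_key, key)], tolerance = 1e-12)
})

test_that("co-expression networks are standardized, symmetric in construction, and rank identical profiles first", {
  x <- rand_expr(10, 8, seed = 23)
  m <- expr_mat(x)
  m["g002", ] <- m["g001", ] + 0.5           # perfectly correlated pair
  x <- tibble::as_tibble(cbind(tibble::tibble(gene = rownames(m)),
                               as.data.frame(m)))
  net <- build_coexpression_network(x)
  expect_lt(abs(mean(net$weight)), 1e-9)
  expect_lt(abs(sd(net$weight) - 1), 1e-9)
  top <- net[which.max(net$weight), ]
  expect_equal(c(top$gene1, top$gene2), c("g001", "g002"))
  expect_equal(nrow(net), choose(10, 2))     # complete

  # invariant to a simultaneous permutation of samples
  perm <- withr::with_seed(1, sample(colnames(m)))
  xp <- x[, c("gene", perm)]
  netp <- build_coexpression_network(xp)
  expect_equal(netp$weight, net$weight, tolerance = 1e-12)

  xc <- x; xc[2, -1] <- as.list(rep(1, 8))
  expect_error(build_coexpression_network(xc), "Zero-variance")
})

test_that("QC summary fractions agree with a direct recount", {
  x <- rand_expr(20, 6, seed = 13, missing_rate = 0.2)
  qc <- qc_summary(x)
  m <- expr_mat(x)
  expect_equal(qc$samples$missing_frac, unname(colMeans(is.na(m))))
  expect_equal(qc$genes$missing_frac, unname(rowMeans(is.na(m))))
  expect_equal(qc$samples$mean, unname(colMeans(m, na.rm = TRUE)))

  complete <- rand_expr(5, 4, seed = 2)
  expect_true(all(qc_summary(complete)$samples$missing_frac == 0))

  x2 <- tibble::tibble(gene = c("g1", "g2"), s1 = c(NA, 1), s2 = c(2, 3))
  expect_equal(sort(qc_summary(x2)$samples$missing_frac), c(0, 0.5))
})
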