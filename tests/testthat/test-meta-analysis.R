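test_that("per-dataset effects implement the Welch contrast with normal CIs", {
  x <- tibble::tibble(gene = "g1", c1 = 3, c2 = 5, t1 = 1, t2 = 3)
  cond <- c(c1 = "case", c2 = "case", t1 = "control", t2 = "control")
  eff <- per_dataset_effects(x, cond)
  expect_equal(eff$y, 2)                         # mean(3,5) - mean(1,3)
  expect_equal(eff$v, 2/2 + 2/2)                 # s2/n per group
  expect_equal(eff$ci_low, 2 - qnorm(0.975) * sqrt(2), tolerance = 1e-9)
  expect_equal(eff$ci_high, 2 + qnorm(0.975) * sqrt(2), tolerance = 1e-9)
  expect_true(eff$ci_low <= eff$y && eff$y <= eff$ci_high)

  # identical groups give a zero effect
  x2 <- tibble::tibble(gene = "g1", c1 = 4, c2 = 6, t1 = 4, t2 = 6)
  expect_equal(per_dataset_effects(x2, cond)$y, 0)

  # degenerate zero variance is floored so pooling stays defined
  x3 <- tibble::tibble(gene = "g1", c1 = 2, c2 = 2, t1 = 1, t2 = 1)
  eff3 <- per_dataset_effects(x3, cond)
  expect_equal(eff3$y, 1)
  expect_equal(eff3$v, 1e-8)
  expect_lt(eff3$ci_high - eff3$ci_low, 1e-3)

  expect_error(per_dataset_effects(x, c(c1 = "case", t1 = "control",
                                        t2 = "control")),
               ">= 2 samples")
})

test_that("genes absent from a group are skipped and counted", {
  x <- tibble::tibble(gene = c("g1", "g2"),
                      c1 = c(1, NA), c2 = c(2, NA),
                      t1 = c(0, 5), t2 = c(1, 6))
  cond <- c(c1 = "case", c2 = "case", t1 = "control", t2 = "control")
  eff <- per_dataset_effects(x, cond)
  expect_equal(eff$gene, "g1")
  expect_equal(attr(eff, "skipped"), "g2")
})

test_that("DerSimonian-Laird pooling matches hand arithmetic exactly", {
  # y = (0, 1, 2), v = 0.1 each: w = 10, ybar = 1, Q = 20,
  # C = 30 - 300/30 = 20, tau2 = (20 - 2)/20 = 0.9
  fit <- pool_random_effects(c(0, 1, 2), c(0.1, 0.1, 0.1), method = "DL")
  expect_equal(fit$q_stat, 20, tolerance = 1e-12)
  expect_equal(fit$c_scale, 20, tolerance = 1e-12)
  expect_equal(fit$tau2, 0.9, tolerance = 1e-12)
  expect_equal(fit$mu_hat, 1, tolerance = 1e-12)
  expect_equal(fit$se_mu, sqrt(1 / (3 / 1)), tolerance = 1e-12)

  # zero heterogeneity collapses to fixed-effect pooling for both estimators
  for (method in c("DL", "REML")) {
    f0 <- pool_random_effects(c(1, 1), c(0.1, 0.1), method = method)
    expect_equal(f0$mu_hat, 1, tolerance = 1e-9)
    expect_equal(f0$tau2, 0, tolerance = 1e-9)
  }

  # Q <= k - 1 means DL reduces to inverse-variance fixed-effect pooling
  fit_fe <- pool_random_effects(c(1.0, 1.01, 0.99), c(0.5, 0.5, 0.5), "DL")
  expect_equal(fit_fe$tau2, 0)
  w <- 1 / c(0.5, 0.5, 0.5)
  expect_equal(fit_fe$mu_hat, sum(w * c(1.0, 1.01, 0.99)) / sum(w))

  expect_error(pool_random_effects(c(1, 2), c(0.1, 0)), "> 0")
})

test_that("REML and DL heterogeneity estimates agree in rank across simulated genes", {
  withr::with_seed(404, {
    k <- 8
    tau2_reml <- tau2_dl <- numeric(100)
    for (i in 1:100) {
      v <- runif(k, 0.01, 0.05)
      y <- rnorm(k, 0.5, sqrt(0.3^2 + v))
      tau2_reml[i] <- pool_random_effects(y, v, "REML")$tau2
      tau2_dl[i] <- pool_random_effects(y, v, "DL")$tau2
    }
    expect_gt(cor(tau2_reml, tau2_dl, method = "spearman"), 0.9)
  })
})

test_that("REML estimates agree with the metafor reference on random inputs", {
  skip_if_not_installed("metafor")
  withr::with_seed(505, {
    for (i in 1:10) {
      k <- sample(4:12, 1)
      v <- runif(k, 0.02, 0.2)
      y <- rnorm(k, 0.3, sqrt(0.2 + v))
      ours <- pool_random_effects(y, v, "REML")
      ref <- suppressWarnings(metafor::rma(yi = y, vi = v, method = "REML"))
      expect_equal(ours$tau2, as.numeric(ref$tau2), tolerance = 1e-3)
      expect_equal(ours$mu_hat, as.numeric(ref$beta), tolerance = 1e-3)
      expect_equal(ours$se_mu, as.numeric(ref$se), tolerance = 1e-3)
    }
  })
})

test_that("single-study genes pass through and the fit object tidies", {
  fit <- pool_random_effects(0.7, 0.04)
  expect_equal(fit$k_studies, 1)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$mu_hat, 0.7)
  td <- broom::tidy(fit)
  expect_equal(nrow(td), 1)
  expect_true(all(c("ci_low", "ci_high") %in% names(td)))
  gl <- broom::glance(fit)
  expect_equal(gl$mu_hat, 0.7)
})

test_that("BH adjustment matches the step-up hand example and is monotone", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(8, {
    p <- runif(50)
    q <- adjust_bh(p)
    perm <- sample(50)
    expect_equal(adjust_bh(p[perm]), q[perm])
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
    expect_true(all(q >= 0 & q <= 1))
  })
})

test_that("gene-wise meta-analysis pools across datasets and adjusts q-values", {
  coll <- gen_case_control_collection(n_datasets = 4, n_genes = 50,
                                      n_per_group = 4, frac_de = 0.2,
                                      mu_de = 2, tau = 0.1, sigma = 0.4,
                                      seed = 21)
  effects <- dplyr::bind_rows(lapply(coll$datasets, function(d) {
    per_dataset_effects(d$matrix, d$conditions, dataset_id = d$dataset_id)
  }))
  meta <- meta_analyze(effects, method = "REML")
  expect_equal(nrow(meta), 50)
  expect_true(all(meta$k_studies == 4))
  expect_true(all(meta$q >= 0 & meta$q <= 1))
  # strongly planted genes dominate the small q-values
  de <- coll$truth$de_genes$gene
  top <- meta$gene[order(meta$q)][seq_along(de)]
  expect_gte(mean(top %in% de), 0.8)
})

test_that("permutation enrichment flags an extreme set and skips tiny sets", {
  withr::with_seed(66, {
    meta <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                           mu_hat = rnorm(200), p = runif(200))
    up <- meta$gene[meta$mu_hat >= 0]
    top_up <- up[order(meta$p[match(up, meta$gene)])][1:20]
    res <- enrich_gene_sets(meta,
                            list(top = top_up, tiny = meta$gene[1:2],
                                 alien = c("x1", "x2", "x3")),
                            B = 1000, seed = 3)
    expect_false(any(res$set_name %in% c("tiny", "alien")))  # skipped
    r_up <- res[res$set_name == "top" & res$direction == "up", ]
    expect_equal(r_up$p_perm, 1 / 1001, tolerance = 1e-12)
    expect_true(all(res$p_perm >= 1 / 1001 & res$p_perm <= 1))
    # reproducible under the same seed
    res2 <- enrich_gene_sets(meta, list(top = top_up), B = 1000, seed = 3)
    expect_equal(res2$p_perm,
                 res$p_perm[res$set_name == "top"])
  })
})

test_that("GMT gene sets parse into a set/genes tibble", {
  f <- file.path(withr::local_tempdir(), "sets.gmt")
  writeLines(c("pathA\tdesc\tg1\tg2\tg3",
               "pathB\tdesc\tg2\tg4\tg5\tg6"), f)
  sets <- read_gmt(f)
  expect_equal(sets$set_name, c("pathA", "pathB"))
  expect_equal(sets$genes[[1]], c("g1", "g2", "g3"))
  expect_length(sets$genes[[2]], 4)
})
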