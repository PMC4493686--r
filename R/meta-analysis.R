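#' Per-dataset differential expression effects
#'
#' Computes, for every gene, the log2 fold change between case and control
#' samples with a Welch-type variance and normal-theory 2.5%/97.5%
#' confidence bounds:
#' `y = mean(case) - mean(control)`, `v = s2_case/n_case + s2_ctrl/n_ctrl`,
#' `CI = y +/- 1.959964 * sqrt(v)`. The matrix must be on the log2 scale and
#' must NOT be z-scored (standardization destroys fold-change units). Genes
#' with no observed value in either group are skipped and counted in the
#' `skipped` attribute. Degenerate zero variances are floored at 1e-8 so
#' downstream pooling stays defined.
#'
#' @param x Log2-scale expression tibble.
#' @param conditions Named character vector mapping sample id to group label.
#' @param case,control Labels identifying the two groups.
#' @param dataset_id Recorded on every returned row.
#' @return Tibble with one row per gene: `gene`, `dataset_id`, `y`, `v`,
#'   `ci_low`, `ci_high`, `n_case`, `n_control`.
#' @export
per_dataset_effects <- function(x, conditions, case = "case",
                                control = "control",
                                dataset_id = NA_character_) {
  check_expr(x)
  m <- expr_to_matrix(x)
  cs <- names(conditions)[conditions == case]
  ct <- names(conditions)[conditions == control]
  cs <- intersect(cs, colnames(m))
  ct <- intersect(ct, colnames(m))
  if (length(cs) < 2 || length(ct) < 2) {
    abort(sprintf("Need >= 2 samples per group (got %d case, %d control).",
                  length(cs), length(ct)))
  }
  mc <- m[, cs, drop = FALSE]
  mt <- m[, ct, drop = FALSE]
  nc <- rowSums(!is.na(mc))
  nt <- rowSums(!is.na(mt))
  ok <- nc >= 2 & nt >= 2
  skipped <- rownames(m)[!ok]
  y <- rowMeans(mc[ok, , drop = FALSE], na.rm = TRUE) -
    rowMeans(mt[ok, , drop = FALSE], na.rm = TRUE)
  vc <- apply(mc[ok, , drop = FALSE], 1, var, na.rm = TRUE)
  vt <- apply(mt[ok, , drop = FALSE], 1, var, na.rm = TRUE)
  v <- pmax(vc / nc[ok] + vt / nt[ok], 1e-8)
  zcrit <- qnorm(0.975)
  out <- tibble(gene = rownames(m)[ok], dataset_id = dataset_id,
                y = unname(y), v = unname(v),
                ci_low = unname(y - zcrit * sqrt(v)),
                ci_high = unname(y + zcrit * sqrt(v)),
                n_case = unname(nc[ok]), n_control = unname(nt[ok]))
  attr(out, "skipped") <- skipped
  out
}

# Restricted log-likelihood of the random-effects model at a given tau2.
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' Pool study effects with a random-effects model
#'
#' Combines per-study effect sizes `y` with variances `v` allowing
#' between-study variance tau^2. Two estimators are available:
#' * `"DL"` — DerSimonian-Laird moment estimator:
#'   `tau2 = max(0, (Q - (k-1)) / C)` with `Q = sum w (y - ybar)^2`,
#'   `C = sum w - sum w^2 / sum w`, `w = 1/v`.
#' * `"REML"` (default) — restricted maximum likelihood by bounded 1-D
#'   search of the restricted log-likelihood on
#'   `[0, 10 * max(var(y), max(v))]` to tolerance 1e-8.
#'
#' Either way the pooled effect is the inverse-variance weighted mean at the
#' estimated tau^2, with `z = mu/se` and a two-sided normal p-value. A single
#' study passes through with `tau2 = 0`.
#'
#' @param y Numeric vector of study effects (log2 fold changes).
#' @param v Positive study variances.
#' @param method `"REML"` or `"DL"`.
#' @return A `rema` object; see [tidy.rema()] and [glance.rema()].
#' @export
pool_random_effects <- function(y, v, method = c("REML", "DL")) {
  method <- match.arg(method)
  if (length(y) != length(v)) abort("`y` and `v` must have equal length.")
  if (any(!is.finite(y)) || any(!is.finite(v))) abort("Non-finite inputs.")
  if (any(v <= 0)) abort("All variances must be > 0.")
  k <- length(y)
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q_stat <- sum(w * (y - ybar)^2)
  c_scale <- sum(w) - sum(w^2) / sum(w)
  tau2_dl <- if (k >= 2) max(0, (q_stat - (k - 1)) / c_scale) else 0
  tau2 <- if (k < 2) {
    0
  } else if (method == "DL") {
    tau2_dl
  } else {
    upper <- 10 * max(var(y), max(v))
    if (upper <= 0) 0 else {
      opt <- optimize(reml_loglik, c(0, upper), y = y, v = v,
                      maximum = TRUE, tol = 1e-8)
      # the interior optimum can miss a boundary maximum at 0
      if (reml_loglik(0, y, v) >= opt$objective) 0 else opt$maximum
    }
  }
  wt <- 1 / (v + tau2)
  mu_hat <- sum(wt * y) / sum(wt)
  se_mu <- sqrt(1 / sum(wt))
  z <- mu_hat / se_mu
  structure(list(mu_hat = mu_hat, se_mu = se_mu, tau2 = tau2, method = method,
                 q_stat = q_stat, c_scale = c_scale, z = z,
                 p = 2 * pnorm(-abs(z)), k_studies = k, y = y, v = v),
            class = "rema")
}

#' @export
print.rema <- function(x, ...) {
  cat(sprintf(
    "<rema %s> k=%d  mu=%.4f (se %.4f)  tau2=%.4f  z=%.3f  p=%.3g\n",
    x$method, x$k_studies, x$mu_hat, x$se_mu, x$tau2, x$z, x$p))
  invisible(x)
}

#' Tidy a random-effects fit
#'
#' `tidy()` returns the per-study rows (forest-plot ready); `glance()` the
#' one-row model summary.
#'
#' @param x A `rema` object.
#' @param ... Unused.
#' @method tidy rema
#' @export
tidy.rema <- function(x, ...) {
  zcrit <- qnorm(0.975)
  tibble(study = seq_along(x$y), y = x$y, v = x$v,
         ci_low = x$y - zcrit * sqrt(x$v), ci_high = x$y + zcrit * sqrt(x$v))
}

#' @rdname tidy.rema
#' @method glance rema
#' @export
glance.rema <- function(x, ...) {
  tibble(mu_hat = x$mu_hat, se_mu = x$se_mu, tau2 = x$tau2, method = x$method,
         q_stat = x$q_stat, c_scale = x$c_scale, z = x$z, p = x$p,
         k_studies = x$k_studies)
}

#' Forest plot of a random-effects fit
#'
#' @param object A `rema` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rema
#' @export
autoplot.rema <- function(object, ...) {
  d <- tidy(object)
  d$study <- factor(d$study, levels = rev(d$study))
  zcrit <- qnorm(0.975)
  pooled <- tibble(study = "pooled", y = object$mu_hat,
                   ci_low = object$mu_hat - zcrit * object$se_mu,
                   ci_high = object$mu_hat + zcrit * object$se_mu)
  ggplot(d, aes(x = .data$y, y = .data$study)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point() +
    geom_point(data = pooled, colour = "red", shape = 18, size = 3) +
    geom_errorbarh(data = pooled,
                   aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.3, colour = "red") +
    labs(x = "log2 fold change", y = "study") +
    theme_minimal()
}

#' Benjamini-Hochberg false-discovery adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min over j >= i of (m * p_(j) / j)`, clipped at 1 and returned in
#' input order.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
adjust_bh <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Gene-wise random-effects meta-analysis across datasets
#'
#' Pools per-dataset effect estimates gene by gene, then applies
#' Benjamini-Hochberg adjustment across all pooled p-values.
#'
#' @param effects Tibble of per-dataset effects
#'   ([per_dataset_effects()] rows, possibly from several datasets).
#' @param method Tau^2 estimator, `"REML"` (default) or `"DL"`.
#' @param min_studies Genes observed in fewer datasets are dropped
#'   (default 2; a gene seen once passes through with `tau2 = 0` when
#'   `min_studies = 1`).
#' @return Tibble with one row per gene: `gene`, `mu_hat`, `se_mu`, `tau2`,
#'   `method`, `q_stat`, `c_scale`, `z`, `p`, `q`, `k_studies`.
#' @export
meta_analyze <- function(effects, method = c("REML", "DL"), min_studies = 2) {
  method <- match.arg(method)
  res <- effects |>
    group_by(.data$gene) |>
    filter(dplyr::n() >= min_studies) |>
    summarise(fit = list(pool_random_effects(.data$y, .data$v, method)),
              .groups = "drop")
  if (!nrow(res)) abort("No gene observed in enough datasets.")
  out <- bind_rows(lapply(res$fit, glance))
  out <- dplyr::bind_cols(tibble(gene = res$gene), out)
  out$q <- adjust_bh(out$p)
  arrange(out, .data$gene)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return Tibble with columns `set_name` and list-column `genes`.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  tibble(set_name = names(sets), genes = unname(sets))
}

#' Permutation gene-set enrichment of meta-analysis p-values
#'
#' Genes are split by the sign of the pooled effect into up- and
#' down-regulated strata (`mu_hat >= 0` counts as up). For each set and
#' direction the observed statistic is the mean of `-ln(p)` over set members
#' in that stratum (0 when none fall there); the null distribution comes
#' from `B` random same-size gene subsets of the same stratum, and
#' `p_perm = (1 + #{null >= observed}) / (B + 1)`. Sets with fewer than 3
#' members in the tested universe are skipped.
#'
#' @param meta Meta-analysis tibble ([meta_analyze()] output: needs `gene`,
#'   `mu_hat`, `p`).
#' @param sets Gene sets as a tibble (`set_name`, list-column `genes`)
#'   or named list.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return Tibble: `set_name`, `direction`, `n_genes`, `observed_stat`,
#'   `n_permutations`, `p_perm`.
#' @export
enrich_gene_sets <- function(meta, sets, B = 1000, seed = 1) {
  if (!nrow(meta)) abort("Empty tested universe.")
  if (is.list(sets) && !is.data.frame(sets)) {
    sets <- tibble(set_name = names(sets), genes = unname(sets))
  }
  strata <- list(up = meta$gene[meta$mu_hat >= 0],
                 down = meta$gene[meta$mu_hat < 0])
  stat <- setNames(-log(pmax(meta$p, .Machine$double.xmin)), meta$gene)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(sets))) {
      members <- intersect(sets$genes[[i]], meta$gene)
      if (length(members) < 3) next
      for (dir in c("up", "down")) {
        stratum <- strata[[dir]]
        mem <- intersect(members, stratum)
        s <- length(mem)
        obs <- if (s) mean(stat[mem]) else 0
        null <- if (s && length(stratum)) {
          vapply(seq_len(B), function(b) {
            mean(stat[sample(stratum, s, replace = FALSE)])
          }, numeric(1))
        } else rep(0, B)
        rows[[length(rows) + 1]] <- tibble(
          set_name = sets$set_name[i], direction = dir, n_genes = s,
          observed_stat = obs, n_permutations = B,
          p_perm = (1 + sum(null >= obs)) / (B + 1))
      }
    }
    if (!length(rows)) {
      return(tibble(set_name = character(), direction = character(),
                    n_genes = integer(), observed_stat = numeric(),
                    n_permutations = integer(), p_perm = numeric()))
    }
    bind_rows(rows)
  })
}
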