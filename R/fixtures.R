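# Seeded synthetic-data generators with planted ground truth. Every stage of
# the pipeline is testable offline against these: the truth objects are
# emitted alongside the fixtures and never consumed by the code under test.

gene_ids <- function(n, prefix = "g") sprintf("%s%04d", prefix, seq_len(n))

#' Generate an expression dataset with planted co-expression modules
#'
#' Equi-correlated Gaussian factor model: each module m has a per-sample
#' factor `f_m ~ N(0,1)` and each member gene observes
#' `x = sqrt(rho) * f_m + sqrt(1-rho) * eps`, giving expected within-module
#' correlation `rho` (closed form, so correlation oracles are exact in
#' expectation). Background genes are iid N(0,1). Each gene then gets a
#' random affine distortion (scale in \[0.5, 2\], shift in \[-1, 1\]) that
#' per-gene z-scoring must undo, and cells are masked missing completely at
#' random.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_modules,module_size Planted module layout
#'   (`n_modules * module_size <= n_genes`).
#' @param rho Within-module correlation, `0 <= rho < 1`.
#' @param missing_rate MCAR missingness rate, `0 <= missing_rate < 0.5`.
#' @param seed Integer seed; outputs are bit-reproducible.
#' @return List with `matrix` (expression tibble) and `truth`
#'   (`module_assignments` tibble, `seed`).
#' @export
gen_expression_dataset <- function(n_genes = 100, n_samples = 20,
                                   n_modules = 3, module_size = 10,
                                   rho = 0.9, missing_rate = 0.05, seed = 1) {
  if (n_modules * module_size > n_genes) abort("Modules exceed gene count.")
  if (rho < 0 || rho >= 1) abort("`rho` must be in [0, 1).")
  if (missing_rate < 0 || missing_rate >= 0.5) {
    abort("`missing_rate` must be in [0, 0.5).")
  }
  withr::with_seed(seed, {
    genes <- gene_ids(n_genes)
    module <- rep(NA_integer_, n_genes)
    if (n_modules > 0) {
      module[seq_len(n_modules * module_size)] <-
        rep(seq_len(n_modules), each = module_size)
    }
    f <- matrix(rnorm(n_modules * n_samples), n_modules, n_samples)
    eps <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    x <- eps
    in_mod <- !is.na(module)
    if (any(in_mod)) {
      x[in_mod, ] <- sqrt(rho) * f[module[in_mod], , drop = FALSE] +
        sqrt(1 - rho) * eps[in_mod, , drop = FALSE]
    }
    scale <- runif(n_genes, 0.5, 2)
    shift <- runif(n_genes, -1, 1)
    x <- x * scale + shift
    if (missing_rate > 0) {
      x[runif(length(x)) < missing_rate] <- NA_real_
    }
    rownames(x) <- genes
    colnames(x) <- sprintf("s%03d", seq_len(n_samples))
    list(matrix = matrix_to_expr(x),
         truth = list(
           module_assignments = tibble(gene = genes, module = module),
           seed = seed))
  })
}

#' Generate a stochastic-block-model interaction network
#'
#' Genes in the same planted cluster are connected with probability `p_in`
#' and weight `N(w_in_mean, 0.5)`; cross-cluster pairs with probability
#' `p_out` and weight `N(w_out_mean, 0.5)`. The defaults reflect tight
#' functional modules sitting well above background on a z-score-like weight
#' scale. The universe covers all genes, including isolated ones.
#'
#' @param n_genes Number of genes (`cluster_size * n_clusters <= n_genes`).
#' @param n_clusters,cluster_size Planted cluster layout.
#' @param p_in,p_out Edge probabilities within / between clusters.
#' @param w_in_mean,w_out_mean Mean edge weights (sd fixed at 0.5).
#' @param seed Integer seed.
#' @return List with `network` (`gene_network`) and `truth`
#'   (`network_clusters` tibble, `seed`).
#' @export
gen_interaction_network <- function(n_genes = 100, n_clusters = 5,
                                    cluster_size = 10, p_in = 0.9,
                                    p_out = 0.05, w_in_mean = 3,
                                    w_out_mean = 0, seed = 1) {
  if (n_clusters * cluster_size > n_genes) abort("Clusters exceed gene count.")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  withr::with_seed(seed, {
    genes <- gene_ids(n_genes)
    cluster <- rep(NA_integer_, n_genes)
    if (n_clusters > 0) {
      cluster[seq_len(n_clusters * cluster_size)] <-
        rep(seq_len(n_clusters), each = cluster_size)
    }
    pair <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    same <- !is.na(cluster[pair[, 1]]) & !is.na(cluster[pair[, 2]]) &
      cluster[pair[, 1]] == cluster[pair[, 2]]
    prob <- ifelse(same, p_in, p_out)
    present <- runif(nrow(pair)) < prob
    mu <- ifelse(same, w_in_mean, w_out_mean)[present]
    edges <- tibble(gene1 = genes[pair[present, 1]],
                    gene2 = genes[pair[present, 2]],
                    weight = rnorm(sum(present), mu, 0.5))
    list(network = gene_network(edges, universe = genes,
                                net_type = "functional", complete = FALSE),
         truth = list(
           network_clusters = tibble(gene = genes, cluster = cluster),
           seed = seed))
  })
}

#' Generate a case-control dataset collection with planted effects
#'
#' Emulates a multi-study differential-expression screen: a fixed fraction
#' of genes is differentially expressed with overall effect `mu_de`, and
#' each study draws its own gene-level effect
#' `theta_gi ~ N(mu_de, tau^2)` (random-effects heterogeneity) added to case
#' means on the log2 scale; all values receive `N(0, sigma^2)` measurement
#' noise around a gene-specific baseline.
#'
#' @param n_datasets Number of studies.
#' @param n_genes Genes per study (shared namespace).
#' @param n_per_group Samples per group per study.
#' @param frac_de Fraction of genes differentially expressed.
#' @param mu_de True mean log2 fold change of DE genes.
#' @param tau Between-study standard deviation of the effect.
#' @param sigma Within-sample noise standard deviation.
#' @param seed Integer seed.
#' @return List with `datasets` (list of `list(matrix, conditions,
#'   dataset_id)`) and `truth` (`de_genes` tibble with true effects,
#'   `true_tau`, `seed`).
#' @export
gen_case_control_collection <- function(n_datasets = 6, n_genes = 200,
                                        n_per_group = 4, frac_de = 0.1,
                                        mu_de = 1, tau = 0.25, sigma = 0.5,
                                        seed = 1) {
  if (frac_de <= 0 || frac_de >= 1) abort("`frac_de` must be in (0, 1).")
  if (min(n_datasets, n_genes, n_per_group) < 1 || tau < 0 || sigma < 0) {
    abort("Counts must be positive and tau, sigma non-negative.")
  }
  withr::with_seed(seed, {
    genes <- gene_ids(n_genes)
    n_de <- max(1, round(frac_de * n_genes))
    de <- genes[seq_len(n_de)]
    base <- rnorm(n_genes, 7, 1)
    datasets <- lapply(seq_len(n_datasets), function(i) {
      theta <- rnorm(n_de, mu_de, tau)
      n_s <- 2 * n_per_group
      x <- matrix(rnorm(n_genes * n_s, 0, sigma), n_genes, n_s) + base
      x[seq_len(n_de), seq_len(n_per_group)] <-
        x[seq_len(n_de), seq_len(n_per_group)] + theta
      rownames(x) <- genes
      colnames(x) <- sprintf("d%02d_s%02d", i, seq_len(n_s))
      conditions <- setNames(rep(c("case", "control"), each = n_per_group),
                             colnames(x))
      list(matrix = matrix_to_expr(x), conditions = conditions,
           dataset_id = sprintf("D%02d", i))
    })
    list(datasets = datasets,
         truth = list(
           de_genes = tibble(gene = de, mu = mu_de),
           true_tau = tau, seed = seed))
  })
}

#' Write a mock on-disk data repository
#'
#' Lays out the per-repository directory structure the pipeline consumes:
#' `data/<source>/<dataset_id>/{raw.tsv, metadata.json}`, per-source gene
#' maps under `maps/`, optional sparse interaction networks under
#' `networks/<source>/`, and curated metadata overrides under
#' `etc/manual_curation/`. Raw matrices use probe ids (`p:<gene>`), so gene
#' mapping is exercised end to end; metadata titles embed searchable
#' keywords so selection screens work; sample condition labels ride along in
#' the metadata for the meta-analysis stage. Planted truth is written to
#' `truth.json` and never read by the pipeline.
#'
#' @param root Writable directory to populate.
#' @param datasets Tibble describing the repository; see
#'   [default_mock_repository_spec()]. Columns: `dataset_id`, `source`,
#'   `taxonomy_id`, `title`, `curated` (logical: write an override file),
#'   `network` (logical: write an interaction network).
#' @param n_genes,n_per_group Shared dimensions of the generated studies.
#' @param frac_de,mu_de,tau,sigma Passed to
#'   [gen_case_control_collection()].
#' @param seed Integer seed.
#' @return `root`, invisibly.
#' @export
gen_mock_repository <- function(root,
                                datasets = default_mock_repository_spec(),
                                n_genes = 60, n_per_group = 4,
                                frac_de = 0.1, mu_de = 1.5, tau = 0.25,
                                sigma = 0.5, seed = 1) {
  if (!dir.exists(root)) {
    ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create repository root %s", root))
  }
  coll <- gen_case_control_collection(
    n_datasets = nrow(datasets), n_genes = n_genes,
    n_per_group = n_per_group, frac_de = frac_de, mu_de = mu_de, tau = tau,
    sigma = sigma, seed = seed)
  genes <- coll$datasets[[1]]$matrix$gene
  for (i in seq_len(nrow(datasets))) {
    d <- datasets[i, ]
    ds <- coll$datasets[[i]]
    ddir <- file.path(root, "data", d$source, d$dataset_id)
    dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
    raw <- ds$matrix
    raw$gene <- paste0("p:", raw$gene)
    write_expression_table(raw, file.path(ddir, "raw.tsv"), overwrite = TRUE)
    rec <- metadata_record(
      d$dataset_id, source = d$source,
      pairs = list(taxonomy_id = d$taxonomy_id, title = d$title,
                   platform = "mock-array",
                   experiment_type = "expression profiling",
                   n_samples = 2L * n_per_group,
                   sample_conditions = as.list(ds$conditions)))
    write_metadata(rec, file.path(ddir, "metadata.json"))
    if (isTRUE(d$curated)) {
      cur <- metadata_record(
        d$dataset_id, source = d$source,
        pairs = list(title = paste(d$title, "(curated)"),
                     curator = "manual"))
      write_metadata(cur, file.path(root, "etc", "manual_curation",
                                    paste0(d$dataset_id, ".json")))
    }
    if (isTRUE(d$network)) {
      net <- gen_interaction_network(
        n_genes = n_genes, n_clusters = 3, cluster_size = 5,
        p_in = 0.9, p_out = 0.02, seed = seed + i)$network
      e <- as_tibble(net)
      e$gene1 <- paste0("p:", e$gene1)
      e$gene2 <- paste0("p:", e$gene2)
      e$weight <- 1  # binary physical evidence
      write_tsv_plain(e, file.path(root, "networks", d$source,
                                   paste0(d$dataset_id, ".tsv")))
    }
  }
  for (src in unique(datasets$source)) {
    map <- tibble(source_id = paste0("p:", genes), target_id = genes)
    write_tsv_plain(map, file.path(root, "maps", paste0(src, ".tsv")))
  }
  jsonlite::write_json(
    list(de_genes = coll$truth$de_genes, true_tau = coll$truth$true_tau,
         seed = seed),
    file.path(root, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(root)
}

#' Default layout for a mock repository
#'
#' Three mouse gut datasets from one source, one of them curated and one
#' carrying a binary interaction network, with keyword-rich titles that
#' selection screens can match.
#'
#' @return A tibble consumed by [gen_mock_repository()].
#' @export
default_mock_repository_spec <- function() {
  tibble(
    dataset_id = c("DS001", "DS002", "DS003"),
    source = "mockrepo",
    taxonomy_id = 10090L,
    title = c("Germ-free vs wild type intestinal tract, colon",
              "Germ-free versus conventional mouse gut epithelium",
              "Wild type germ-free comparison, small intestine"),
    curated = c(TRUE, FALSE, FALSE),
    network = c(TRUE, FALSE, FALSE))
}
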