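#' Simulate a case/control expression dataset with planted differential genes
#'
#' Draws per-gene baseline means once, plants a fraction of genes as
#' differentially expressed by shifting cases up or down by `effect_log2fc`
#' (direction Bernoulli(0.5) per gene, so neither regulation pattern
#' dominates), and adds Gaussian noise on the log2 scale. Values are generated
#' directly on the log2 (RMA output) scale.
#'
#' @param n_genes,n_case,n_control counts; each phenotype needs >= 3 samples.
#' @param deg_fraction fraction of genes planted as differential, in `[0, 1]`.
#' @param effect_log2fc absolute case-minus-control shift (log2 units) for
#'   planted genes.
#' @param noise_sd standard deviation of the per-observation Gaussian noise.
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param name dataset identifier.
#' @param deg_genes optional character vector of gene ids to plant instead of
#'   sampling them, so several datasets can share one planted signal;
#'   overrides `deg_fraction`.
#' @param deg_sign optional named vector of +1/-1 giving the planted direction
#'   per gene in `deg_genes`.
#' @param gene_ids optional gene universe (defaults to `"G0001"...`).
#' @return list with `dataset` (an [expression_dataset()]), `deg_genes`
#'   (planted set) and `deg_sign` (named +1/-1 directions).
#' @examples
#' sim <- generate_expression(100, 10, 10, deg_fraction = 0.2,
#'                            effect_log2fc = 1, noise_sd = 0.5, seed = 7)
#' length(sim$deg_genes)  # 20
#' @export
generate_expression <- function(n_genes, n_case, n_control,
                                deg_fraction = 0.1, effect_log2fc = 1,
                                noise_sd = 0.5, seed = 1L,
                                name = "synthetic", deg_genes = NULL,
                                deg_sign = NULL, gene_ids = NULL) {
  if (n_genes < 1 || n_case < 3 || n_control < 3)
    stop_invalid("need n_genes >= 1 and at least 3 samples per phenotype")
  if (deg_fraction < 0 || deg_fraction > 1)
    stop_invalid("deg_fraction must be in [0, 1]")
  if (noise_sd <= 0) stop_invalid("noise_sd must be positive")
  if (is.null(gene_ids)) gene_ids <- id_seq("G", n_genes, width = 4L)
  stopifnot(length(gene_ids) == n_genes)

  with_seed(seed, {
    if (is.null(deg_genes)) {
      n_deg <- round(deg_fraction * n_genes)
      deg_genes <- if (n_deg > 0) sample(gene_ids, n_deg) else character(0)
    } else {
      stopifnot(all(deg_genes %in% gene_ids))
    }
    if (is.null(deg_sign)) {
      deg_sign <- stats::setNames(
        sample(c(-1, 1), length(deg_genes), replace = TRUE), deg_genes)
    }
    baseline <- stats::runif(n_genes, min = 4, max = 10)
    names(baseline) <- gene_ids
    n <- n_case + n_control
    samples <- c(id_seq(paste0(name, "_case_"), n_case, width = 3L),
                 id_seq(paste0(name, "_ctrl_"), n_control, width = 3L))
    labels <- rep(c("case", "control"), c(n_case, n_control))
    mat <- matrix(baseline, nrow = n_genes, ncol = n,
                  dimnames = list(gene_ids, samples))
    if (length(deg_genes) > 0) {
      shift <- effect_log2fc * deg_sign[deg_genes]
      mat[deg_genes, labels == "case"] <-
        mat[deg_genes, labels == "case"] + shift
    }
    mat <- mat + matrix(stats::rnorm(n_genes * n, sd = noise_sd),
                        nrow = n_genes)
    list(dataset = expression_dataset(mat, labels, name),
         deg_genes = sort(deg_genes),
         deg_sign = deg_sign)
  })
}

#' Simulate a scale-free protein-protein interaction network
#'
#' Preferential-attachment (Barabasi-Albert) growth: each new node attaches
#' `attach_m` edges to existing nodes with probability proportional to their
#' degree, which produces the heavy-tailed degree distribution and hub nodes
#' typical of curated physical interactomes.
#'
#' @param n_nodes number of proteins; must exceed `attach_m`.
#' @param attach_m edges added per new node, >= 1.
#' @param seed integer seed.
#' @param node_ids optional node names (defaults to the gene universe dialect
#'   `"G0001"...` so the network shares identifiers with expression data).
#' @return two-column character data.frame (`from`, `to`): a simple,
#'   connected, undirected edge list with no self-loops.
#' @export
generate_ppi <- function(n_nodes, attach_m = 2L, seed = 1L, node_ids = NULL) {
  if (attach_m < 1 || n_nodes <= attach_m)
    stop_invalid("need n_nodes > attach_m >= 1")
  if (is.null(node_ids)) node_ids <- id_seq("G", n_nodes, width = 4L)
  stopifnot(length(node_ids) == n_nodes)
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    # randomize which identifier lands on which topological position so the
    # planted DEG set is not biased toward early (high-degree) nodes
    igraph::V(g)$name <- sample(node_ids)
    el <- igraph::as_edgelist(g)
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  })
}

#' Simulate a bipartite regulator-target network with planted active features
#'
#' Emulates a TF-target (or receptor-protein) network in which a few "active"
#' regulators have neighborhoods enriched for differentially expressed genes:
#' each active feature draws a fraction `enrichment` of its targets from
#' `deg_genes` and the rest uniformly; inactive features draw all targets
#' uniformly from the gene universe.
#'
#' @param n_features number of regulators (TFs or receptors).
#' @param genes character gene universe the targets are drawn from.
#' @param targets_per_feature integer range `c(lo, hi)`: each feature's
#'   out-degree is sampled uniformly from it.
#' @param n_active number of planted active features (<= `n_features`).
#' @param deg_genes gene set the active neighborhoods are enriched for.
#' @param enrichment fraction of an active feature's targets drawn from
#'   `deg_genes`, in `[0, 1]`.
#' @param seed integer seed.
#' @param prefix feature identifier prefix, e.g. `"TF"` or `"R"`.
#' @return list with `edges` (data.frame `feature`, `gene`) and `active`
#'   (character vector of planted active features).
#' @export
generate_bipartite <- function(n_features, genes,
                               targets_per_feature = c(5L, 20L),
                               n_active = 0L, deg_genes = character(0),
                               enrichment = 0.9, seed = 1L, prefix = "TF") {
  if (length(genes) == 0) stop_invalid("gene universe is empty")
  if (enrichment < 0 || enrichment > 1)
    stop_invalid("enrichment must be in [0, 1]")
  if (n_active > n_features)
    stop_invalid("n_active cannot exceed n_features")
  stopifnot(length(targets_per_feature) == 2L,
            targets_per_feature[1] >= 1,
            targets_per_feature[2] <= length(genes))
  features <- id_seq(prefix, n_features)
  with_seed(seed, {
    active <- if (n_active > 0) sort(sample(features, n_active)) else character(0)
    non_deg <- setdiff(genes, deg_genes)
    edges <- lapply(features, function(f) {
      k <- sample(seq.int(targets_per_feature[1], targets_per_feature[2]), 1L)
      if (f %in% active && length(deg_genes) > 0) {
        k_deg <- min(round(enrichment * k), length(deg_genes))
        from_deg <- sample(deg_genes, k_deg)
        # remainder uniform over the rest of the universe, so enrichment = 0
        # makes active features indistinguishable from inactive ones
        tgt <- c(from_deg, sample(setdiff(genes, from_deg), k - k_deg))
      } else {
        tgt <- sample(genes, k)
      }
      data.frame(feature = f, gene = tgt, stringsAsFactors = FALSE)
    })
    list(edges = do.call(rbind, edges), active = active)
  })
}

#' Simulate right-censored survival outcomes from a proportional-hazards model
#'
#' Event times are exponential with per-sample rate
#' `h0 * exp(sum_g beta_g * x_g)` where `x_g` is the per-gene standardized
#' (z-score) expression, and censoring is independent uniform on
#' `[0, censor_time_max]`.
#'
#' @param expr an [expression_dataset()]; every sample gets an outcome.
#' @param coefs named numeric vector: true log-hazard coefficient per gene
#'   (per standard deviation of expression); names must be measured genes.
#' @param baseline_hazard baseline event rate per day, > 0.
#' @param censor_time_max upper bound of the uniform censoring time (days).
#' @param seed integer seed.
#' @return data.frame with `sample`, `time_days`, `event` (1 = death
#'   observed, 0 = censored).
#' @export
generate_survival <- function(expr, coefs, baseline_hazard = 1 / 1000,
                              censor_time_max = 3000, seed = 1L) {
  stopifnot(inherits(expr, "ExpressionDataset"))
  if (baseline_hazard <= 0) stop_invalid("baseline_hazard must be positive")
  if (censor_time_max < 0) stop_invalid("censor_time_max must be >= 0")
  if (length(coefs) > 0 && !all(names(coefs) %in% expr$gene_ids))
    stop_invalid("coefs refer to genes absent from the expression matrix")
  n <- ncol(expr$matrix)
  lp <- rep(0, n)
  if (length(coefs) > 0) {
    x <- expr$matrix[names(coefs), , drop = FALSE]
    xs <- t(scale(t(x)))          # per-gene z-score across samples
    lp <- as.vector(coefs %*% xs)
  }
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = baseline_hazard * exp(lp))
    t_cens <- stats::runif(n, 0, censor_time_max)
    data.frame(sample = colnames(expr$matrix),
               time_days = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study bundle with planted ground truth
#'
#' Builds everything the pipeline consumes: several case/control discovery
#' datasets sharing one planted DEG signal, a scale-free PPI over the gene
#' universe, TF-target and receptor-protein bipartite networks with planted
#' active regulators, and an independent validation cohort with case/control
#' labels and proportional-hazards survival outcomes. Feature identifiers
#' (TFs, receptors) are included as rows of the validation expression matrix
#' so candidate regulators can themselves be screened diagnostically and
#' prognostically, as in a transcriptome-wide validation cohort.
#'
#' @param n_genes size of the gene universe.
#' @param n_datasets number of discovery datasets (>= 2).
#' @param n_case,n_control discovery-cohort sizes per dataset.
#' @param deg_fraction,effect_log2fc,noise_sd planted differential signal
#'   shared by the discovery datasets (see [generate_expression()]).
#' @param n_tf,n_receptor feature-universe sizes.
#' @param n_active_tf,n_active_receptor planted active regulators.
#' @param enrichment DEG enrichment of active neighborhoods.
#' @param attach_m preferential-attachment parameter of the PPI.
#' @param val_n_case,val_n_control validation-cohort sizes.
#' @param val_effect_sd case/control shift of planted diagnostic rows in the
#'   validation cohort, in units of the noise standard deviation.
#' @param n_prognostic number of planted prognostic rows (drawn from the
#'   active features), each with true log-hazard coefficient
#'   `prognostic_beta` per sd.
#' @param prognostic_beta true per-sd log hazard ratio of planted rows.
#' @param baseline_hazard,censor_time_max survival-model parameters
#'   (see [generate_survival()]).
#' @param seed master integer seed; every sub-generator derives its own
#'   stream from it, so the whole bundle is reproducible bit-for-bit.
#' @return list of class `SyntheticBundle`: `datasets` (list of
#'   [expression_dataset()]), `ppi`, `tf_net`, `receptor_net`, `validation`
#'   (expression + `survival` table), `truth` (planted sets) and `seed`.
#' @export
generate_bundle <- function(n_genes = 600, n_datasets = 3,
                            n_case = 10, n_control = 10,
                            deg_fraction = 0.1, effect_log2fc = 2,
                            noise_sd = 0.5,
                            n_tf = 50, n_receptor = 50,
                            n_active_tf = 5, n_active_receptor = 5,
                            enrichment = 0.9, attach_m = 2,
                            val_n_case = 100, val_n_control = 30,
                            val_effect_sd = 2,
                            n_prognostic = 5, prognostic_beta = 1,
                            baseline_hazard = 1 / 1000,
                            censor_time_max = 3000,
                            seed = 42L) {
  if (n_datasets < 2) stop_invalid("need at least 2 discovery datasets")
  seed <- as.integer(seed)
  gene_ids <- id_seq("G", n_genes, width = 4L)
  # derive disjoint sub-seeds from the master seed (kept below 2^31)
  sub <- function(i) (seed * 101L + i * 7919L) %% 2000000000L

  first <- generate_expression(n_genes, n_case, n_control, deg_fraction,
                               effect_log2fc, noise_sd, seed = sub(1L),
                               name = "dataset_1", gene_ids = gene_ids)
  deg_genes <- first$deg_genes
  deg_sign <- first$deg_sign
  datasets <- c(list(first$dataset), lapply(seq_len(n_datasets - 1L), function(i) {
    generate_expression(n_genes, n_case, n_control, deg_fraction,
                        effect_log2fc, noise_sd, seed = sub(1L + i),
                        name = paste0("dataset_", i + 1L),
                        deg_genes = deg_genes, deg_sign = deg_sign,
                        gene_ids = gene_ids)$dataset
  }))

  ppi <- generate_ppi(n_genes, attach_m = attach_m, seed = sub(50L),
                      node_ids = gene_ids)
  tf <- generate_bipartite(n_tf, gene_ids, n_active = n_active_tf,
                           deg_genes = deg_genes, enrichment = enrichment,
                           seed = sub(60L), prefix = "TF")
  rec <- generate_bipartite(n_receptor, gene_ids, n_active = n_active_receptor,
                            deg_genes = deg_genes, enrichment = enrichment,
                            seed = sub(61L), prefix = "R")

  # validation cohort measures genes and regulators; planted diagnostic rows
  # are the discovery DEGs plus all active regulators
  active <- c(tf$active, rec$active)
  val_ids <- c(gene_ids, id_seq("TF", n_tf), id_seq("R", n_receptor))
  diagnostic <- sort(c(deg_genes, active))
  val <- generate_expression(length(val_ids), val_n_case, val_n_control,
                             effect_log2fc = val_effect_sd, noise_sd = 1,
                             seed = sub(70L), name = "validation",
                             deg_genes = diagnostic, gene_ids = val_ids)

  prog_pool <- if (length(active) > 0) active else deg_genes
  n_prognostic <- min(n_prognostic, length(prog_pool))
  prognostic <- with_seed(sub(80L), sort(sample(prog_pool, n_prognostic)))
  coefs <- stats::setNames(rep(prognostic_beta, n_prognostic), prognostic)
  surv <- generate_survival(val$dataset, coefs, baseline_hazard,
                            censor_time_max, seed = sub(81L))

  structure(list(
    datasets = datasets,
    ppi = ppi,
    tf_net = tf$edges,
    receptor_net = rec$edges,
    validation = list(expr = val$dataset, survival = surv),
    truth = list(deg_genes = deg_genes,
                 deg_sign = deg_sign,
                 active_tfs = tf$active,
                 active_receptors = rec$active,
                 prognostic_genes = as.list(coefs),
                 diagnostic_genes = diagnostic),
    seed = seed
  ), class = "SyntheticBundle")
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' File dialect: `expression_<i>.tsv` (first column `gene`, one column per
#' sample), `labels_<i>.tsv` (`sample`, `phenotype`), `ppi.tsv`,
#' `tf_targets.tsv`, `receptor_net.tsv`, `validation_expression.tsv`,
#' `validation_labels.tsv`, `survival.tsv` (`sample`, `time_days`, `event`)
#' and `truth.json`.
#'
#' @param bundle a `SyntheticBundle` from [generate_bundle()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SyntheticBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (i in seq_along(bundle$datasets)) {
    ds <- bundle$datasets[[i]]
    wr(data.frame(gene = rownames(ds$matrix), ds$matrix, check.names = FALSE),
       sprintf("expression_%d.tsv", i))
    wr(data.frame(sample = names(ds$sample_labels),
                  phenotype = unname(ds$sample_labels)),
       sprintf("labels_%d.tsv", i))
  }
  wr(bundle$ppi, "ppi.tsv")
  wr(bundle$tf_net, "tf_targets.tsv")
  wr(bundle$receptor_net, "receptor_net.tsv")
  vexpr <- bundle$validation$expr
  wr(data.frame(gene = rownames(vexpr$matrix), vexpr$matrix,
                check.names = FALSE), "validation_expression.tsv")
  wr(data.frame(sample = names(vexpr$sample_labels),
                phenotype = unname(vexpr$sample_labels)),
     "validation_labels.tsv")
  wr(bundle$validation$survival, "survival.tsv")
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
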