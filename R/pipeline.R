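#' Assemble and validate a pipeline configuration
#'
#' Collects every input path and analysis threshold in one serializable
#' object. Threshold defaults: DEG adjusted p < 0.05 with 2-fold change,
#' over-representation adjusted p < 0.01, reporter adjusted p < 0.001, hub
#' rank cutoff 10 per metric, diagnostic AUC >= 0.70, prognostic log-rank
#' p < 0.05.
#'
#' @param expression,labels character vectors (same length, >= 2) of
#'   per-dataset expression and label TSV paths.
#' @param ppi undirected PPI edge-list TSV path.
#' @param tf_net,receptor_net bipartite network TSV paths.
#' @param validation_expression,validation_labels validation-cohort TSVs.
#' @param survival survival TSV path (optional; prognostic screen and the
#'   alive/dead classification are skipped without it).
#' @param gene_sets optional GMT path for over-representation analysis.
#' @param known_genes optional path to a plain list of genes already
#'   associated with the disease (one id per line).
#' @param out_dir output directory.
#' @param deg_alpha,fc,ora_alpha,reporter_alpha,auc_threshold,logrank_alpha
#'   stage thresholds (see description).
#' @param hub_k rank cutoff per centrality metric.
#' @param n_samples Monte-Carlo draws for the reporter background.
#' @param seed master seed.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(expression, labels, ppi, tf_net, receptor_net,
                            validation_expression, validation_labels,
                            survival = NULL, gene_sets = NULL,
                            known_genes = NULL, out_dir = "reporternet_out",
                            deg_alpha = 0.05, fc = 2.0, ora_alpha = 0.01,
                            reporter_alpha = 0.001, auc_threshold = 0.70,
                            logrank_alpha = 0.05, hub_k = 10,
                            n_samples = 1e5, seed = 42L) {
  stopifnot(length(expression) == length(labels), length(expression) >= 2)
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || x <= lo || x > hi)
      stop_invalid("%s must be in (%g, %g]", nm, lo, hi)
  }
  chk(deg_alpha, 0, 1, "deg_alpha"); chk(ora_alpha, 0, 1, "ora_alpha")
  chk(reporter_alpha, 0, 1, "reporter_alpha")
  chk(logrank_alpha, 0, 1, "logrank_alpha")
  if (fc < 1) stop_invalid("fc must be >= 1")
  if (auc_threshold < 0.5 || auc_threshold > 1)
    stop_invalid("auc_threshold must be in [0.5, 1]")
  if (hub_k < 1) stop_invalid("hub_k must be >= 1")
  structure(list(
    expression = expression, labels = labels, ppi = ppi, tf_net = tf_net,
    receptor_net = receptor_net,
    validation_expression = validation_expression,
    validation_labels = validation_labels, survival = survival,
    gene_sets = gene_sets, known_genes = known_genes, out_dir = out_dir,
    deg_alpha = deg_alpha, fc = fc, ora_alpha = ora_alpha,
    reporter_alpha = reporter_alpha, auc_threshold = auc_threshold,
    logrank_alpha = logrank_alpha, hub_k = hub_k,
    n_samples = n_samples, seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Point a configuration at a written synthetic bundle directory
#'
#' Convenience constructor mapping the [write_bundle()] file dialect onto
#' [pipeline_config()].
#'
#' @param dir directory written by [write_bundle()].
#' @param n_datasets number of discovery datasets in the bundle.
#' @param out_dir output directory (default `<dir>/results`).
#' @param ... further arguments passed to [pipeline_config()].
#' @return a `PipelineConfig`.
#' @export
bundle_config <- function(dir, n_datasets = 3,
                          out_dir = file.path(dir, "results"), ...) {
  idx <- seq_len(n_datasets)
  pipeline_config(
    expression = file.path(dir, sprintf("expression_%d.tsv", idx)),
    labels = file.path(dir, sprintf("labels_%d.tsv", idx)),
    ppi = file.path(dir, "ppi.tsv"),
    tf_net = file.path(dir, "tf_targets.tsv"),
    receptor_net = file.path(dir, "receptor_net.tsv"),
    validation_expression = file.path(dir, "validation_expression.tsv"),
    validation_labels = file.path(dir, "validation_labels.tsv"),
    survival = file.path(dir, "survival.tsv"),
    out_dir = out_dir, ...)
}

#' Flag which candidates are not on a known disease-gene list
#'
#' Membership is matched case-insensitively. A missing list file flags every
#' candidate as novel (status unknown) with a warning.
#'
#' @param candidates character vector of candidate identifiers.
#' @param known character vector of known disease genes, or a path to a
#'   one-id-per-line file.
#' @return data.frame `gene`, `novel`.
#' @export
annotate_known <- function(candidates, known = character(0)) {
  if (length(known) == 1 && !is.null(known) && file.exists(known))
    known <- readLines(known, warn = FALSE)
  else if (is.character(known) && length(known) == 1 && grepl("[/\\\\]", known)) {
    warning("known-gene list file not found; all candidates flagged novel")
    known <- character(0)
  }
  known <- trimws(tolower(known))
  data.frame(gene = candidates,
             novel = !(tolower(trimws(candidates)) %in% known),
             stringsAsFactors = FALSE)
}

#' Run the full biomarker-discovery pipeline
#'
#' Stages, in order: per-dataset moderated-t differential expression and
#' DEG calls; cross-dataset intersection; optional over-representation
#' analysis; DEG-centred PPI subnetwork, centralities and hub selection;
#' reporter TF and reporter receptor scoring (gene p-values combined across
#' datasets by Fisher's method); diagnostic (AUC) and, when survival data
#' are supplied, prognostic (Cox PI / log-rank / HR) screening of the
#' pooled candidates on the validation cohort; candidate calling by the
#' union rule (diagnostic OR prognostic); known-gene annotation; and
#' cross-validated classification of the candidate panel (case/control and,
#' with survival data, alive/dead). Every intermediate is written as TSV
#' into `config$out_dir` together with `manifest.json` recording versions,
#' seed, thresholds and per-stage counts. A failing stage halts the run
#' with the stage name; earlier outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  paths <- c(config$expression, config$labels, config$ppi, config$tf_net,
             config$receptor_net, config$validation_expression,
             config$validation_labels, config$survival, config$gene_sets)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop_invalid("missing input file(s): %s", paste(missing, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) utils::write.table(
    df, file.path(config$out_dir, file), sep = "\t", quote = FALSE,
    row.names = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
  }

  datasets <- stage("load", lapply(seq_along(config$expression), function(i)
    read_expression(config$expression[i], config$labels[i])))
  names(datasets) <- vapply(datasets, `[[`, "", "name")

  results <- stage("diffexpr", lapply(datasets, moderated_ttest))
  deg_tables <- lapply(results, call_degs,
                       alpha = config$deg_alpha, fc_threshold = config$fc)
  for (nm in names(deg_tables)) wr(deg_tables[[nm]], sprintf("degs_%s.tsv", nm))

  common <- stage("intersect", intersect_degs(deg_tables))
  writeLines(common$genes, file.path(config$out_dir, "common_degs.txt"))

  ora <- NULL
  if (!is.null(config$gene_sets)) {
    ora <- stage("ora", {
      universe <- sort(Reduce(intersect, lapply(datasets, `[[`, "gene_ids")))
      hypergeometric_ora(intersect(common$genes, universe),
                         read_gmt(config$gene_sets), universe,
                         alpha = config$ora_alpha)
    })
    wr(ora, "ora.tsv")
  }

  hubs <- stage("hubs", {
    ppi <- load_edge_list(config$ppi, directed = FALSE)
    sub <- reconstruct_subnetwork(common$genes, ppi)
    select_hubs(centralities(sub), k = config$hub_k)
  })
  wr(hubs, "hubs.tsv")
  hub_genes <- hubs$node[hubs$hub_flag]

  combined <- stage("combine", combine_pvalues(results, method = "fisher"))
  rep_tf <- stage("reporter_tf", score_reporters(
    combined, read_bipartite(config$tf_net), alpha = config$reporter_alpha,
    n_samples = config$n_samples, seed = config$seed))
  wr(rep_tf, "reporters_tf.tsv")
  rep_rec <- stage("reporter_receptor", score_reporters(
    combined, read_bipartite(config$receptor_net),
    alpha = config$reporter_alpha, n_samples = config$n_samples,
    seed = config$seed + 1L))
  wr(rep_rec, "reporters_receptor.tsv")

  pool <- sort(unique(c(hub_genes,
                        rep_tf$feature[rep_tf$significant],
                        rep_rec$feature[rep_rec$significant])))

  val <- stage("validation_load", read_expression(
    config$validation_expression, config$validation_labels, "validation"))
  diag <- stage("diagnostic", screen_diagnostic(
    val, pool, threshold = config$auc_threshold))
  wr(diag, "diagnostic.tsv")

  prog <- NULL
  surv <- NULL
  if (!is.null(config$survival)) {
    surv <- read_survival(config$survival)
    prog <- stage("prognostic", screen_prognostic(
      val, surv, pool, alpha = config$logrank_alpha))
    wr(prog, "prognostic.tsv")
  }

  diag_ok <- diag$gene[!is.na(diag$diagnostic_flag) & diag$diagnostic_flag]
  prog_ok <- if (is.null(prog)) character(0)
             else prog$gene[!is.na(prog$prognostic_flag) & prog$prognostic_flag]
  cand_ids <- sort(unique(c(diag_ok, prog_ok)))   # union rule
  candidates <- annotate_known(
    cand_ids,
    if (is.null(config$known_genes)) character(0) else config$known_genes)
  candidates$diagnostic <- candidates$gene %in% diag_ok
  candidates$prognostic <- candidates$gene %in% prog_ok
  wr(candidates, "candidates.tsv")

  classification <- NULL
  if (length(cand_ids) > 0) {
    classification <- stage("classify", {
      cc <- evaluate_panel(val, panel = cand_ids, seed = config$seed)
      cc$task <- "case_control"
      out <- cc
      if (!is.null(surv)) {
        idx <- match(colnames(val$matrix), surv$sample)
        if (!anyNA(idx)) {
          vital <- ifelse(surv$event[idx] == 1, "dead", "alive")
          ad <- evaluate_panel(val, labels = vital, panel = cand_ids,
                               seed = config$seed)
          ad$task <- "alive_dead"
          out <- rbind(cc, ad)
        }
      }
      out
    })
    wr(classification, "classification.tsv")
  }

  manifest <- list(
    package = "reporternet",
    version = as.character(utils::packageVersion("reporternet")),
    seed = config$seed,
    thresholds = list(deg_alpha = config$deg_alpha, fc = config$fc,
                      ora_alpha = config$ora_alpha,
                      reporter_alpha = config$reporter_alpha,
                      auc_threshold = config$auc_threshold,
                      logrank_alpha = config$logrank_alpha,
                      hub_k = config$hub_k, n_samples = config$n_samples),
    counts = list(
      datasets = length(datasets),
      degs_per_dataset = lapply(deg_tables, nrow),
      common_degs = length(common$genes),
      ora_significant = if (is.null(ora)) NA else sum(ora$significant),
      hubs = sum(hubs$hub_flag),
      reporter_tfs = sum(rep_tf$significant),
      reporter_receptors = sum(rep_rec$significant),
      diagnostic = length(diag_ok),
      prognostic = length(prog_ok),
      candidates = nrow(candidates),
      novel_candidates = sum(candidates$novel)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(datasets = datasets, results = results,
                 deg_tables = deg_tables, common = common, ora = ora,
                 hubs = hubs, reporters_tf = rep_tf,
                 reporters_receptor = rep_rec, diagnostic = diag,
                 prognostic = prog, candidates = candidates,
                 classification = classification, manifest = manifest))
}
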