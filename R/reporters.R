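#' Convert gene-level p-values to upper-tail standard-normal Z-scores
#'
#' The reporter-features construction works on \eqn{Z_g = \Phi^{-1}(1 - p_g)}
#' so that small p-values map to large positive scores. P-values are clamped
#' to `[1e-15, 1 - 1e-15]` before inversion so the quantile stays finite.
#' Unadjusted p-values should be supplied: the multiple-testing correction
#' belongs at the feature level, after aggregation.
#'
#' @param results data.frame with `gene` and `p` columns (e.g. from
#'   [moderated_ttest()] or [combine_pvalues()]), or a named numeric vector
#'   of p-values.
#' @return named numeric vector of Z-scores; genes with missing p are
#'   skipped with a warning.
#' @export
gene_zscores <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("gene", "p") %in% names(results)))
    p <- stats::setNames(results$p, results$gene)
  } else {
    stopifnot(is.numeric(results), !is.null(names(results)))
    p <- results
  }
  if (anyNA(p)) {
    warning(sprintf("%d gene(s) with missing p-value skipped", sum(is.na(p))))
    p <- p[!is.na(p)]
  }
  eps <- 1e-15
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Combine per-dataset gene p-values across studies
#'
#' Restricted to genes measured in every dataset. Fisher's method refers
#' \eqn{-2\sum_i \log p_i} to a chi-square on `2m` degrees of freedom;
#' Stouffer's method averages the per-dataset Z-scores with a `1/sqrt(m)`
#' scaling.
#'
#' @param results_list list of data.frames with `gene` and `p` columns.
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return data.frame `gene`, `p` (combined).
#' @export
combine_pvalues <- function(results_list, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (is.data.frame(results_list)) results_list <- list(results_list)
  stopifnot(length(results_list) >= 1)
  genes <- sort(Reduce(intersect, lapply(results_list, `[[`, "gene")))
  if (length(genes) == 0) stop_invalid("no genes shared across datasets")
  pm <- vapply(results_list,
               function(d) d$p[match(genes, d$gene)],
               numeric(length(genes)))
  pm <- matrix(pm, nrow = length(genes))
  eps <- 1e-300
  pm <- pmin(pmax(pm, eps), 1)
  m <- ncol(pm)
  p <- if (method == "fisher") {
    stats::pchisq(-2 * rowSums(log(pm)), df = 2 * m, lower.tail = FALSE)
  } else {
    z <- rowSums(stats::qnorm(pmin(pm, 1 - 1e-15), lower.tail = FALSE)) / sqrt(m)
    stats::pnorm(z, lower.tail = FALSE)
  }
  data.frame(gene = genes, p = p, stringsAsFactors = FALSE)
}

#' Aggregate gene Z-scores onto one network feature
#'
#' The raw reporter score of a feature with `k` measured neighbor genes is
#' \eqn{Z_{agg} = \sum_{i} Z_i / \sqrt{k}}.
#'
#' @param z named numeric vector of gene Z-scores.
#' @param neighbors character vector of the feature's target genes; genes
#'   absent from `z` are ignored.
#' @return list `k` (measured neighbor count) and `z_agg`; `k = 0` yields
#'   `NULL` (caller drops the feature).
#' @export
aggregate_feature <- function(z, neighbors) {
  nb <- intersect(unique(neighbors), names(z))
  k <- length(nb)
  if (k == 0) return(NULL)
  list(k = k, z_agg = sum(z[nb]) / sqrt(k))
}

# Monte-Carlo moments of the size-k aggregate under the null: mean and sd of
# sum(sample(pool, k)) / sqrt(k) over n_samples draws without replacement.
background_moments <- function(k, z_pool, n_samples) {
  n <- length(z_pool)
  draws <- vapply(seq_len(n_samples),
                  function(i) sum(z_pool[sample.int(n, k)]),
                  0.0) / sqrt(k)
  c(mu = mean(draws), sigma = stats::sd(draws))
}

#' Background-correct an aggregate reporter score
#'
#' Standardizes `z_agg` against the Monte-Carlo null distribution of
#' aggregate scores of random same-size gene sets drawn (without
#' replacement) from the full measured-gene Z pool:
#' \eqn{Z_{corr} = (Z_{agg} - \mu_k) / \sigma_k}. This removes the bias a
#' feature would inherit purely from its neighborhood size and from the
#' overall shift of the Z pool.
#'
#' @param z_agg raw aggregate score.
#' @param k neighborhood size used to form `z_agg`; must not exceed the pool.
#' @param z_pool numeric vector of all measured genes' Z-scores.
#' @param n_samples Monte-Carlo draws (default 1e5, minimum 1000).
#' @param seed integer seed.
#' @return the corrected Z-score (scalar).
#' @export
background_correct <- function(z_agg, k, z_pool, n_samples = 1e5, seed = 1L) {
  if (n_samples < 1000) stop_invalid("n_samples must be >= 1000")
  if (k < 1 || k > length(z_pool))
    stop_invalid("k must be in [1, length(z_pool)]")
  mom <- with_seed(seed, background_moments(k, z_pool, n_samples))
  if (!is.finite(mom[["sigma"]]) || mom[["sigma"]] == 0)
    stop_invalid("degenerate Z pool: null aggregate has zero variance")
  (z_agg - mom[["mu"]]) / mom[["sigma"]]
}

#' Score reporter features (TFs or receptors) on a bipartite network
#'
#' Full reporter-features chain: gene p-values are converted to upper-tail
#' Z-scores, summed over each feature's measured neighborhood as
#' \eqn{\sum Z_i / \sqrt{k}}, background-corrected against random same-size
#' gene sets from the whole measured-gene pool, converted to a one-sided
#' p-value \eqn{p = 1 - \Phi(Z_{corr})} and BH-adjusted across features.
#' A feature is a significant reporter iff its adjusted p-value (or raw
#' p-value when `raw_threshold = TRUE`) is below `alpha`.
#'
#' @param results gene-level statistics: a data.frame with `gene` and `p`, a
#'   named p-value vector, or a list of per-dataset data.frames (combined
#'   with [combine_pvalues()] using `combine`).
#' @param net bipartite network: data.frame with `feature` and `gene`
#'   columns (first two columns used), e.g. a TRRUST-style TF-target table
#'   or a receptor-protein table.
#' @param alpha significance cutoff (default 0.001).
#' @param n_samples Monte-Carlo draws per distinct neighborhood size.
#' @param seed integer seed for the background sampling.
#' @param raw_threshold flag the `significant` column on the raw instead of
#'   the BH-adjusted p-value.
#' @param combine p-value combination method when `results` is a list.
#' @return data.frame sorted by p (ties by feature id): `feature`, `k`,
#'   `z_agg`, `z_corrected`, `p`, `p_adj`, `significant`.
#' @export
score_reporters <- function(results, net, alpha = 0.001, n_samples = 1e5,
                            seed = 1L, raw_threshold = FALSE,
                            combine = c("fisher", "stouffer")) {
  if (is.list(results) && !is.data.frame(results) && !is.numeric(results))
    results <- combine_pvalues(results, method = match.arg(combine))
  z <- gene_zscores(results)
  stopifnot(is.data.frame(net), ncol(net) >= 2)
  edges <- data.frame(feature = as.character(net[[1]]),
                      gene = as.character(net[[2]]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges[edges$gene %in% names(z), , drop = FALSE])
  if (nrow(edges) == 0)
    stop_invalid("no network edge maps onto a measured gene")
  neigh <- split(edges$gene, edges$feature)
  agg <- lapply(neigh, function(nb) aggregate_feature(z, nb))
  keep <- !vapply(agg, is.null, TRUE)
  agg <- agg[keep]
  feat <- names(agg)
  k <- vapply(agg, `[[`, 0, "k")
  z_agg <- vapply(agg, `[[`, 0.0, "z_agg")

  # one seeded stream; moments computed per distinct k in increasing order,
  # cached, so the full table is identical across runs
  mom <- with_seed(seed, {
    ks <- sort(unique(k))
    stats::setNames(lapply(ks, function(kk) {
      m <- background_moments(kk, z, n_samples)
      if (!is.finite(m[["sigma"]]) || m[["sigma"]] == 0)
        stop_invalid("degenerate Z pool: null aggregate has zero variance")
      m
    }), ks)
  })
  mu <- vapply(as.character(k), function(kk) mom[[kk]][["mu"]], 0.0)
  sigma <- vapply(as.character(k), function(kk) mom[[kk]][["sigma"]], 0.0)
  z_corr <- (z_agg - mu) / sigma
  p <- stats::pnorm(z_corr, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  out <- data.frame(feature = feat, k = as.integer(k), z_agg = z_agg,
                    z_corrected = z_corr, p = p, p_adj = p_adj,
                    significant = (if (raw_threshold) p else p_adj) < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
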