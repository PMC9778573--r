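#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Fits, per gene, an equal-variance two-group linear model (case vs control)
#' and shrinks the residual variances toward a common prior. The prior
#' (`d0` degrees of freedom, `s0^2` scale) is estimated by fitting a scaled
#' inverse-chi-square distribution to the observed sample variances via
#' method-of-moments on the log variances; the moderated statistic
#' \deqn{\tilde t_g = \frac{\bar x_{g,case} - \bar x_{g,ctrl}}
#'   {\tilde s_g \sqrt{1/n_1 + 1/n_2}}, \quad
#'   \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#' is referred to a t distribution on `d_g + d0` degrees of freedom.
#' Borrowing strength across genes stabilizes the per-gene variance at the
#' small sample sizes typical of microarray case/control series.
#'
#' @param data an [expression_dataset()].
#' @param force_d0 optional override of the prior degrees of freedom:
#'   `0` recovers the ordinary pooled t-test exactly, `Inf` replaces every
#'   `s_g^2` by `s0^2`. Mainly for testing and sensitivity analysis.
#' @return data.frame, one row per gene: `gene`, `log2fc` (case minus
#'   control mean), `t_moderated`, `df_total`, `p` (two-sided, unadjusted).
#' @seealso [call_degs()] to apply significance and fold-change cutoffs.
#' @export
moderated_ttest <- function(data, force_d0 = NULL) {
  stopifnot(inherits(data, "ExpressionDataset"))
  mat <- data$matrix
  is_case <- data$sample_labels == "case"
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  dg <- n1 + n2 - 2L
  if (dg < 2L) stop_invalid("need at least 2 residual degrees of freedom")

  m1 <- rowMeans(mat[, is_case, drop = FALSE])
  m2 <- rowMeans(mat[, !is_case, drop = FALSE])
  v1 <- apply(mat[, is_case, drop = FALSE], 1L, stats::var)
  v2 <- apply(mat[, !is_case, drop = FALSE], 1L, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (all(s2 == 0)) stop_invalid("all genes have zero residual variance")

  prior <- fit_variance_prior(s2[s2 > 0], dg)
  d0 <- if (is.null(force_d0)) prior$d0 else force_d0
  s02 <- prior$s02

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df_total <- dg + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tt))
       else 2 * stats::pt(-abs(tt), df = df_total)

  data.frame(gene = rownames(mat), log2fc = m1 - m2, t_moderated = tt,
             df_total = df_total, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Method-of-moments fit of a scaled inverse-chi-square prior to sample
# variances s2 with common df dg, working on z = log(s2):
#   E[z] = log s0^2 + psi(dg/2) - log(dg/2) - (psi(d0/2) - log(d0/2))
#   Var[z] = psi'(dg/2) + psi'(d0/2)
# Returns d0 = Inf when the observed log-variance spread does not exceed the
# chi-square sampling noise (no evidence of variance heterogeneity).
fit_variance_prior <- function(s2, dg) {
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2) * n / max(n - 1, 1) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(x) = y; y > 0
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotone enforcement, capped at 1 and returned in
#' the input order. Thin validating wrapper around [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_invalid("p-values must lie in [0, 1] and contain no NA")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes by dual significance cutoff
#'
#' A gene is differential iff its BH-adjusted p-value is below `alpha` AND its
#' absolute fold change reaches `fc_threshold` (i.e. `|log2fc| >=
#' log2(fc_threshold)`); the regulation direction follows the sign of the
#' fold change.
#'
#' @param results data.frame from [moderated_ttest()]; a `p_adj` column is
#'   computed with [bh_adjust()] if absent.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @param fc_threshold fold-change cutoff on the natural scale (default 2,
#'   i.e. `|log2fc| >= 1`).
#' @return data.frame of the genes passing both cutoffs: `gene`, `log2fc`,
#'   `p`, `p_adj`, `direction` (`"up"` or `"down"`).
#' @export
call_degs <- function(results, alpha = 0.05, fc_threshold = 2) {
  stopifnot(is.data.frame(results), all(c("gene", "log2fc", "p") %in% names(results)))
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must be in (0, 1]")
  if (fc_threshold < 1) stop_invalid("fc_threshold must be >= 1")
  if (is.null(results$p_adj)) results$p_adj <- bh_adjust(results$p)
  lfc_cut <- log2(fc_threshold)
  keep <- results$p_adj < alpha & abs(results$log2fc) >= lfc_cut
  out <- results[keep, c("gene", "log2fc", "p", "p_adj"), drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Intersect per-dataset DEG calls into a common signature
#'
#' Membership is by gene identifier only ("excluding the regulatory
#' patterns"): a gene up-regulated in one dataset and down-regulated in
#' another stays in the intersection but is flagged as a direction conflict.
#'
#' @param per_dataset named list (>= 2 elements) of [call_degs()] tables.
#' @return list of class `CommonDEGSet`: `genes` (sorted character vector),
#'   `directions` (data.frame gene x dataset) and `conflict` (logical per
#'   gene).
#' @export
intersect_degs <- function(per_dataset) {
  if (!is.list(per_dataset) || length(per_dataset) < 2)
    stop_invalid("need at least 2 DEG tables to intersect")
  if (is.null(names(per_dataset)))
    names(per_dataset) <- paste0("dataset_", seq_along(per_dataset))
  sets <- lapply(per_dataset, function(d) d$gene)
  common <- sort(Reduce(intersect, sets))
  dirs <- as.data.frame(lapply(per_dataset, function(d) {
    d$direction[match(common, d$gene)]
  }), stringsAsFactors = FALSE, optional = TRUE)
  if (length(common) > 0) rownames(dirs) <- common
  conflict <- if (length(common) > 0)
    apply(dirs, 1L, function(r) length(unique(r)) > 1L)
  else logical(0)
  structure(list(genes = common, directions = dirs,
                 conflict = stats::setNames(conflict, common)),
            class = "CommonDEGSet")
}

#' @export
print.CommonDEGSet <- function(x, ...) {
  cat(sprintf("CommonDEGSet: %d genes common to %d datasets (%d direction conflicts)\n",
              length(x$genes), ncol(x$directions), sum(x$conflict)))
  invisible(x)
}

#' Over-representation analysis by the hypergeometric tail
#'
#' Tests each annotated gene set for enrichment in a query set (one-sided
#' Fisher test): `P(X >= overlap)` where `X` is hypergeometric with the set,
#' the query and a common gene universe. Gene sets are intersected with the
#' universe before testing; p-values are BH-adjusted across sets.
#'
#' @param query character gene set (must be contained in `universe`).
#' @param gene_sets named list of character vectors.
#' @param universe character background universe.
#' @param alpha adjusted-p cutoff for the `significant` flag (default 0.01).
#' @return data.frame sorted by p: `set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `p_adj`, `significant`.
#' @export
hypergeometric_ora <- function(query, gene_sets, universe, alpha = 0.01) {
  if (length(universe) == 0) stop_invalid("universe is empty")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop_invalid("query contains genes outside the universe")
  if (length(gene_sets) == 0 || is.null(names(gene_sets)))
    stop_invalid("gene_sets must be a named list")
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(query, gs))
    p <- stats::phyper(ov - 1, length(gs), length(universe) - length(gs),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(gs),
               query_size = length(query), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
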