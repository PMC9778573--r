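#' Area under the ROC curve by the Mann-Whitney probability
#'
#' `AUC = (#concordant pairs + 0.5 * #tied pairs) / (n_case * n_control)`,
#' i.e. the probability that a randomly chosen case scores above a randomly
#' chosen control. Computed from midranks, which is algebraically identical
#' to pair enumeration. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric score per sample (e.g. expression of one gene).
#' @param labels binary labels per sample; the positive class is `"case"`
#'   (or `1`/`TRUE`).
#' @return scalar AUC in `[0, 1]` (not orientation-corrected).
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels %in% c("case", "dead", 1, TRUE)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_invalid("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Screen candidate genes for diagnostic power by orientation-maximized AUC
#'
#' Each candidate's expression is scored against the case/control labels;
#' because a marker may separate the classes in either direction, the
#' reported AUC is `max(raw, 1 - raw)` with the orientation recorded. A gene
#' is a diagnostic biomolecule iff its AUC reaches `threshold`.
#'
#' @param expr an [expression_dataset()] (the validation cohort).
#' @param candidates character vector of gene identifiers to screen.
#' @param threshold AUC cutoff (default 0.70).
#' @return data.frame sorted by decreasing AUC: `gene`, `auc`, `orientation`
#'   (`"up"` = higher in cases), `diagnostic_flag`. Unmeasured candidates
#'   are reported with NA values.
#' @export
screen_diagnostic <- function(expr, candidates, threshold = 0.70) {
  stopifnot(inherits(expr, "ExpressionDataset"))
  candidates <- unique(candidates)
  measured <- candidates[candidates %in% expr$gene_ids]
  if (length(measured) == 0)
    stop_invalid("no candidate is measured in the validation cohort")
  rows <- lapply(candidates, function(g) {
    if (!g %in% measured)
      return(data.frame(gene = g, auc = NA_real_,
                        orientation = NA_character_, diagnostic_flag = NA))
    raw <- auc(expr$matrix[g, ], expr$sample_labels)
    data.frame(gene = g, auc = max(raw, 1 - raw),
               orientation = if (raw >= 0.5) "up" else "down",
               diagnostic_flag = max(raw, 1 - raw) >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$auc), -Inf, out$auc), out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a univariate Cox proportional-hazards coefficient
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) for a single
#' covariate. A monotone likelihood (infinite coefficient) or failed
#' convergence is raised as an error rather than returned silently.
#'
#' @param x numeric covariate per sample (e.g. standardized expression).
#' @param surv data.frame with `time_days` and `event` columns, rows aligned
#'   with `x`.
#' @return scalar `beta`, the log hazard ratio per unit of `x`.
#' @export
fit_univariate_cox <- function(x, surv) {
  stopifnot(is.numeric(x), is.data.frame(surv),
            all(c("time_days", "event") %in% names(surv)),
            length(x) == nrow(surv))
  if (sum(surv$event) < 1) stop_invalid("no events observed")
  if (stats::sd(x) == 0) stop_invalid("constant covariate")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(surv$time_days, surv$event) ~ x,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w),
                ignore.case = TRUE))
        stop_invalid("Cox fit did not converge: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  unname(stats::coef(fit))
}

#' Split samples into high/low risk groups by prognostic index
#'
#' High risk = prognostic index strictly above the cut quantile (default the
#' median); samples tied at the cut fall into the low-risk group, so the
#' split is deterministic and group sizes differ by at most 1 for an
#' all-distinct even/odd `pi`.
#'
#' @param pi numeric prognostic index per sample (`beta * x`).
#' @param probs quantile for the cut point (default 0.5).
#' @return factor with levels `c("high", "low")`, same length as `pi`.
#' @export
split_risk_groups <- function(pi, probs = 0.5) {
  if (length(pi) < 2) stop_invalid("need at least 2 samples to split")
  cut <- stats::quantile(pi, probs = probs, names = FALSE, type = 7)
  factor(ifelse(pi > cut, "high", "low"), levels = c("high", "low"))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' @param surv data.frame with `time_days` and `event`.
#' @return list: `time` (distinct event times), `surv` (survival probability
#'   after each), `n_risk`, `n_event`, and `fn`, a right-continuous step
#'   function `t -> S(t)`. With no events the estimate is identically 1.
#' @export
kaplan_meier <- function(surv) {
  stopifnot(is.data.frame(surv), all(c("time_days", "event") %in% names(surv)))
  if (nrow(surv) == 0) stop_invalid("empty survival table")
  if (any(surv$time_days < 0)) stop_invalid("negative follow-up time")
  fit <- survival::survfit(survival::Surv(surv$time_days, surv$event) ~ 1)
  keep <- fit$n.event > 0
  time <- fit$time[keep]
  s <- fit$surv[keep]
  fn <- if (length(time) == 0) function(t) rep(1, length(t))
        else stats::stepfun(time, c(1, s), right = FALSE)
  list(time = time, surv = s, n_risk = fit$n.risk[keep],
       n_event = fit$n.event[keep], fn = fn)
}

#' Two-group log-rank test with observed/expected hazard ratio
#'
#' At each distinct event time the expected number of deaths in group 1 is
#' accumulated under the hypergeometric null (`E1 += d_t * n1t / nt`),
#' giving the log-rank chi-square `(O1 - E1)^2 / V` on 1 df and the hazard
#' ratio as the ratio of relative mortality rates
#' `HR = (O1 / E1) / (O2 / E2)`, where O and E are observed and expected
#' deaths per group.
#'
#' @param surv data.frame with `time_days` and `event`.
#' @param group factor/vector with exactly two levels; the first level (for
#'   a factor) is group 1.
#' @return list: `O1`, `E1`, `O2`, `E2`, `chi2`, `p`, `hr`.
#' @export
logrank <- function(surv, group) {
  stopifnot(is.data.frame(surv), all(c("time_days", "event") %in% names(surv)),
            length(group) == nrow(surv))
  group <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(group) != 2) stop_invalid("need exactly 2 non-empty groups")
  if (sum(surv$event) < 1) stop_invalid("no events observed")
  sd_fit <- survival::survdiff(
    survival::Surv(surv$time_days, surv$event) ~ group)
  O <- unname(sd_fit$obs)
  E <- unname(sd_fit$exp)
  V <- sd_fit$var[1, 1]
  if (!is.finite(V) || V <= 0)
    stop_invalid("log-rank variance is zero; groups carry no comparable events")
  chi2 <- (O[1] - E[1])^2 / V
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  hr <- if (E[1] == 0 || E[2] == 0) {
    warning("expected deaths zero in one group; hazard ratio undefined")
    if (E[1] == 0 && O[1] > 0) Inf else if (E[2] == 0 && O[2] > 0) 0 else NaN
  } else {
    (O[1] / E[1]) / (O[2] / E[2])
  }
  list(O1 = O[1], E1 = E[1], O2 = O[2], E2 = E[2],
       chi2 = chi2, p = p, hr = hr)
}

#' Screen candidate genes for prognostic power
#'
#' Per gene: fit a univariate Cox coefficient on (optionally standardized)
#' expression, form the prognostic index `PI = beta * x`, split samples into
#' high/low risk at the median PI, and compare the groups by the log-rank
#' test with the observed/expected hazard ratio. A gene is prognostic iff
#' its log-rank p-value is below `alpha`. Genes whose Cox fit fails are
#' returned as NA rows so a screen never aborts mid-panel.
#'
#' @param expr an [expression_dataset()] (validation cohort).
#' @param surv data.frame `sample`, `time_days`, `event`; matched to the
#'   expression columns by sample id.
#' @param candidates character vector of genes to screen.
#' @param alpha log-rank significance cutoff (default 0.05).
#' @param standardize z-score expression per gene before the Cox fit
#'   (default TRUE, so `beta` is per standard deviation).
#' @param probs risk-split quantile (default median).
#' @return data.frame sorted by `logrank_p`: `gene`, `beta`, `O1`, `E1`,
#'   `O2`, `E2`, `hr`, `logrank_p`, `prognostic_flag`, plus mean expression
#'   per risk group (`mean_expr_high`, `mean_expr_low`).
#' @export
screen_prognostic <- function(expr, surv, candidates, alpha = 0.05,
                              standardize = TRUE, probs = 0.5) {
  stopifnot(inherits(expr, "ExpressionDataset"), is.data.frame(surv),
            all(c("sample", "time_days", "event") %in% names(surv)))
  common <- intersect(colnames(expr$matrix), surv$sample)
  if (length(common) == 0)
    stop_invalid("no samples shared between expression and survival data")
  surv <- surv[match(common, surv$sample), , drop = FALSE]
  na_row <- function(g) data.frame(
    gene = g, beta = NA_real_, O1 = NA_real_, E1 = NA_real_, O2 = NA_real_,
    E2 = NA_real_, hr = NA_real_, logrank_p = NA_real_,
    prognostic_flag = NA, mean_expr_high = NA_real_, mean_expr_low = NA_real_,
    stringsAsFactors = FALSE)
  rows <- lapply(unique(candidates), function(g) {
    if (!g %in% expr$gene_ids) return(na_row(g))
    x <- expr$matrix[g, common]
    if (standardize) {
      if (stats::sd(x) == 0) return(na_row(g))
      x <- as.vector(scale(x))
    }
    res <- tryCatch({
      beta <- fit_univariate_cox(x, surv)
      grp <- split_risk_groups(beta * x, probs = probs)
      lr <- logrank(surv, grp)
      data.frame(gene = g, beta = beta, O1 = lr$O1, E1 = lr$E1, O2 = lr$O2,
                 E2 = lr$E2, hr = lr$hr, logrank_p = lr$p,
                 prognostic_flag = lr$p < alpha,
                 mean_expr_high = mean(expr$matrix[g, common][grp == "high"]),
                 mean_expr_low = mean(expr$matrix[g, common][grp == "low"]),
                 stringsAsFactors = FALSE)
    }, error = function(e) na_row(g))
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(ifelse(is.na(out$logrank_p), Inf, out$logrank_p),
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
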