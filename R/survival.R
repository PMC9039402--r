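#' Univariate Cox proportional-hazards fit for one feature
#'
#' Fits `Surv(time, event) ~ x` by Cox partial likelihood with the Breslow
#' tie convention (via [survival::coxph()]), returning the log hazard
#' ratio per expression unit, its standard error and the Wald p-value.
#' Degenerate inputs are flagged rather than silently propagated: a
#' constant covariate gives `beta = 0` with `converged = FALSE` (the
#' partial likelihood is flat), and monotone-likelihood separation gives a
#' capped `beta` with `converged = FALSE` and a warning.
#'
#' @param expr Numeric vector, one value per sample in `clinical` order.
#' @param clinical Data frame with `time` and `event` columns.
#' @param feature_id Optional identifier carried into the result.
#' @return List with `feature_id`, `beta`, `se`, `p_value`, `converged`.
#' @export
cox_univariate <- function(expr, clinical, feature_id = NA_character_) {
  clinical <- validate_clinical(clinical)
  if (length(expr) != nrow(clinical))
    stop("one expression value per clinical sample required")
  if (any(!is.finite(expr))) stop("expression values must be finite")
  if (sum(clinical$event) == 0) stop("no events in clinical table")
  if (stats::sd(expr) == 0)
    return(list(feature_id = feature_id, beta = 0, se = NA_real_,
                p_value = 1, converged = FALSE))
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(clinical$time, clinical$event) ~ expr,
                    ties = "breslow"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1L]
  converged <- is.finite(beta) && is.finite(se) && abs(beta) < 15 && se < 100
  if (!converged) {
    warning("monotone likelihood / non-convergence; beta capped")
    beta <- sign(beta) * min(abs(beta), 15)
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(feature_id = feature_id, beta = beta, se = se,
       p_value = max(p, .Machine$double.xmin), converged = converged)
}

#' Risk model from per-feature Cox coefficients
#'
#' @param features Ordered character vector of feature ids.
#' @param betas Matching numeric vector of univariate Cox coefficients.
#' @return A `risk_model` object.
#' @export
risk_model <- function(features, betas) {
  if (length(features) != length(betas) || length(features) < 1L)
    stop("features and betas must be non-empty and of equal length")
  structure(list(features = as.character(features), betas = as.numeric(betas)),
            class = "risk_model")
}

#' Fit a risk model by univariate Cox screening
#'
#' Convenience constructor: one [cox_univariate()] fit per requested
#' feature of a log2 expression matrix.
#'
#' @param expr log2-scale `ExpressionMatrix`.
#' @param clinical Clinical table whose `sample_id`s appear in `expr`.
#' @param features Features to include (default: all rows of `expr`).
#' @return List with `model` (a `risk_model`) and `fits` (data frame of
#'   per-feature `beta`, `se`, `p_value`, `converged`).
#' @export
fit_risk_model <- function(expr, clinical, features = rownames(expr)) {
  clinical <- validate_clinical(clinical)
  missing_s <- setdiff(clinical$sample_id, colnames(expr))
  if (length(missing_s))
    stop("clinical samples absent from expression matrix: ",
         paste(utils::head(missing_s, 3), collapse = ", "))
  fits <- lapply(features, function(f) {
    if (!f %in% rownames(expr)) stop("feature missing from matrix: ", f)
    cox_univariate(as.numeric(expr[f, clinical$sample_id]), clinical, f)
  })
  df <- do.call(rbind, lapply(fits, function(x)
    data.frame(feature_id = x$feature_id, beta = x$beta, se = x$se,
               p_value = x$p_value, converged = x$converged,
               stringsAsFactors = FALSE)))
  list(model = risk_model(df$feature_id, df$beta), fits = df)
}

#' Risk scores and mean-cutoff stratification
#'
#' Computes `score_s = sum_i beta_i * Exp_i(s)` per sample and stratifies
#' at the arithmetic mean of the scores: samples strictly above the mean
#' are `high` risk, all others (including samples exactly at the mean)
#' `low`.
#'
#' @param model A [risk_model()].
#' @param expr log2-scale `ExpressionMatrix` containing every model
#'   feature.
#' @return A `risk_stratification` data frame (`sample_id`, `score`,
#'   `group`) with attributes `cutoff` and `degenerate` (all scores
#'   equal).
#' @export
risk_score <- function(model, expr) {
  stopifnot(inherits(model, "risk_model"))
  miss <- setdiff(model$features, rownames(expr))
  if (length(miss))
    stop("model feature(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))
  x <- unclass(expr)[model$features, , drop = FALSE]
  score <- as.numeric(crossprod(x, model$betas))
  cutoff <- mean(score)
  group <- factor(ifelse(score > cutoff, "high", "low"),
                  levels = c("low", "high"))
  degenerate <- length(unique(score)) == 1L
  if (degenerate) warning("all risk scores identical; stratification degenerate")
  structure(data.frame(sample_id = colnames(expr), score = score,
                       group = group, stringsAsFactors = FALSE),
            cutoff = cutoff, degenerate = degenerate,
            class = c("risk_stratification", "data.frame"))
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit survival estimates per group (via
#' [survival::survfit()]) and the log-rank chi-square with 1 degree of
#' freedom (via [survival::survdiff()]).
#'
#' @param clinical Data frame with `time`, `event` (and optionally
#'   `sample_id`).
#' @param groups Two-level factor over the rows of `clinical`.
#' @return List with `curves` (per-group data frame: `group`, `time`,
#'   `surv`, `n_risk`, `n_event`), `logrank_chi2`, `logrank_p`.
#' @export
km_logrank <- function(clinical, groups) {
  clinical <- validate_clinical(cbind(
    sample_id = if ("sample_id" %in% names(clinical)) clinical$sample_id
                else as.character(seq_len(nrow(clinical))),
    clinical[c("time", "event")]))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two non-empty groups required")
  if (length(groups) != nrow(clinical)) stop("one group label per sample")
  sv <- survival::Surv(clinical$time, clinical$event)
  fit <- survival::survfit(sv ~ groups)
  strata_grp <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata_grp, time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE)
  if (sum(clinical$event) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(curves = curves, logrank_chi2 = 0, logrank_p = 1))
  }
  sd <- survival::survdiff(sv ~ groups)
  chi2 <- unname(sd$chisq)
  list(curves = curves, logrank_chi2 = chi2,
       logrank_p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Area under the ROC curve by the rank formulation
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' randomly chosen positive outscores a randomly chosen negative, ties
#' counting one half.
#'
#' @param scores Numeric vector.
#' @param labels Binary outcome (0/1, logical, or two-level factor whose
#'   second level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
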