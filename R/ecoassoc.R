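# Partner-association and environmental-association models.

#' Pearson chi-squared test on a contingency table
#'
#' Chi-squared test of independence with Yates continuity correction on by
#' default for 2x2 tables — the convention that reproduces the printed
#' partner-association statistic from the raw co-occurrence counts.
#'
#' @param tab matrix of non-negative integer counts (typically 2x2), or a
#'   vector of four counts filled by row.
#' @param correct apply the continuity correction (2x2 only; default TRUE).
#' @return A one-row tibble: `chi2`, `df`, `p`.
#' @export
#' @examples
#' contingency_chisq(c(100, 65, 96, 44))  # chi2 = 1.76, p = 0.18
contingency_chisq <- function(tab, correct = TRUE) {
  if (!is.matrix(tab)) {
    if (length(tab) != 4) abort("supply a matrix or four counts")
    tab <- matrix(tab, 2, 2, byrow = TRUE)
  }
  if (any(tab < 0) || any(tab != round(tab)))
    abort("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("zero row or column marginal")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Correlation-matrix PCA of climate variables
#'
#' Standardizes the (incommensurate: mm and degrees C) climate variables
#' and performs PCA on the correlation matrix; PC1 is the climate gradient
#' used as a covariate in the association models.
#'
#' @param env data frame containing the climate columns.
#' @param vars character vector of column names; default: all columns
#'   matching `^bio`.
#' @return A `chc_pca` object (scores, loadings, `eigen_pct`).
#' @export
climate_pca <- function(env, vars = NULL) {
  env <- as_tibble(env)
  vars <- vars %||% grep("^bio", names(env), value = TRUE)
  if (length(vars) < 2) abort("need >= 2 climate variables")
  m <- as.matrix(env[vars])
  if (anyNA(m)) abort("climate columns must be complete")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    abort(sprintf("constant climate variable: %s",
                  vars[which(sds == 0)[1]]))
  if ("sample" %in% names(env)) rownames(m) <- env$sample
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  ev <- p$sdev^2
  structure(
    list(scores = p$x, loadings = p$rotation,
         eigen_pct = 100 * ev / sum(ev), center = p$center,
         scale = p$scale, sdev = p$sdev),
    class = "chc_pca")
}

#' Binomial GLM with separation diagnostics
#'
#' Logit-link binomial regression fitted by iteratively reweighted least
#' squares (to convergence tolerance 1e-8, at most 100 iterations), with a
#' quasi-separation check: the fit is flagged when fitted probabilities
#' collapse to 0/1 or coefficients diverge.
#'
#' @param formula model formula; the response must be binary (0/1 or a
#'   two-level factor).
#' @param data data frame of covariates.
#' @return A `glm` object with extra class `eco_glm` and attribute
#'   `separation` (logical).  `tidy()`/`glance()` work via broom.
#' @export
fit_binomial_glm <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) abort("response must be binary (0/1)")
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) abort("collinear design matrix")
  fit <- glm(formula, family = binomial("logit"), data = data,
             control = list(epsilon = 1e-8, maxit = 100))
  eps <- 1e-8
  sep <- !fit$converged ||
    any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(abs(coef(fit)) > 15)
  if (sep) warn("possible (quasi-)separation detected in binomial GLM")
  attr(fit, "separation") <- sep
  class(fit) <- c("eco_glm", class(fit))
  fit
}

#' Backward stepwise model reduction by AIC
#'
#' Repeatedly removes the single term whose removal lowers the AIC most
#' (via `drop1`, which respects marginality: an interaction is eligible
#' before its main effects and a main effect is never dropped while its
#' interaction remains), stopping when no removal lowers the AIC.  Ties
#' break deterministically by term order.
#'
#' @param fit a fitted [fit_binomial_glm()] (or any `glm`).
#' @return The reduced fit, with the elimination trace (term removed and
#'   AIC at each step) in attribute `aic_trace`.
#' @export
stepwise_aic <- function(fit) {
  trace <- tibble(step = 0L, dropped = NA_character_,
                  aic = stats::AIC(fit))
  step_i <- 0L
  repeat {
    dr <- drop1(fit, test = "none")
    cand <- rownames(dr)[-1]
    if (length(cand) == 0) break
    aics <- dr$AIC[-1]
    best <- which.min(aics)  # first minimum wins ties (term order)
    if (aics[best] >= stats::AIC(fit) - 1e-12) break
    step_i <- step_i + 1L
    newcall <- update(fit, as.formula(paste(". ~ . -", cand[best])),
                      evaluate = FALSE)
    fit <- eval(newcall, list(data = fit$data),
                environment(formula(fit)))
    trace <- bind_rows(trace,
                       tibble(step = step_i, dropped = cand[best],
                              aic = stats::AIC(fit)))
  }
  attr(fit, "aic_trace") <- trace
  fit
}

#' Analysis-of-deviance test between nested binomial GLMs
#'
#' Likelihood-ratio chi-squared: `chi2 = deviance_reduced - deviance_full`
#' on `df` = difference in parameter count, the statistic reported per
#' model term in the association analysis.
#'
#' @param full,reduced nested `glm` fits (same data; `reduced`'s terms a
#'   subset of `full`'s).
#' @return A one-row tibble: `chi2`, `df`, `p`.
#' @export
deviance_term_test <- function(full, reduced) {
  t_full <- attr(terms(full), "term.labels")
  t_red <- attr(terms(reduced), "term.labels")
  if (!all(t_red %in% t_full))
    abort("`reduced` is not nested in `full`")
  df <- length(coef(full)) - length(coef(reduced))
  if (df < 0) abort("`reduced` has more parameters than `full`")
  chi2 <- max(0, reduced$deviance - full$deviance)
  tibble(chi2 = chi2, df = as.integer(df),
         p = if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE))
}
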