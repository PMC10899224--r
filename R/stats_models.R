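## Mixed-effects inference layer: maximum-likelihood LME fits with Wald
## intervals, named model presets, and a parametric-bootstrap likelihood-ratio
## comparison.

#' Fit a linear mixed-effects model (ML) with Wald summaries
#'
#' Thin wrapper over [lme4::lmer()] fitted by maximum likelihood (so
#' log-likelihoods are comparable across fixed-effect structures), with
#' unstructured (Cholesky-parameterized) random-effect covariance — lme4's
#' default — and Wald 95% confidence intervals and two-sided p-values per
#' fixed effect using a residual degrees-of-freedom approximation.
#'
#' If a grouping factor has a single level the formula is degraded by
#' dropping that random term, with a warning.
#'
#' @param formula an lmer formula.
#' @param data data.frame with no missing values in the model columns.
#' @param df_method `"residual"` (t with n - p df) or `"normal"` (z).
#' @return list of class `lme_fit`: `coefficients` (data.frame with
#'   `estimate`, `ci_lo`, `ci_hi`, `p_value`), `loglik`, `n_obs`, `model`.
#' @export
fit_lme <- function(formula, data, df_method = c("residual", "normal")) {
  df_method <- match.arg(df_method)
  vars <- all.vars(formula)
  if (anyNA(data[, intersect(vars, names(data))]))
    stop("missing values in model columns")
  bars <- lme4::findbars(formula)
  grp_vars <- unique(unlist(lapply(bars, function(b) all.vars(b[[3]]))))
  single <- grp_vars[vapply(grp_vars,
                            function(g) length(unique(data[[g]])) < 2, TRUE)]
  if (length(single)) {
    warning("grouping factor(s) with one level dropped: ",
            paste(single, collapse = ", "))
    keep <- vapply(bars, function(b)
      !any(all.vars(b[[3]]) %in% single), TRUE)
    rhs_fixed <- deparse(lme4::nobars(formula)[[3]])
    rhs_rand <- vapply(bars[keep], function(b)
      paste0("(", deparse(b), ")"), "")
    if (!length(rhs_rand))
      stop("no random terms left; use lm for a fixed-effects-only model")
    formula <- stats::reformulate(c(rhs_fixed, rhs_rand),
                                  response = vars[1])
  }
  fit <- lme4::lmer(formula, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- stats::nobs(fit)
  p <- length(co)
  tval <- co / se
  if (df_method == "residual") {
    df <- max(n - p, 1)
    pv <- 2 * stats::pt(-abs(tval), df)
    q <- stats::qt(0.975, df)
  } else {
    pv <- 2 * stats::pnorm(-abs(tval))
    q <- stats::qnorm(0.975)
  }
  structure(list(
    coefficients = data.frame(term = names(co), estimate = unname(co),
                              se = unname(se),
                              ci_lo = unname(co - q * se),
                              ci_hi = unname(co + q * se),
                              p_value = unname(pv)),
    loglik = as.numeric(stats::logLik(fit)), n_obs = n, model = fit,
    formula = formula), class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("<lme_fit> ", deparse(x$formula), "  (ML, n =", x$n_obs, ")\n")
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, 3)
  cf$ci <- sprintf("[%.3g, %.3g]", cf$ci_lo, cf$ci_hi)
  cf$p_value <- signif(cf$p_value, 2)
  print(cf[, c("term", "estimate", "ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Parametric-bootstrap likelihood-ratio comparison of nested LME fits
#'
#' Simulates responses from the null fit, refits both models on each
#' simulated response and compares the observed likelihood-ratio statistic
#' to the bootstrap distribution: `p = (1 + #\{LR* >= LR\}) / (n_reps + 1)`.
#'
#' @param fit_null,fit_alt [fit_lme()] results on the same data; the null
#'   fixed effects must be nested in the alternative's.
#' @param n_reps bootstrap replications.
#' @param seed RNG seed.
#' @return list(`lr`, `p_value`, `lr_boot`).
#' @export
compare_lme_bootstrap <- function(fit_null, fit_alt, n_reps = 100,
                                  seed = 1L) {
  stopifnot(inherits(fit_null, "lme_fit"), inherits(fit_alt, "lme_fit"))
  if (fit_null$n_obs != fit_alt$n_obs)
    stop("models must be fitted on the same data")
  t0 <- attr(stats::terms(lme4::nobars(fit_null$formula)), "term.labels")
  t1 <- attr(stats::terms(lme4::nobars(fit_alt$formula)), "term.labels")
  if (!all(t0 %in% t1))
    stop("models are not nested (null fixed effects must be a subset)")
  lr <- 2 * (fit_alt$loglik - fit_null$loglik)
  with_seed(seed, {
    sims <- stats::simulate(fit_null$model, nsim = n_reps)
    lr_boot <- vapply(seq_len(n_reps), function(i) {
      y <- sims[[i]]
      m0 <- lme4::refit(fit_null$model, y)
      m1 <- lme4::refit(fit_alt$model, y)
      2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0)))
    }, 0)
    list(lr = lr, p_value = (1 + sum(lr_boot >= lr)) / (n_reps + 1),
         lr_boot = lr_boot)
  })
}

#' Named model presets for the pipeline's standard analyses
#'
#' One-call formulas for the analyses the pipeline reports:
#' \describe{
#'   \item{stage-contrast}{band power ~ sleep stage, participant and night
#'     random intercepts.}
#'   \item{disease-contrast}{night-level band-power change ~ disease group,
#'     participant random intercept.}
#'   \item{on-off}{band power ~ stimulation state, participant random
#'     intercept.}
#'   \item{beta-delta}{epoch-level cortical delta ~ subcortical beta, with
#'     hemisphere and night random intercepts within participant.}
#'   \item{beta-delta-hemisphere}{single-participant variant: cortical delta
#'     ~ subcortical beta with hemisphere as random effect.}
#'   \item{quadrant}{cortical delta ~ subcortical beta * night quadrant
#'     (first vs last), night random intercept.}
#' }
#'
#' @param name preset name.
#' @return an lmer formula.
#' @export
lme_preset <- function(name = c("stage-contrast", "disease-contrast",
                                "on-off", "beta-delta",
                                "beta-delta-hemisphere", "quadrant")) {
  name <- match.arg(name)
  switch(name,
    "stage-contrast" =
      power ~ stage + (1 | participant_id) + (1 | participant_id:night_id),
    "disease-contrast" = power_change ~ disease + (1 | participant_id),
    "on-off" = power ~ stim_state + (1 | participant_id),
    "beta-delta" = cort_delta ~ subcort_beta + (1 | participant_id) +
      (1 | participant_id:night_id) + (1 | participant_id:hemisphere),
    "beta-delta-hemisphere" = cort_delta ~ subcort_beta + (1 | hemisphere),
    "quadrant" = cort_delta ~ subcort_beta * quadrant + (1 | night_id))
}
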