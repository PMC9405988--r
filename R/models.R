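# Relating temporal variability of connectivity to the self-assessment
# scales with mixed-effects regression: scale ~ tv + (1 | subject).

#' Mixed-effects regression of a rating scale on temporal variability
#'
#' Fits `scale ~ tv + (1 | subject)` by restricted maximum likelihood
#' (REML). Both the predictor and the outcome are z-scored before
#' fitting, so the reported slope is standardized (a slope of 0.5 means
#' half a standard deviation of the rating per standard deviation of
#' tvDFC). Slope inference is by Wald test: `t = beta / se`, two-sided p
#' from the normal reference, and `ci95 = beta +/- 1.96 * se`.
#'
#' @param records data.frame of per-event records with columns `tv`,
#'   `subject` and the requested scale.
#' @param scale Name of the outcome column (e.g. `"arousal"`).
#' @return list of class `lmm_fit`: `scale`, `beta`, `se`, `ci95`, `t`,
#'   `df` (residual-style, `n_obs - 2`; the Wald p uses the normal
#'   reference), `p`, `n_obs`, `n_subjects`, `converged`, `method`
#'   (`"REML"`), and the underlying `lme4` fit in `$fit`.
#' @export
fit_scale_on_tv <- function(records, scale) {
  if (!scale %in% names(records)) {
    stop("no column '", scale, "' in the records")
  }
  y <- records[[scale]]
  tv <- records$tv
  subj <- factor(records$subject)
  if (nlevels(subj) < 2) {
    stop("only one subject: a random-intercept model is not identified; ",
         "use ordinary regression instead")
  }
  if (stats::sd(y) == 0) stop("outcome '", scale, "' has zero variance")
  if (stats::sd(tv) == 0) stop("tv has zero variance")
  d <- data.frame(y = as.numeric(scale(y)), tv = as.numeric(scale(tv)),
                  subject = subj)
  fit <- lme4::lmer(y ~ tv + (1 | subject), data = d, REML = TRUE)
  msgs <- fit@optinfo$conv$lme4$messages
  # a boundary (singular) fit -- subject variance estimated at 0 -- is a
  # valid REML solution, not a convergence failure
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  converged <- is.null(msgs) || !length(msgs)
  co <- summary(fit)$coefficients
  beta <- co["tv", "Estimate"]
  se <- co["tv", "Std. Error"]
  t <- beta / se
  structure(list(
    scale = scale, beta = beta, se = se,
    ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
    t = t, df = nrow(d) - 2,
    p = 2 * stats::pnorm(-abs(t)),
    n_obs = nrow(d), n_subjects = nlevels(subj),
    converged = converged, method = "REML", fit = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %s ~ tv + (1|subject): beta = %.3f (SE %.3f), 95%% CI [%.2f, %.2f], t = %.2f, p = %.2g%s\n",
    x$scale, x$beta, x$se, x$ci95[1], x$ci95[2], x$t, x$p,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Logistic mixed model: does arousal x dominance predict high tvDFC?
#'
#' Binarizes tv at the within-dataset median ("high temporal
#' variability") and fits
#' `high_tv ~ arousal * dominance + (1 | subject)` with a logistic
#' link. Arousal and dominance are z-scored first. The quantity of
#' interest is the interaction coefficient.
#'
#' @param records data.frame with `tv`, `arousal`, `dominance`,
#'   `subject`.
#' @return list: `beta_interaction`, `se`, `z`, `p` (Wald), `converged`,
#'   `flagged` (TRUE on convergence/separation warnings), `n_obs`, and
#'   the `glmer` fit in `$fit`.
#' @export
fit_interaction_logistic <- function(records) {
  med <- stats::median(records$tv)
  high <- as.integer(records$tv > med)
  if (length(unique(high)) < 2) {
    stop("tv median split is degenerate (all observations on one side)")
  }
  d <- data.frame(high = high,
                  ar = as.numeric(scale(records$arousal)),
                  do = as.numeric(scale(records$dominance)),
                  subject = factor(records$subject))
  flagged <- FALSE
  fit <- withCallingHandlers(
    lme4::glmer(high ~ ar * do + (1 | subject), data = d,
                family = stats::binomial()),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  beta <- co["ar:do", "Estimate"]
  se <- co["ar:do", "Std. Error"]
  # huge |beta| with huge SE indicates (quasi-)separation
  if (abs(beta) > 10 && se > 10) flagged <- TRUE
  list(beta_interaction = beta, se = se, z = beta / se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       converged = !flagged, flagged = flagged,
       n_obs = nrow(d), fit = fit)
}
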