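#' Linear mixed model of heart rate on temperature
#'
#' Fits, by REML, the repeated-measures model of segment heart rate on
#' acute temperature:
#' \deqn{HR_{its} = \beta_0 + \beta_g g_i + \beta_T (T_{s} - 22) +
#'   \beta_{gT} g_i (T_s - 22) + \beta_{ph} \, phase_s + u_i +
#'   \varepsilon_{its}}
#' with a random intercept per spat (`u_i`) and first-order autocorrelated
#' residuals within spat across the ordered protocol segments. Temperature
#' is centred at 22 deg C so each group's intercept is its heart rate at
#' the ramp start; phase is coded cooling = 0, warming = 1; the
#' group-by-temperature interaction carries the difference in cooling
#' slopes between acclimation groups.
#'
#' Under `convention = "active_only"` asystolic segments are missing;
#' under `"zeroed"` they enter as ordinary observations of 0 beats/min.
#'
#' @param cohort a `cohort_dataset` from [make_cohort()], or a segment
#'   table with columns `spat_id`, `group`, `step`, `set_point_c`,
#'   `phase`, `hr_active`, `hr_zeroed`.
#' @param convention `"zeroed"` (default) or `"active_only"`.
#' @return an object of class `hr_model_fit` with the per-group 22 deg C
#'   intercepts and cooling declines (beats/min per deg C of cooling,
#'   positive = HR falls when cooled), their Wald 95% CIs and p-values,
#'   the slope difference, phase effect, random-intercept SD, AR(1)
#'   coefficient, and the underlying [nlme::lme] fit.
#' @seealso [coef.hr_model_fit()], [predict.hr_model_fit()]
#' @export
fit_hr_model <- function(cohort, convention = c("zeroed", "active_only")) {
  convention <- match.arg(convention)
  seg <- if (inherits(cohort, "cohort_dataset")) cohort$segments else cohort
  need <- c("spat_id", "group", "step", "set_point_c", "phase")
  if (!all(need %in% names(seg)))
    stop_param("segment table must have columns ",
               paste(need, collapse = ", "))
  d <- data.frame(spat_id = seg$spat_id,
                  group = factor(seg$group),
                  step = seg$step,
                  tc = seg$set_point_c - 22,
                  phase = factor(seg$phase, levels = c("cooling", "warming")),
                  hr = if (convention == "zeroed") seg$hr_zeroed else seg$hr_active)
  d <- d[!is.na(d$hr), , drop = FALSE]
  if (nlevels(d$group) != 2L) stop_param("exactly two groups are required")
  n_per <- tapply(d$spat_id, d$group, function(x) length(unique(x)))
  if (any(n_per < 2)) stop_param("at least 2 spat per group are required")
  if (length(unique(d$tc)) < 3L)
    stop_param("at least 3 temperature levels with non-missing HR are required")

  fit_with <- function(corr) {
    nlme::lme(hr ~ group * tc + phase, random = ~ 1 | spat_id,
              correlation = corr, data = d, method = "REML",
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         opt = "optim", returnObject = FALSE))
  }
  converged <- TRUE
  fit <- tryCatch(fit_with(nlme::corAR1(form = ~ step | spat_id)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    warning("AR(1) mixed model did not converge (", conditionMessage(fit),
            "); falling back to independent residuals", call. = FALSE)
    converged <- FALSE
    fit <- fit_with(NULL)
  }

  fe <- nlme::fixef(fit)
  V <- stats::vcov(fit)
  lv <- levels(d$group)
  ref <- lv[1L]; other <- lv[2L]
  nm <- names(fe)
  pick <- function(what) {
    i <- match(what, nm)
    if (is.na(i)) stop_param("unexpected coefficient layout")
    i
  }
  i0 <- pick("(Intercept)")
  ig <- pick(paste0("group", other))
  it <- pick("tc")
  igt <- pick(paste0("group", other, ":tc"))
  combo <- function(w) {
    est <- sum(w * fe)
    se <- sqrt(drop(t(w) %*% V %*% w))
    z <- est / se
    c(estimate = est, se = se,
      lower = est - 1.96 * se, upper = est + 1.96 * se,
      p = 2 * stats::pnorm(-abs(z)))
  }
  unit <- function(i, extra = NULL) {
    w <- numeric(length(fe)); w[i] <- 1
    if (!is.null(extra)) w[extra] <- 1
    w
  }
  # the coefficient on (T - 22) is positive when HR falls during cooling,
  # so it is directly the decline in beats/min per deg C of cooling
  rows <- rbind(
    intercept_ref = combo(unit(i0)),
    intercept_other = combo(unit(i0, ig)),
    decline_ref = combo(unit(it)),
    decline_other = combo(unit(it, igt)),
    decline_difference = combo(unit(igt)),
    intercept_difference = combo(unit(ig)))
  tab <- data.frame(
    term = c(sprintf("HR at 22C, %s", ref), sprintf("HR at 22C, %s", other),
             sprintf("cooling decline, %s", ref),
             sprintf("cooling decline, %s", other),
             "decline difference", "intercept difference"),
    rows, row.names = NULL)

  iph <- match("phasewarming", nm)
  phase_eff <- if (!is.na(iph)) combo(unit(iph)) else NULL
  vc <- nlme::VarCorr(fit)
  sigma_u <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  phi <- NA_real_
  cs <- fit$modelStruct$corStruct
  if (!is.null(cs)) phi <- unname(stats::coef(cs, unconstrained = FALSE))[1L]

  structure(list(
    table = tab,
    groups = stats::setNames(
      list(list(intercept = rows["intercept_ref", ], decline = rows["decline_ref", ]),
           list(intercept = rows["intercept_other", ], decline = rows["decline_other", ])),
      c(ref, other)),
    phase_effect = phase_eff,
    random_intercept_sd = sigma_u,
    ar1_phi = phi,
    sigma = fit$sigma,
    convention = convention,
    converged = converged,
    n_obs = nrow(d),
    n_spat = length(unique(d$spat_id)),
    model = fit),
    class = "hr_model_fit")
}

#' @export
print.hr_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Heart rate vs temperature mixed model (%s convention, REML%s)\n",
              x$convention,
              if (x$converged) ", AR(1) residuals" else ", independent residuals [AR(1) fit failed]"))
  cat(sprintf("  %d observations, %d spat\n", x$n_obs, x$n_spat))
  tab <- x$table
  tab[, -1L] <- round(tab[, -1L], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("  random intercept SD %.2f, AR(1) phi %.3f, residual SD %.2f\n",
              x$random_intercept_sd, x$ar1_phi, x$sigma))
  invisible(x)
}

#' @export
summary.hr_model_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying lme fit:\n")
  print(summary(object$model))
  invisible(object)
}

#' Fixed effects of a heart-rate model fit
#' @param object an `hr_model_fit`.
#' @param ... unused.
#' @return named numeric vector of the underlying fixed effects.
#' @export
coef.hr_model_fit <- function(object, ...) nlme::fixef(object$model)

#' @export
confint.hr_model_fit <- function(object, parm, level = 0.95, ...) {
  fe <- nlme::fixef(object$model)
  se <- sqrt(diag(stats::vcov(object$model)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(fe - z * se, fe + z * se)
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Population-level predictions from a heart-rate model fit
#' @param object an `hr_model_fit`.
#' @param newdata data frame with `group`, `set_point_c`, `phase`.
#' @param ... passed to [nlme::predict.lme].
#' @return predicted HR, beats/min.
#' @export
predict.hr_model_fit <- function(object, newdata, ...) {
  newdata$tc <- newdata$set_point_c - 22
  stats::predict(object$model, newdata = newdata, level = 0, ...)
}

#' @export
residuals.hr_model_fit <- function(object, ...) stats::residuals(object$model, ...)
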