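# Near-turbine binomial GLMM: facing probability vs. bird traits, wind
# component toward the turbine, uplift and turbine height, with a per-bird
# random intercept. Two configurations mirror the collinearity split between
# turbine height and thermal uplift.

.glmm_predictors <- function(config) {
  base <- c("age", "sex", "wind_component", "orographic_uplift")
  switch(config,
         with_thermal = c(base, "thermal_uplift"),
         with_turbine_height = c(base, "turbine_max_height"),
         stop("unknown GLMM configuration '", config, "'", call. = FALSE))
}

#' Fit the near-turbine facing-probability GLMM
#'
#' Logit-link mixed model fitted with [lme4::glmer()] (maximum likelihood,
#' Laplace approximation): per-bird random intercept and fixed effects age,
#' sex, wind component toward the nearest turbine (m/s, raw scale),
#' orographic uplift, and either thermal uplift (`config = "with_thermal"`)
#' or turbine maximum height (`config = "with_turbine_height"`). The two
#' configurations exist because turbine height and thermal uplift are too
#' collinear to enter one model; any numeric predictor pair with `|r|`
#' above the threshold inside the requested configuration is refused.
#'
#' @param data Annotated data frame (normally [subset_glmm()] output).
#' @param config `"with_thermal"` or `"with_turbine_height"`.
#' @param collinearity_threshold Absolute Pearson correlation above which a
#'   predictor pair is refused; default 0.7.
#' @return Object of class `facing_glmm`: coefficient table (`estimate`,
#'   `se`, `z`, `lower`, `upper`, `p_value` per term; Wald CI = estimate
#'   +/- 1.96 SE), bird random-intercept variance, Nakagawa marginal and
#'   conditional R-squared, and the underlying `glmerMod`.
#' @export
fit_facing_glmm <- function(data, config = c("with_thermal",
                                             "with_turbine_height"),
                            collinearity_threshold = 0.7) {
  config <- match.arg(config)
  preds <- .glmm_predictors(config)
  .require_columns(data, c("facing", "bird_id", preds), "GLMM input")
  keep <- stats::complete.cases(data[c("facing", "bird_id", preds)])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) stop("no complete cases for the GLMM", call. = FALSE)
  data$bird_id <- factor(data$bird_id)
  for (v in c("age", "sex")) {
    if (!is.numeric(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  usable <- vapply(preds, function(v) {
    x <- data[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else stats::sd(x) > 0
  }, logical(1))
  if (!all(usable)) {
    stop("rank-deficient design: constant predictor(s) ",
         paste(preds[!usable], collapse = ", "), call. = FALSE)
  }
  num_preds <- preds[vapply(data[preds], is.numeric, logical(1))]
  if (length(num_preds) >= 2) {
    ct <- predictor_correlation(data, vars = num_preds,
                                threshold = collinearity_threshold)
    flagged <- !is.na(ct$r) & ct$flagged
    if (any(flagged)) {
      bad <- ct[flagged, , drop = FALSE][1, ]
      stop("collinear predictors within one configuration: ", bad$var1,
           " and ", bad$var2, " (r = ", round(bad$r, 2),
           "); use the alternative configuration", call. = FALSE)
    }
  }
  form <- stats::as.formula(paste("facing ~", paste(preds, collapse = " + "),
                                  "+ (1 | bird_id)"))
  fit <- lme4::glmer(form, data = data, family = stats::binomial())
  co <- summary(fit)$coefficients
  coefficients <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    z = co[, "z value"],
    lower = co[, "Estimate"] - 1.96 * co[, "Std. Error"],
    upper = co[, "Estimate"] + 1.96 * co[, "Std. Error"],
    p_value = co[, "Pr(>|z|)"],
    row.names = NULL
  )
  re_var <- as.numeric(lme4::VarCorr(fit)$bird_id[1, 1])
  out <- structure(list(
    model = fit,
    config = config,
    coefficients = coefficients,
    re_var = re_var,
    n = nrow(data),
    n_birds = nlevels(data$bird_id)
  ), class = "facing_glmm")
  r2 <- nakagawa_r2(out)
  out$r2_marginal <- r2[["r2_marginal"]]
  out$r2_conditional <- r2[["r2_conditional"]]
  out
}

#' @export
print.facing_glmm <- function(x, ...) {
  cat("Binomial facing-probability GLMM (", x$config, "; ", x$n, " fixes, ",
      x$n_birds, " birds)\n", sep = "")
  print(x$coefficients, digits = 3)
  cat("Bird random-intercept variance:", format(x$re_var, digits = 3), "\n")
  cat("Nakagawa R2 marginal/conditional:",
      format(x$r2_marginal, digits = 2), "/",
      format(x$r2_conditional, digits = 2), "\n")
  invisible(x)
}

#' Nakagawa-Schielzeth R-squared for a logit mixed model
#'
#' Theoretical method:
#' `R2_marginal = s2_f / (s2_f + s2_b + pi^2/3)` and
#' `R2_conditional = (s2_f + s2_b) / (s2_f + s2_b + pi^2/3)`, where `s2_f`
#' is the variance of the fixed-effect linear predictor over the modelling
#' data, `s2_b` the random-intercept variance, and `pi^2/3` the variance of
#' the standard logistic distribution.
#'
#' @param object A `facing_glmm`, a fitted [lme4::glmer()] model, or the
#'   fixed-effect linear-predictor variance `s2_f` itself (numeric scalar,
#'   in which case `sigma2_random` must be supplied).
#' @param sigma2_random Random-intercept variance; only used for the numeric
#'   form of `object`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(object, sigma2_random = NULL) {
  if (is.numeric(object)) {
    stopifnot(length(object) == 1, !is.null(sigma2_random))
    s2f <- object
    s2b <- sigma2_random
  } else {
    fit <- if (inherits(object, "facing_glmm")) object$model else object
    if (!inherits(fit, "glmerMod")) {
      stop("'object' must be a facing_glmm, a glmerMod, or a variance",
           call. = FALSE)
    }
    X <- lme4::getME(fit, "X")
    eta_fixed <- as.numeric(X %*% lme4::fixef(fit))
    s2f <- stats::var(eta_fixed)
    vc <- lme4::VarCorr(fit)
    s2b <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  }
  denom <- s2f + s2b + pi^2 / 3
  c(r2_marginal = s2f / denom,
    r2_conditional = (s2f + s2b) / denom)
}
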