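#' Tidy an incentive fit
#'
#' Returns the fixed-effect (incentive) coefficients of both mixed-effects
#' threshold models in broom's long format.
#'
#' @param x A `cei_incentive_fit` from [fit_incentive()].
#' @param ... Unused.
#' @return A tibble: `threshold` (`"upper"`/`"lower"`), `term`, `estimate`,
#'   `std.error`, `statistic`.
#' @export
tidy.cei_incentive_fit <- function(x, ...) {
  one <- function(fit, label) {
    cs <- stats::coef(summary(fit))
    tibble::tibble(threshold = label, term = rownames(cs),
                   estimate = cs[, "Estimate"],
                   std.error = cs[, "Std. Error"],
                   statistic = cs[, "t value"])
  }
  dplyr::bind_rows(one(x$fit_u, "upper"), one(x$fit_l, "lower"))
}

#' Glance at an incentive fit
#'
#' @param x A `cei_incentive_fit`.
#' @param ... Unused.
#' @return A one-row-per-model tibble: `threshold`, `nobs`,
#'   `n_participants`, `sigma` (residual sd), `sd_intercept` (random
#'   intercept sd), `REMLcrit`, `singular`.
#' @export
glance.cei_incentive_fit <- function(x, ...) {
  one <- function(fit, label, singular) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    tibble::tibble(
      threshold = label,
      nobs = stats::nobs(fit),
      n_participants = nrow(x$thetas),
      sigma = stats::sigma(fit),
      sd_intercept = vc$sdcor[vc$grp == "participant"][1],
      REMLcrit = lme4::REMLcrit(fit),
      singular = singular
    )
  }
  dplyr::bind_rows(one(x$fit_u, "upper", x$singular[["upper"]]),
                   one(x$fit_l, "lower", x$singular[["lower"]]))
}
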