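#' Estimate peptide-specific back-exchange from a maxD reference
#'
#' Back-exchange is the loss of label between quench and detection. It is
#' estimated from a maximally deuterated (maxD) reference series as a single
#' retention fraction: mean measured maxD uptake divided by the theoretical
#' maximum (`d2o_fraction * Q`). A linear regression of per-exposure retention
#' on mixing time (seconds) is reported alongside as a diagnostic for
#' time-invariance; with turbulent-flow mixing the slope is expected to be
#' indistinguishable from zero.
#'
#' @param maxd A data frame of the maxD reference series with columns
#'   `exposure` (s) and `uptake` (Da); replicates as extra rows.
#' @param theoretical_max Theoretical maximum uptake in Da
#'   (see [theoretical_max_uptake()]); must be positive.
#' @param clip Clip retention values above 1 down to 1 (default keeps them
#'   with a warning).
#' @return An object of class `bex_model` with elements `retention`,
#'   `theoretical_max`, `slope` (fraction per second), `slope_se`, `p_value`,
#'   `r_squared`, and `per_exposure` (tibble of exposure, mean uptake,
#'   retention).
#' @export
estimate_backexchange <- function(maxd, theoretical_max, clip = FALSE) {
  stopifnot(is.data.frame(maxd))
  if (!all(c("exposure", "uptake") %in% names(maxd))) {
    abort("`maxd` needs columns `exposure` and `uptake`.")
  }
  maxd <- dplyr::filter(maxd, !is.na(.data$uptake))
  if (nrow(maxd) == 0L) abort("Empty maxD reference series.")
  if (!is.numeric(theoretical_max) || theoretical_max <= 0) {
    abort("`theoretical_max` must be positive (is the peptide devoid of exchangeable amides?).")
  }
  if (any(maxd$uptake < 0)) abort("maxD uptake must be non-negative.")

  retention <- mean(maxd$uptake) / theoretical_max
  if (retention > 1) {
    if (clip) {
      warn(sprintf("Retention %.3f > 1 clipped to 1.", retention))
      retention <- 1
    } else {
      warn(sprintf("Retention %.3f exceeds 1; kept unclipped.", retention))
    }
  }
  if (retention <= 0) abort("Estimated retention is zero; cannot correct uptake.")

  per_exposure <- maxd |>
    dplyr::group_by(exposure = .data$exposure) |>
    dplyr::summarise(
      mean_uptake = mean(.data$uptake),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(retention = .data$mean_uptake / theoretical_max) |>
    dplyr::arrange(.data$exposure)

  slope <- 0; slope_se <- NA_real_; p_value <- NA_real_; r2 <- 0
  if (nrow(per_exposure) >= 3L && stats::var(per_exposure$retention) > 0) {
    fit <- lm(retention ~ exposure, data = per_exposure)
    cf <- summary(fit)$coefficients
    slope <- cf["exposure", "Estimate"]
    slope_se <- cf["exposure", "Std. Error"]
    p_value <- cf["exposure", "Pr(>|t|)"]
    r2 <- summary(fit)$r.squared
  }

  structure(
    list(
      retention = retention,
      theoretical_max = theoretical_max,
      slope = slope,
      slope_se = slope_se,
      p_value = p_value,
      r_squared = r2,
      per_exposure = per_exposure
    ),
    class = "bex_model"
  )
}

#' @export
print.bex_model <- function(x, ...) {
  cat(sprintf(
    "<bex_model> retention %.3f (max %.3f Da); slope %.3g /s, R^2 %.3f\n",
    x$retention, x$theoretical_max, x$slope, x$r_squared
  ))
  invisible(x)
}

#' @export
tidy.bex_model <- function(x, ...) {
  x$per_exposure
}

#' @export
glance.bex_model <- function(x, ...) {
  tibble::tibble(
    retention = x$retention,
    theoretical_max = x$theoretical_max,
    slope = x$slope,
    slope_se = x$slope_se,
    p_value = x$p_value,
    r_squared = x$r_squared
  )
}

#' Correct observed uptake for back-exchange
#'
#' Divides observed uptake by the estimated retention fraction to obtain
#' absolute uptake in Da. Corrected values exceeding the theoretical maximum
#' by more than 5% are flagged (kept, not clipped, to preserve the noise
#' structure for fitting).
#'
#' @param observed Data frame with columns `exposure` and `uptake` (Da).
#' @param model A `bex_model` from [estimate_backexchange()].
#' @return The input tibble with `uptake` replaced by the corrected value and
#'   a logical `above_max` flag column.
#' @export
correct_uptake <- function(observed, model) {
  stopifnot(is.data.frame(observed), inherits(model, "bex_model"))
  if (!all(c("exposure", "uptake") %in% names(observed))) {
    abort("`observed` needs columns `exposure` and `uptake`.")
  }
  if (model$retention <= 0) abort("Retention must be positive.")
  out <- tibble::as_tibble(observed)
  out$uptake <- out$uptake / model$retention
  out$above_max <- out$uptake > model$theoretical_max * 1.05
  if (any(out$above_max, na.rm = TRUE)) {
    warn(sprintf(
      "%d corrected value(s) exceed the theoretical maximum by > 5%%.",
      sum(out$above_max, na.rm = TRUE)
    ))
  }
  out
}

#' Normalize absolute uptake to percent of the theoretical maximum
#'
#' `100 * uptake / theoretical_max`, where the theoretical maximum already
#' includes the D2O-fraction factor.
#'
#' @param absolute Data frame with columns `exposure` and `uptake` (absolute
#'   Da, back-exchange corrected).
#' @param theoretical_max Theoretical maximum uptake in Da; must be positive.
#' @return The input tibble with `uptake` in percent and a `units` column set
#'   to `"percent"`.
#' @export
normalize_percent <- function(absolute, theoretical_max) {
  stopifnot(is.data.frame(absolute))
  if (!is.numeric(theoretical_max) || theoretical_max <= 0) {
    abort("`theoretical_max` must be positive.")
  }
  out <- tibble::as_tibble(absolute)
  out$uptake <- 100 * out$uptake / theoretical_max
  out$units <- "percent"
  out
}
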