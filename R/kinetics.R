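#' Fit a multi-phase stretched-exponential uptake model
#'
#' Fits D(t) = sum_j Q_j * (1 - exp(-(k_j t)^beta_j)) for j = 1..n_phases to
#' a deuterium-uptake series by nonlinear least squares (Levenberg-Marquardt
#' with box constraints), with a deterministic grid of log-spaced rate
#' multi-starts. The stretching exponent beta_j in (0, 1] absorbs rate
#' heterogeneity among the amides pooled in a phase; beta = 1 recovers a
#' simple exponential. Replicates are collapsed to per-exposure means;
#' weights are inverse squared standard errors when every exposure has at
#' least 3 replicates, otherwise the fit is unweighted.
#'
#' @param data Data frame with columns `exposure` (s) and `uptake` (Da);
#'   replicates as extra rows.
#' @param n_phases Number of phases, 1-3.
#' @param q_max Optional cap used to initialize and bound the amplitudes
#'   (e.g. the theoretical maximum uptake). Defaults to twice the largest
#'   observed mean uptake.
#' @param n_starts Approximate size of the multi-start grid (default 16).
#' @return An object of class `hdx_fit`: phase parameter tibble (`phases`,
#'   ordered by decreasing rate), `rss`, `r_squared`, `sigma`,
#'   `df_residual`, `n_obs`, `converged`, `status`
#'   (`"fitted"`/`"uninformative"`/`"failed"`), `weighted`, and the
#'   per-exposure `data` used.
#' @export
fit_stretched_exponential <- function(data, n_phases = 1L, q_max = NULL,
                                      n_starts = 16L) {
  n_phases <- as.integer(n_phases)
  if (n_phases < 1L || n_phases > 3L) abort("`n_phases` must be 1, 2 or 3.")
  stopifnot(is.data.frame(data))
  if (!all(c("exposure", "uptake") %in% names(data))) {
    abort("`data` needs columns `exposure` and `uptake`.")
  }
  data <- dplyr::filter(data, !is.na(.data$uptake), .data$exposure > 0)
  n_obs_total <- nrow(data)
  n_par <- 3L * n_phases
  if (n_obs_total < 2L * n_par) {
    abort(sprintf(
      "Need at least %d observations for %d phase(s); got %d.",
      2L * n_par, n_phases, n_obs_total
    ))
  }

  byexp <- data |>
    dplyr::group_by(exposure = .data$exposure) |>
    dplyr::summarise(
      sd = stats::sd(.data$uptake),
      n = dplyr::n(),
      uptake = mean(.data$uptake),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$exposure)
  if (nrow(byexp) <= n_par) {
    abort(sprintf(
      "Need more than %d distinct exposures for %d phase(s); got %d.",
      n_par, n_phases, nrow(byexp)
    ))
  }

  weighted <- all(byexp$n >= 3L) && !anyNA(byexp$sd) && all(byexp$sd > 0)
  w <- if (weighted) byexp$n / byexp$sd^2 else rep(1, nrow(byexp))

  tt <- byexp$exposure
  yy <- byexp$uptake
  amp <- max(yy)
  if (amp < 0.02) {
    # flat series: no measurable exchange, report a degenerate single phase
    phases <- tibble::tibble(
      phase = seq_len(n_phases), q = 0, k = NA_real_, beta = NA_real_,
      q_se = NA_real_, k_se = NA_real_, beta_se = NA_real_
    )
    return(new_hdx_fit(
      phases, n_phases, rss = sum(w * yy^2), tss = sum(w * (yy - mean(yy))^2),
      df = nrow(byexp) - n_par, n_obs = n_obs_total, converged = TRUE,
      status = "uninformative", weighted = weighted, byexp = byexp
    ))
  }
  q_cap <- (q_max %||% (2 * amp)) * 1.05

  model_fun <- function(p, t) {
    q <- p[seq_len(n_phases)]
    k <- p[n_phases + seq_len(n_phases)]
    b <- p[2L * n_phases + seq_len(n_phases)]
    rowSums(vapply(
      seq_len(n_phases),
      function(j) q[j] * (1 - exp(-(k[j] * t)^b[j])),
      numeric(length(t))
    ))
  }
  resid_fun <- function(p) sqrt(w) * (yy - model_fun(p, tt))

  lower <- c(rep(1e-8, n_phases), rep(1e-8, n_phases), rep(0.05, n_phases))
  upper <- c(rep(q_cap, n_phases), rep(1e6, n_phases), rep(1, n_phases))

  starts <- rate_start_grid(n_phases, range(tt), n_starts)
  best <- NULL
  for (ks in starts) {
    p0 <- c(rep(amp / n_phases, n_phases), ks, rep(0.9, n_phases))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    phases <- tibble::tibble(
      phase = seq_len(n_phases), q = NA_real_, k = NA_real_, beta = NA_real_,
      q_se = NA_real_, k_se = NA_real_, beta_se = NA_real_
    )
    return(new_hdx_fit(
      phases, n_phases, rss = NA_real_, tss = NA_real_,
      df = nrow(byexp) - n_par, n_obs = n_obs_total, converged = FALSE,
      status = "failed", weighted = weighted, byexp = byexp
    ))
  }

  p <- best$fit$par
  se <- tryCatch(
    sqrt(diag(solve(best$fit$hessian)) * best$rss /
      max(nrow(byexp) - n_par, 1L)),
    error = function(e) rep(NA_real_, length(p))
  )
  q <- p[seq_len(n_phases)]
  k <- p[n_phases + seq_len(n_phases)]
  b <- p[2L * n_phases + seq_len(n_phases)]
  ord <- order(k, decreasing = TRUE)
  idx <- function(block) block[ord]
  phases <- tibble::tibble(
    phase = seq_len(n_phases),
    q = q[ord], k = k[ord], beta = b[ord],
    q_se = idx(se[seq_len(n_phases)]),
    k_se = idx(se[n_phases + seq_len(n_phases)]),
    beta_se = idx(se[2L * n_phases + seq_len(n_phases)])
  )
  if (!is.null(q_max) && sum(phases$q) > q_max * 1.05) {
    warn("Sum of fitted amplitudes exceeds the theoretical cap by > 5%.")
  }
  new_hdx_fit(
    phases, n_phases, rss = best$rss,
    tss = sum(w * (yy - mean(yy))^2),
    df = nrow(byexp) - n_par, n_obs = n_obs_total,
    converged = best$fit$info %in% 1:4,
    status = "fitted", weighted = weighted, byexp = byexp
  )
}

# deterministic multi-start grid: log-spaced rates spanning the sampled time
# window, ordered combinations for multi-phase fits
rate_start_grid <- function(n_phases, t_range, n_starts = 16L) {
  lo <- log10(0.1 / t_range[2])
  hi <- log10(10 / t_range[1])
  if (n_phases == 1L) {
    g <- 10^seq(lo, hi, length.out = n_starts)
    return(lapply(g, function(x) x))
  }
  gsize <- if (n_phases == 2L) 6L else 5L
  g <- 10^seq(lo, hi, length.out = gsize)
  combs <- utils::combn(sort(g, decreasing = TRUE), n_phases, simplify = FALSE)
  combs
}

new_hdx_fit <- function(phases, n_phases, rss, tss, df, n_obs, converged,
                        status, weighted, byexp) {
  r2 <- if (is.na(rss) || is.na(tss) || tss <= 0) NA_real_ else 1 - rss / tss
  structure(
    list(
      phases = phases, n_phases = n_phases, rss = rss,
      r_squared = r2,
      sigma = if (is.na(rss) || df <= 0) NA_real_ else sqrt(rss / df),
      df_residual = df, n_obs = n_obs, converged = converged,
      status = status, weighted = weighted, data = byexp
    ),
    class = "hdx_fit"
  )
}

#' @export
print.hdx_fit <- function(x, ...) {
  cat(sprintf(
    "<hdx_fit> %d phase(s), status %s, R^2 %s\n",
    x$n_phases, x$status,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))
  ))
  print(x$phases)
  invisible(x)
}

#' @export
tidy.hdx_fit <- function(x, ...) {
  x$phases |>
    tidyr::pivot_longer(
      c("q", "k", "beta"),
      names_to = "term", values_to = "estimate"
    ) |>
    dplyr::mutate(
      std.error = dplyr::case_when(
        .data$term == "q" ~ .data$q_se,
        .data$term == "k" ~ .data$k_se,
        TRUE ~ .data$beta_se
      )
    ) |>
    dplyr::select("phase", "term", "estimate", "std.error")
}

#' @export
glance.hdx_fit <- function(x, ...) {
  tibble::tibble(
    n_phases = x$n_phases, rss = x$rss, r.squared = x$r_squared,
    sigma = x$sigma, df.residual = x$df_residual, nobs = x$n_obs,
    converged = x$converged, status = x$status
  )
}

#' Evaluate a fitted stretched-exponential model
#'
#' @param object An `hdx_fit`.
#' @param times Times (s) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric uptake values (Da).
#' @export
predict.hdx_fit <- function(object, times = object$data$exposure, ...) {
  ph <- object$phases
  if (object$status == "uninformative" || any(is.na(ph$k))) {
    return(rep(0, length(times)))
  }
  rowSums(vapply(
    seq_len(nrow(ph)),
    function(j) ph$q[j] * (1 - exp(-(ph$k[j] * times)^ph$beta[j])),
    numeric(length(times))
  ))
}

#' Select the minimal adequate number of phases
#'
#' Fits 1, 2 and 3 phases and returns the smallest model that a richer model
#' does not significantly improve on, by the extra-sum-of-squares F-test at
#' level `alpha` (or by AIC when `criterion = "aic"`). Models that the data
#' cannot support (too few observations) are not attempted.
#'
#' @inheritParams fit_stretched_exponential
#' @param max_phases Largest phase count to consider (1-3).
#' @param alpha Significance level of the extra-sum-of-squares F-test.
#' @param criterion `"ftest"` (default) or `"aic"`.
#' @return The selected `hdx_fit` (with attribute `candidates`, the glances
#'   of all fitted models).
#' @export
select_model <- function(data, max_phases = 3L, alpha = 0.05,
                         criterion = c("ftest", "aic"), q_max = NULL,
                         n_starts = 16L) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(data))
  dat <- dplyr::filter(data, !is.na(.data$uptake), .data$exposure > 0)
  n_exposures <- length(unique(dat$exposure))
  feasible <- which(vapply(
    1:3,
    function(n) nrow(dat) >= 2L * 3L * n && n_exposures > 3L * n,
    logical(1)
  ))
  max_n <- min(as.integer(max_phases), max(feasible))
  fits <- lapply(seq_len(max_n), function(n) {
    fit_stretched_exponential(dat, n_phases = n, q_max = q_max, n_starts = n_starts)
  })
  sel <- fits[[1]]
  if (sel$status != "uninformative") {
    for (n in seq_len(max_n - 1L)) {
      f_simple <- fits[[n]]
      f_rich <- fits[[n + 1L]]
      if (f_rich$status != "fitted") break
      p <- phase_f_test(f_simple, f_rich)
      if (is.na(p) || p >= alpha_or_aic(criterion, alpha, f_simple, f_rich)) break
      sel <- f_rich
    }
  }
  attr(sel, "candidates") <- dplyr::bind_rows(lapply(fits, glance))
  sel
}

alpha_or_aic <- function(criterion, alpha, f_simple, f_rich) {
  if (criterion == "ftest") return(alpha)
  # AIC route: accept the richer model iff its AIC is lower; encode as a
  # threshold the p-value is compared against (0 or 1)
  n <- nrow(f_simple$data)
  aic <- function(f) n * log(f$rss / n) + 2 * (3 * f$n_phases)
  if (aic(f_rich) < aic(f_simple)) 1 else 0
}

# extra-sum-of-squares F-test p-value for nested stretched-exponential fits
phase_f_test <- function(f_simple, f_rich) {
  if (is.na(f_simple$rss) || is.na(f_rich$rss)) return(NA_real_)
  df1 <- 3L * (f_rich$n_phases - f_simple$n_phases)
  df2 <- f_rich$df_residual
  if (df2 <= 0) return(NA_real_)
  num <- (f_simple$rss - f_rich$rss) / df1
  den <- f_rich$rss / df2
  if (den <= 0) return(0)
  if (num <= 0) return(1)
  pf(num / den, df1, df2, lower.tail = FALSE)
}

#' Segment-averaged protection factors
#'
#' The protection factor of a phase is the ratio of the intrinsic
#' (unprotected) rate to the measured rate: ln(Pf) = ln(k_int) - ln(k_exp).
#' Both fits should carry the same phase count; otherwise phases are matched
#' by amplitude rank over the common count, with a warning.
#'
#' @param exp_fit `hdx_fit` of the back-exchange-corrected experimental curve.
#' @param intrinsic_fit `hdx_fit` of the theoretical intrinsic curve.
#' @return A tibble with one row per matched phase: `phase`, `k_exp`,
#'   `k_int`, `ln_pf`, and the experimental amplitude `q_exp` (useful as a
#'   weight when averaging across phases).
#' @export
protection_factors <- function(exp_fit, intrinsic_fit) {
  stopifnot(inherits(exp_fit, "hdx_fit"), inherits(intrinsic_fit, "hdx_fit"))
  pe <- exp_fit$phases
  pi_ <- intrinsic_fit$phases
  if (any(is.na(pe$k)) || any(is.na(pi_$k))) {
    abort("Both fits must carry finite positive rates.")
  }
  if (any(pe$k <= 0) || any(pi_$k <= 0)) abort("Rates must be positive.")
  if (nrow(pe) != nrow(pi_)) {
    warn("Phase counts differ; matching by amplitude rank over the common count.")
    m <- min(nrow(pe), nrow(pi_))
    pe <- pe[order(pe$q, decreasing = TRUE)[seq_len(m)], ]
    pi_ <- pi_[order(pi_$q, decreasing = TRUE)[seq_len(m)], ]
    pe <- pe[order(pe$k, decreasing = TRUE), ]
    pi_ <- pi_[order(pi_$k, decreasing = TRUE), ]
  }
  tibble::tibble(
    phase = seq_len(nrow(pe)),
    k_exp = pe$k,
    k_int = pi_$k,
    ln_pf = log(pi_$k) - log(pe$k),
    q_exp = pe$q
  )
}

#' Peptide-averaged ln protection factor
#'
#' The amplitude-weighted mean log rate of the intrinsic fit minus that of
#' the experimental fit. Unlike averaging per-phase ln(Pf) values, this
#' summary is insensitive to the two fits splitting amplitude differently
#' across phases, which happens freely when phases are not well separated.
#'
#' @inheritParams protection_factors
#' @return A single ln(Pf) value.
#' @export
mean_ln_pf <- function(exp_fit, intrinsic_fit) {
  stopifnot(inherits(exp_fit, "hdx_fit"), inherits(intrinsic_fit, "hdx_fit"))
  wmean_lnk <- function(fit) {
    ph <- fit$phases
    if (any(is.na(ph$k)) || any(ph$k <= 0)) abort("Fit carries no usable rates.")
    sum(ph$q * log(ph$k)) / sum(ph$q)
  }
  wmean_lnk(intrinsic_fit) - wmean_lnk(exp_fit)
}

#' First-order exponential-decay fit
#'
#' Fits A(t) = A0 * exp(-k t) + C by nonlinear least squares and reports the
#' rate constant with a linearized 95% confidence interval, as used for
#' chemical-clock (DNPA hydrolysis) timing validation. Decay traces from
#' absorbance detection carry error roughly proportional to the signal, and
#' the signal spans several decades over a millisecond time course, so the
#' default minimizes relative residuals (signal - fit)/fit; `weighting =
#' "none"` gives the plain unweighted least-squares fit.
#'
#' @param times Times in seconds (>= 4 points).
#' @param signal Signal values (absorbance, concentration, ...).
#' @param weighting `"relative"` (default) or `"none"`.
#' @return An object of class `decay_fit`: `k`, `k_se`, `conf_low`,
#'   `conf_high` (95%), `a0`, `c0`, `rss`, `df_residual`, `decaying`
#'   (FALSE flags non-decaying data), `converged`.
#' @export
fit_first_order_decay <- function(times, signal,
                                  weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  if (length(times) != length(signal)) abort("`times` and `signal` lengths differ.")
  ok <- !is.na(times) & !is.na(signal)
  times <- times[ok]; signal <- signal[ok]
  if (length(times) < 4L) abort("Need at least 4 points.")
  df <- length(times) - 3L

  c0 <- min(signal)
  a0 <- max(signal) - c0
  scale_floor <- 1e-6 * max(abs(signal))
  degenerate <- a0 <= 0 || stats::sd(signal) == 0
  if (!degenerate) {
    shifted <- signal - c0
    pos <- shifted > a0 * 1e-6
    k0 <- if (sum(pos) >= 2L) {
      max(-coef(lm(log(shifted[pos]) ~ times[pos]))[[2]], 1e-6)
    } else {
      1 / mean(times)
    }
    resid_fn <- function(p) {
      f <- p[1] * exp(-p[2] * times) + p[3]
      r <- signal - f
      if (weighting == "relative") r / pmax(abs(f), scale_floor) else r
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a0 = a0, k = k0, c0 = c0),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
  } else {
    fit <- NULL
  }

  if (is.null(fit)) {
    # constant / non-decaying degenerate input: rate 0 with an uninformative CI
    return(structure(
      list(
        k = 0, k_se = NA_real_, conf_low = -Inf, conf_high = Inf,
        a0 = 0, c0 = mean(signal), rss = sum((signal - mean(signal))^2),
        df_residual = df, decaying = FALSE, converged = FALSE
      ),
      class = "decay_fit"
    ))
  }
  p <- fit$par
  rss <- sum(fit$fvec^2)
  se <- tryCatch(
    sqrt(diag(solve(fit$hessian)) * rss / max(df, 1L)),
    error = function(e) rep(Inf, 3)
  )
  k_se <- se[2]
  tcrit <- qt(0.975, max(df, 1L))
  structure(
    list(
      k = unname(p[2]), k_se = unname(k_se),
      conf_low = unname(p[2] - tcrit * k_se),
      conf_high = unname(p[2] + tcrit * k_se),
      a0 = unname(p[1]), c0 = unname(p[3]),
      rss = rss, df_residual = df,
      decaying = unname(p[2]) > 0 && unname(p[1]) > 0,
      converged = fit$info %in% 1:4
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> k = %.3g /s (95%% CI %.3g to %.3g)%s\n",
    x$k, x$conf_low, x$conf_high,
    if (!x$decaying) " [non-decaying]" else ""
  ))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a0", "k", "c0"),
    estimate = c(x$a0, x$k, x$c0),
    std.error = c(NA_real_, x$k_se, NA_real_),
    conf.low = c(NA_real_, x$conf_low, NA_real_),
    conf.high = c(NA_real_, x$conf_high, NA_real_)
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, conf.low = x$conf_low, conf.high = x$conf_high,
    rss = x$rss, df.residual = x$df_residual,
    decaying = x$decaying, converged = x$converged
  )
}
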