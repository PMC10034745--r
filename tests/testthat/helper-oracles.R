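# Independent oracles used to cross-check the implementation.

# Spreadsheet-style intrinsic-rate computation: scalar base-R arithmetic
# straight off the shipped parameter CSVs, written independently of the
# package's vectorized path.
oracle_kint <- function(sequence, pd_read, temperature) {
  fac <- read.csv(
    system.file("extdata", "hx_sidechain_factors_v1.csv", package = "mshdx"),
    stringsAsFactors = FALSE
  )
  ref <- read.csv(
    system.file("extdata", "hx_reference_rates_v1.csv", package = "mshdx"),
    stringsAsFactors = FALSE
  )
  val <- function(p) ref$value[ref$parameter == p]
  pd <- pd_read + 0.4
  look <- function(res, col) {
    rows <- fac[fac$residue == res, , drop = FALSE]
    if (nrow(rows) == 1L) {
      v <- rows[[col]]
      return(if (is.na(v)) 0 else v)
    }
    fp <- rows[[col]][rows$form == "prot"]
    fd <- rows[[col]][rows$form == "deprot"]
    pk <- rows$pk[rows$form == "prot"]
    if (is.na(fp) || is.na(fd)) return(0)
    log10((10^(fp - pd) + 10^(fd - pk)) / (10^(-pd) + 10^(-pk)))
  }
  rgas <- 1.987e-3
  tref <- val("t_ref_k")
  ka <- 10^val("log10_ka") * exp(-val("ea_acid_kcal_mol") / rgas * (1 / temperature - 1 / tref))
  kb <- 10^val("log10_kb") * exp(-val("ea_base_kcal_mol") / rgas * (1 / temperature - 1 / tref))
  kw <- 10^val("log10_kw") * exp(-val("ea_water_kcal_mol") / rgas * (1 / temperature - 1 / tref))
  cd <- 10^(-pd)
  cod <- 10^(pd - val("pkd"))
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= 2 || aa[i] == "P") next
    la <- look(aa[i], "acid_lambda")
    lb <- look(aa[i], "base_lambda")
    ra <- look(aa[i - 1], "acid_rho")
    rb <- look(aa[i - 1], "base_rho")
    if (i == n) {
      la <- la + look("cterm", "acid_lambda")
      lb <- lb + look("cterm", "base_lambda")
    }
    out[i] <- (ka * 10^(la + ra) * cd + kb * 10^(lb + rb) * cod + kw * 10^(lb + rb)) / 60
  }
  out
}

# Brute-force uptake oracle: accumulate each included residue's own
# single-exponential curve, one residue at a time.
oracle_uptake <- function(k_included, times, d2o_fraction) {
  total <- rep(0, length(times))
  for (k in k_included) {
    total <- total + (1 - exp(-k * times))
  }
  d2o_fraction * total
}

# Closed-form ordinary least-squares slope and its standard error.
oracle_ols <- function(x, y) {
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  yhat <- ybar + slope * (x - xbar)
  se <- sqrt(sum((y - yhat)^2) / (length(x) - 2) / sxx)
  list(slope = slope, se = se)
}

# Shared small simulators for the fitting tests.
two_phase_uptake <- function(t) {
  2 * (1 - exp(-(10 * t)^0.8)) + 3 * (1 - exp(-0.05 * t))
}

simulate_series <- function(truth_fun, times, n_rep = 3, cv = 0.01, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_rep), function(r) {
    data.frame(
      exposure = times,
      uptake = truth_fun(times) * (1 + rnorm(length(times), 0, cv))
    )
  }))
}
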