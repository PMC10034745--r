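#' Pipeline configuration
#'
#' Collects everything one reproducible analysis run needs: the observed
#' uptake table (tibble or state CSV path), the maxD reference (a separate
#' table/path, or the name of a `state` within the observed table), labeling
#' conditions, fitting options, and the seed all randomness flows from.
#'
#' @param observed Tibble in the [read_state_csv()] schema, or a CSV path.
#' @param maxd Like `observed`, or `NULL` to take rows whose `state` equals
#'   `maxd_state` from the observed table.
#' @param maxd_state Name of the maxD reference state (default `"maxD"`).
#' @param conditions A [labeling_conditions()].
#' @param max_phases,alpha,n_starts Fitting options passed to
#'   [select_model()]; `alpha` must lie in (0, 1).
#' @param seed Integer seed.
#' @param output_dir Optional directory for the result bundle (JSON fits +
#'   corrected CSV); created if needed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(observed, maxd = NULL, maxd_state = "maxD",
                            conditions = labeling_conditions(),
                            max_phases = 3L, alpha = 0.05, n_starts = 16L,
                            seed = 1L, output_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(
    list(
      observed = observed, maxd = maxd, maxd_state = maxd_state,
      conditions = conditions, max_phases = as.integer(max_phases),
      alpha = alpha, n_starts = as.integer(n_starts),
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

resolve_table <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) return(read_state_csv(x))
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  abort("Expected a data frame or a CSV path.")
}

#' Run the full uptake-analysis pipeline
#'
#' For every peptide in the observed table: counts exchangeable amides,
#' estimates peptide-specific back-exchange from its maxD reference, corrects
#' the observed uptake to absolute Da, fits the minimal adequate
#' stretched-exponential model to the corrected curve, fits the theoretical
#' intrinsic curve (evaluated on a dense log-time grid) with the same phase
#' count, and reports per-phase and amplitude-weighted ln protection
#' factors. Peptides with no exchangeable amides, no maxD reference or a
#' failed fit are kept in the output with a diagnostic status. The run is
#' deterministic given the seed; a rerun with the same config writes
#' byte-identical JSON.
#'
#' @param config A [pipeline_config()].
#' @return A tibble with one row per peptide: identity columns, `q`
#'   (exchangeable amides), `retention`, `n_phases`, `r_squared`,
#'   `ln_pf_mean` (amplitude-weighted), `status`, and a `fits` list-column
#'   of per-phase tibbles (`phase`, `k_exp`, `k_int`, `ln_pf`, `q_exp`).
#'   When `output_dir` is set, also writes `fits.json`, `corrected.csv` and
#'   `run_log.json` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  observed <- resolve_table(config$observed)
  if (is.null(observed) || nrow(observed) == 0L) {
    abort("Empty observed uptake table: nothing to analyze.")
  }
  maxd <- resolve_table(config$maxd)
  if (is.null(maxd)) {
    maxd <- dplyr::filter(observed, .data$state == config$maxd_state)
    observed <- dplyr::filter(observed, .data$state != config$maxd_state)
  }
  if (nrow(observed) == 0L) abort("No labeled rows left after removing the maxD state.")
  set.seed(config$seed)
  cond <- config$conditions

  keys <- dplyr::distinct(observed, .data$protein, .data$sequence, .data$start, .data$end)
  corrected_all <- list()
  rows <- purrr::pmap(keys, function(protein, sequence, start, end) {
    obs <- dplyr::filter(
      observed,
      .data$sequence == !!sequence, .data$start == !!start, .data$end == !!end
    )
    ref <- dplyr::filter(
      maxd,
      .data$sequence == !!sequence, .data$start == !!start, .data$end == !!end
    )
    base <- tibble::tibble(
      protein = protein, sequence = sequence, start = start, end = end
    )
    q <- exchangeable_amides(sequence)
    empty <- function(status, retention = NA_real_) {
      dplyr::mutate(
        base,
        q = q, retention = retention, n_phases = NA_integer_,
        r_squared = NA_real_, ln_pf_mean = NA_real_, status = status,
        fits = list(tibble::tibble())
      )
    }
    if (q == 0L) return(empty("uninformative"))
    if (nrow(ref) == 0L) return(empty("no_maxd_reference"))
    tmax <- theoretical_max_uptake(sequence, cond$d2o_fraction)
    bex <- estimate_backexchange(ref, tmax)
    corr <- correct_uptake(obs, bex)
    corrected_all[[length(corrected_all) + 1L]] <<- dplyr::bind_cols(
      base[rep(1, nrow(corr)), ],
      dplyr::select(corr, dplyr::any_of(c("state", "exposure", "replicate", "uptake")))
    )
    exp_fit <- tryCatch(
      select_model(
        corr,
        max_phases = config$max_phases, alpha = config$alpha,
        q_max = tmax, n_starts = config$n_starts
      ),
      error = function(e) NULL
    )
    if (is.null(exp_fit) || exp_fit$status == "failed") return(empty("failed", bex$retention))
    if (exp_fit$status == "uninformative") return(empty("uninformative", bex$retention))

    rates <- residue_intrinsic_rates(sequence, cond)
    grid <- 10^seq(
      log10(min(corr$exposure) / 2), log10(max(corr$exposure) * 2),
      length.out = 60
    )
    int_curve <- intrinsic_uptake_curve(rates, grid, cond$d2o_fraction)
    int_fit <- fit_stretched_exponential(
      int_curve,
      n_phases = exp_fit$n_phases, q_max = tmax, n_starts = config$n_starts
    )
    pf <- tryCatch(protection_factors(exp_fit, int_fit), error = function(e) NULL)
    if (is.null(pf)) return(empty("failed", bex$retention))
    dplyr::mutate(
      base,
      q = q, retention = bex$retention, n_phases = exp_fit$n_phases,
      r_squared = exp_fit$r_squared,
      ln_pf_mean = mean_ln_pf(exp_fit, int_fit),
      status = "fitted",
      fits = list(pf)
    )
  })
  results <- dplyr::bind_rows(rows)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- dplyr::select(results, -"fits")
    jsonlite::write_json(
      list(
        results = flat,
        phases = purrr::map(
          stats::setNames(results$fits, results$sequence),
          ~ as.data.frame(.x)
        )
      ),
      file.path(config$output_dir, "fits.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null"
    )
    readr::write_csv(
      dplyr::bind_rows(corrected_all),
      file.path(config$output_dir, "corrected.csv"), progress = FALSE
    )
    jsonlite::write_json(
      list(
        package_version = as.character(utils::packageVersion("mshdx")),
        seed = config$seed,
        alpha = config$alpha,
        max_phases = config$max_phases,
        config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
        n_peptides = nrow(results),
        statuses = as.list(table(results$status))
      ),
      file.path(config$output_dir, "run_log.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE
    )
  }
  results
}
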