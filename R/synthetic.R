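#' Reference peptide panel
#'
#' The five synthetic peptides used to characterize millisecond exchange: the
#' hormone bradykinin, the neurotransmitter leucine enkephalin, a consensus
#' antifreeze protein peptide (CN-AFP), and two designed TPR-motif peptides.
#'
#' @return A tibble with `name`, `sequence`, `start`, `end`.
#' @export
reference_peptides <- function() {
  tibble::tibble(
    name = c("bradykinin", "leu_enkephalin", "cn_afp", "ctprh1", "ctprs"),
    sequence = c(
      "RPPGFSPFR",
      "YGGFL",
      "DTASDAAAAAALTAANAAAAAEKTAADAAAAAAATAA",
      "AEAWYNLGNAYYK",
      "AEAKQNLGNAKQK"
    )
  ) |>
    dplyr::mutate(start = 1L, end = nchar(.data$sequence))
}

#' Exposure schedule used by the millisecond labeling experiments
#'
#' Fifteen labeling times spanning 50 ms to 300 s.
#'
#' @return Numeric vector of seconds.
#' @export
default_exposures <- function() {
  c(0.05, 0.1, 0.15, 0.20, 0.25, 0.35, 0.5, 0.75, 1, 2.5, 5, 15, 30, 60, 300)
}

#' Ground truth for a synthetic uptake study
#'
#' Bundles everything the generator needs: the peptide panel, per-peptide
#' protection (uniform ln(Pf) applied to every included residue), labeling
#' conditions, per-peptide back-exchange retention, replicate noise, exposure
#' schedule and seed. The default noise SD of 0.084 Da is fixed by requiring
#' a +/-0.01 Da 95% confidence interval at n = 270 replicates.
#'
#' @param peptides Tibble with `name`, `sequence` columns
#'   (default [reference_peptides()]).
#' @param ln_pf Uniform per-residue ln protection factor; scalar or one value
#'   per peptide.
#' @param conditions A [labeling_conditions()] object.
#' @param retention Back-exchange retention fraction in (0, 1]; scalar or per
#'   peptide.
#' @param noise_sd Additive Gaussian replicate noise SD in Da.
#' @param exposures Labeling times in seconds, strictly increasing.
#' @param n_replicates Replicates per exposure.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(peptides = reference_peptides(),
                             ln_pf = 0,
                             conditions = labeling_conditions(),
                             retention = 0.9,
                             noise_sd = 0.084,
                             exposures = default_exposures(),
                             n_replicates = 3L,
                             seed = 1L) {
  stopifnot(is.data.frame(peptides), all(c("name", "sequence") %in% names(peptides)))
  n_pep <- nrow(peptides)
  ln_pf <- rep_len(ln_pf, n_pep)
  retention <- rep_len(retention, n_pep)
  if (any(retention <= 0 | retention > 1)) abort("`retention` must lie in (0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (is.unsorted(exposures, strictly = TRUE) || any(exposures <= 0)) {
    abort("`exposures` must be strictly increasing and positive.")
  }
  structure(
    list(
      peptides = tibble::as_tibble(peptides),
      ln_pf = ln_pf, conditions = conditions, retention = retention,
      noise_sd = noise_sd, exposures = as.numeric(exposures),
      n_replicates = as.integer(n_replicates), seed = as.integer(seed)
    ),
    class = "simulation_truth"
  )
}

# noiseless expected uptake of one peptide under the truth's forward model
expected_uptake <- function(sequence, ln_pf, conditions, times) {
  rates <- residue_intrinsic_rates(sequence, conditions)
  k <- rates$k_int[rates$included] / exp(ln_pf)
  vapply(
    times,
    function(t) conditions$d2o_fraction * sum(1 - exp(-k * t)),
    numeric(1)
  )
}

#' Generate synthetic uptake tables with known ground truth
#'
#' Forward-simulates per-peptide deuterium uptake: intrinsic rates slowed by
#' the true protection factor, scaled by the D2O fraction and the
#' back-exchange retention, plus additive Gaussian replicate noise. A matched
#' maximally deuterated (maxD) reference series (retention times the
#' theoretical maximum, same noise) is produced for every peptide. Output is
#' in the state-data table schema accepted by [read_state_csv()] /
#' [write_state_csv()], so generated tables are valid inputs to every other
#' stage.
#'
#' @param truth A [simulation_truth()].
#' @return A list with `observed` and `maxd` tibbles (columns `protein`,
#'   `sequence`, `start`, `end`, `state`, `exposure`, `replicate`, `uptake`)
#'   and the `truth` object.
#' @export
generate_uptake_tables <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  cond <- truth$conditions
  pieces <- purrr::pmap(
    list(
      name = truth$peptides$name,
      sequence = truth$peptides$sequence,
      ln_pf = truth$ln_pf,
      retention = truth$retention
    ),
    function(name, sequence, ln_pf, retention) {
      q <- exchangeable_amides(sequence)
      grid <- tidyr::expand_grid(
        exposure = truth$exposures,
        replicate = seq_len(truth$n_replicates)
      )
      clean <- retention *
        expected_uptake(sequence, ln_pf, cond, grid$exposure)
      maxd_clean <- retention * cond$d2o_fraction * q
      base <- tibble::tibble(
        protein = name, sequence = sequence,
        start = 1L, end = nchar(sequence)
      )
      list(
        observed = dplyr::bind_cols(
          base[rep(1, nrow(grid)), ], state = "labeled", grid,
          uptake = pmax(clean + rnorm(nrow(grid), 0, truth$noise_sd), 0)
        ),
        maxd = dplyr::bind_cols(
          base[rep(1, nrow(grid)), ], state = "maxD", grid,
          uptake = pmax(maxd_clean + rnorm(nrow(grid), 0, truth$noise_sd), 0)
        )
      )
    }
  )
  list(
    observed = dplyr::bind_rows(purrr::map(pieces, "observed")),
    maxd = dplyr::bind_rows(purrr::map(pieces, "maxd")),
    truth = truth
  )
}

#' Replicate-dispersion study at a single labeling time
#'
#' Simulates many technical replicates of one peptide at one labeling time
#' and summarizes the deviations from the mean, as used to establish the
#' repeatability of a millisecond labeling instrument.
#'
#' @param peptide Sequence string or `peptide_spec`.
#' @param n_replicates Number of replicates (>= 2).
#' @param time Labeling time in seconds.
#' @param truth A [simulation_truth()] providing conditions, retention (first
#'   element), noise SD and seed.
#' @param ln_pf Uniform ln protection factor for the peptide.
#' @return A list with `replicates` (tibble of `replicate`, `uptake`,
#'   `deviation`) and `summary` (one-row tibble: `mean`, `sd`, `ci95`
#'   half-width, `relative_dispersion`).
#' @export
generate_replicate_study <- function(peptide, n_replicates, time,
                                     truth = simulation_truth(), ln_pf = 0) {
  if (n_replicates < 2L) abort("Need at least 2 replicates.")
  peptide <- as_peptide_spec(peptide)
  set.seed(truth$seed)
  clean <- truth$retention[1] *
    expected_uptake(peptide$sequence, ln_pf, truth$conditions, time)
  uptake <- clean + rnorm(n_replicates, 0, truth$noise_sd)
  dev <- uptake - mean(uptake)
  summary <- tibble::tibble(
    mean = mean(uptake),
    sd = sd(uptake),
    ci95 = qt(0.975, n_replicates - 1L) * sd(uptake) / sqrt(n_replicates),
    relative_dispersion = sd(uptake) / mean(uptake)
  )
  list(
    replicates = tibble::tibble(
      replicate = seq_len(n_replicates), uptake = uptake, deviation = dev
    ),
    summary = summary
  )
}

#' Generate a protein-scale peptide map (workload fixture)
#'
#' Random proteolytic-style peptide segments tiling a random protein
#' sequence, shaped like the peptide map of a large-enzyme benchmark
#' (hundreds of peptides, >95% coverage). Used to stress-test table handling
#' at realistic scale; the sequences carry no biological meaning.
#'
#' @param n_peptides Number of segments.
#' @param protein_length Length of the synthetic parent protein.
#' @param seed Integer seed.
#' @return A tibble with `name`, `sequence`, `start`, `end` and a
#'   `coverage` attribute (fraction of residues covered by at least one
#'   segment).
#' @export
generate_peptide_map <- function(n_peptides = 273, protein_length = 900,
                                 seed = 1L) {
  set.seed(seed)
  aa_pool <- setdiff(canonical_residues(), "P")
  protein <- c(
    sample(aa_pool, protein_length, replace = TRUE)
  )
  # sprinkle some prolines to exercise the exclusion rules
  pro_sites <- sample(protein_length, round(protein_length * 0.05))
  protein[pro_sites] <- "P"
  starts <- sort(sample(seq_len(protein_length - 25L), n_peptides, replace = TRUE))
  lens <- sample(5:25, n_peptides, replace = TRUE)
  ends <- pmin(starts + lens - 1L, protein_length)
  covered <- logical(protein_length)
  for (i in seq_len(n_peptides)) covered[starts[i]:ends[i]] <- TRUE
  out <- tibble::tibble(
    name = sprintf("pep%03d", seq_len(n_peptides)),
    sequence = vapply(
      seq_len(n_peptides),
      function(i) paste(protein[starts[i]:ends[i]], collapse = ""),
      character(1)
    ),
    start = starts, end = ends
  )
  attr(out, "coverage") <- mean(covered)
  out
}
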