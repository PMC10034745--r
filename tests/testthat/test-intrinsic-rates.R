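cond_ref <- labeling_conditions(pd_read = 6.6, temperature = 293.15, d2o_fraction = 1)

test_that("terminal and proline exclusion rules", {
  pos <- amide_positions("AAAAA")
  expect_equal(sum(pos$included), 3L)
  expect_equal(pos$exclusion_reason[1:2], c("N-terminal-1", "N-terminal-2"))

  expect_equal(exchangeable_amides("AAPA"), 1L)
  pos2 <- amide_positions("AAPA")
  expect_equal(pos2$exclusion_reason[3], "proline")
  expect_true(pos2$included[4])

  # bradykinin: positions 1-2 dropped, prolines at 3 and 7 carry no amide
  expect_equal(exchangeable_amides("RPPGFSPFR"), 5L)
  r <- residue_intrinsic_rates("RPPGFSPFR", cond_ref)
  expect_identical(r$k_int[!r$included], rep(0, 4))
  expect_true(all(r$k_int[r$included] > 0))
})

test_that("invalid sequences and out-of-range conditions are rejected", {
  expect_error(peptide_spec("AAXA"), "position 3")
  expect_error(peptide_spec("AAA", start_residue = 10, end_residue = 11), "span")
  expect_error(labeling_conditions(pd_read = 13.5), "pD")
  expect_error(labeling_conditions(temperature = 350), "[Tt]emperature")
  expect_error(labeling_conditions(d2o_fraction = 0), "d2o_fraction")
  rates <- residue_intrinsic_rates("AAAA", cond_ref)
  expect_error(intrinsic_uptake_curve(rates, c(-1, 1), 1), "non-negative")
})

test_that("alanine tetrapeptide rates match the hand spreadsheet computation", {
  r <- residue_intrinsic_rates("AAAA", cond_ref)
  k_oracle <- oracle_kint("AAAA", pd_read = 6.6, temperature = 293.15)
  expect_equal(r$k_int, k_oracle, tolerance = 1e-12)
  # frozen values computed from the oracle: pD 7.0, 293.15 K
  expect_equal(r$k_int[3], 2.2488, tolerance = 1e-4)
  expect_equal(r$k_int[4], 2.2466, tolerance = 1e-4)
})

test_that("rates agree with the oracle across sequences, pD and temperature", {
  cases <- expand.grid(
    seq = c("RPPGFSPFR", "YGGFL", "AEAWYNLGNAYYK", "DTASDAAAAAALTAANAAAAAEKTAADAAAAAAATAA"),
    pd_read = c(2.0, 6.6, 9.0),
    temp = c(278.15, 296.15),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    cond <- labeling_conditions(cases$pd_read[i], cases$temp[i], 0.95)
    r <- residue_intrinsic_rates(cases$seq[i], cond)
    expect_equal(
      r$k_int, oracle_kint(cases$seq[i], cases$pd_read[i], cases$temp[i]),
      tolerance = 1e-10
    )
  }
})

test_that("uptake curve basics: zero at t = 0, half-life identity, saturation", {
  rates <- residue_intrinsic_rates("AAAA", cond_ref)
  expect_equal(intrinsic_uptake_curve(rates, 0, 1)$uptake, 0)

  # one included residue with k = 1/s: at t = ln 2 exactly half a dalton
  one <- tibble::tibble(k_int = 1, included = TRUE)
  expect_equal(intrinsic_uptake_curve(one, log(2), 1)$uptake, 0.5)

  # saturates at d2o_fraction * Q
  curve <- intrinsic_uptake_curve(rates, 1e7, 0.95)
  expect_equal(curve$uptake, 0.95 * 2, tolerance = 1e-9)
})

test_that("uptake curves are monotone, bounded, and additive over residues", {
  cond <- labeling_conditions()
  times <- sort(c(0, 10^seq(-3, 3, length.out = 40)))
  for (seqn in reference_peptides()$sequence) {
    r <- residue_intrinsic_rates(seqn, cond)
    curve <- intrinsic_uptake_curve(r, times, cond$d2o_fraction)
    expect_true(all(diff(curve$uptake) >= -1e-12))
    expect_true(all(curve$uptake <= cond$d2o_fraction * exchangeable_amides(seqn) + 1e-9))
    expect_equal(
      curve$uptake,
      oracle_uptake(r$k_int[r$included], times, cond$d2o_fraction),
      tolerance = 1e-12
    )
  }
})

test_that("rates are continuous in pD within the table range", {
  pds <- seq(3, 9, by = 0.05)
  k3 <- vapply(pds, function(p) {
    residue_intrinsic_rates("AHDA", labeling_conditions(p, 293.15, 1))$k_int[3]
  }, numeric(1))
  ratio <- k3[-1] / k3[-length(k3)]
  expect_true(all(ratio > 0.5 & ratio < 2)) # no jumps across titration points
})
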