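#' Peptide specification
#'
#' Describes one peptide (a synthetic peptide or a proteolytic fragment) with
#' its residue numbering in the parent protein, and the bookkeeping of which
#' backbone amides can retain an observable deuterium label. The first two
#' residues are always excluded: after proteolysis the first amide is a
#' primary amine, and deuterium on the second residue is lost during the
#' chromatographic separation. Proline carries no amide hydrogen.
#'
#' @param sequence One-letter amino-acid string (canonical residues only).
#' @param start_residue,end_residue 1-based residue numbers of the peptide in
#'   the parent protein. Defaults describe a free peptide numbered from 1.
#' @param is_free_peptide Logical; synthetic peptide rather than a proteolytic
#'   fragment. Exclusion rules are identical for both; the flag is carried as
#'   metadata.
#'
#' @return An object of class `peptide_spec`: a list with `sequence`,
#'   `start_residue`, `end_residue`, `is_free_peptide`, and `n_amides` (the
#'   number of exchangeable amides, Q).
#' @examples
#' bk <- peptide_spec("RPPGFSPFR")
#' bk$n_amides
#' @export
peptide_spec <- function(sequence,
                         start_residue = 1L,
                         end_residue = start_residue + nchar(sequence) - 1L,
                         is_free_peptide = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    abort("`sequence` must be a single non-empty string.")
  }
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% canonical_residues())
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-canonical residue '%s' at position %d of '%s'.",
      aa[bad[1]], bad[1], sequence
    ))
  }
  start_residue <- as.integer(start_residue)
  end_residue <- as.integer(end_residue)
  if (end_residue - start_residue + 1L != nchar(sequence)) {
    abort("Residue span does not match sequence length.")
  }
  structure(
    list(
      sequence = sequence,
      start_residue = start_residue,
      end_residue = end_residue,
      is_free_peptide = isTRUE(is_free_peptide),
      n_amides = exchangeable_amides(sequence)
    ),
    class = "peptide_spec"
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf(
    "<peptide_spec> %s [%d-%d], Q = %d exchangeable amides\n",
    x$sequence, x$start_residue, x$end_residue, x$n_amides
  ))
  invisible(x)
}

canonical_residues <- function() {
  c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
}

as_peptide_spec <- function(x) {
  if (inherits(x, "peptide_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(peptide_spec(x))
  abort("Expected a `peptide_spec` or a single sequence string.")
}

#' Count exchangeable backbone amides
#'
#' Q = length - 2 - (number of prolines at position 3 onwards). Positions 1
#' and 2 never contribute an observable amide.
#'
#' @param sequence One-letter amino-acid string.
#' @return Integer count, >= 0.
#' @examples
#' exchangeable_amides("AAAAA") # 3
#' exchangeable_amides("AAPA")  # 1
#' @export
exchangeable_amides <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n <= 2L) return(0L)
  as.integer(n - 2L - sum(aa[3:n] == "P"))
}

#' Per-position amide bookkeeping for a peptide
#'
#' @param peptide A `peptide_spec` or sequence string.
#' @return A tibble with one row per residue: `position` (within peptide),
#'   `residue` (number in the parent protein), `aa`, `included`, and
#'   `exclusion_reason` (`NA` for included residues).
#' @export
amide_positions <- function(peptide) {
  peptide <- as_peptide_spec(peptide)
  aa <- strsplit(peptide$sequence, "")[[1]]
  n <- length(aa)
  reason <- rep(NA_character_, n)
  if (n >= 1L) reason[1] <- "N-terminal-1"
  if (n >= 2L) reason[2] <- "N-terminal-2"
  pro <- which(aa == "P")
  pro <- pro[pro >= 3L]
  reason[pro] <- "proline"
  tibble::tibble(
    position = seq_len(n),
    residue = peptide$start_residue + seq_len(n) - 1L,
    aa = aa,
    included = is.na(reason),
    exclusion_reason = reason
  )
}

#' Labeling conditions for the deuteration reaction
#'
#' @param pd_read pH-meter reading of the D2O labeling buffer (uncorrected).
#'   The glass-electrode correction pD = pD_read + 0.4 is applied downstream.
#' @param temperature Labeling temperature in kelvin.
#' @param d2o_fraction Fraction of D2O in the labeling reaction after mixing,
#'   in (0, 1].
#' @return An object of class `labeling_conditions`.
#' @examples
#' labeling_conditions(pd_read = 7.06, temperature = 296.15, d2o_fraction = 0.95)
#' @export
labeling_conditions <- function(pd_read = 7.06,
                                temperature = 296.15,
                                d2o_fraction = 0.95) {
  pd <- pd_read + 0.4
  if (pd < 1 || pd > 13) {
    abort(sprintf("Corrected pD %.2f outside the table validity range 1-13.", pd))
  }
  if (temperature <= 273 || temperature < 258 || temperature > 323) {
    abort(sprintf("Temperature %.1f K outside the supported range 273-323 K.", temperature))
  }
  if (d2o_fraction <= 0 || d2o_fraction > 1) {
    abort("`d2o_fraction` must lie in (0, 1].")
  }
  structure(
    list(
      pd_read = pd_read, pd = pd,
      temperature = temperature, d2o_fraction = d2o_fraction
    ),
    class = "labeling_conditions"
  )
}

#' D2O fraction obtained by mixing a protonated sample into D2O buffer
#'
#' A 1:`mix_ratio` mix of protonated sample into buffer of the given isotopic
#' purity gives `mix_ratio * purity / (mix_ratio + 1)` D2O in the labeling
#' reaction, e.g. 1:20 into 99.9% D2O gives ~0.951.
#'
#' @param mix_ratio Volumetric parts of D2O buffer per part of sample.
#' @param d2o_purity Isotopic purity of the D2O buffer, in (0, 1].
#' @return D2O fraction in (0, 1).
#' @export
d2o_fraction_after_mixing <- function(mix_ratio = 20, d2o_purity = 0.999) {
  if (mix_ratio <= 0) abort("`mix_ratio` must be positive.")
  if (d2o_purity <= 0 || d2o_purity > 1) abort("`d2o_purity` must lie in (0, 1].")
  mix_ratio * d2o_purity / (mix_ratio + 1)
}
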