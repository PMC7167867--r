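#' Published reference summaries (worked-example inputs)
#'
#' Group summary statistics (controls vs. retinitis pigmentosa cases, 20
#' eyes each) from the published widefield OCTA case-control tables this
#' package emulates: functional parameters (visual acuity, ERG/mfERG),
#' per-plexus per-region perfusion density, and vessel length density. Each
#' row carries the printed group means and SDs, the printed
#' controls-minus-cases mean difference, and the printed p-value. They are
#' used as worked-example inputs for the reporting layer; the printed
#' differences are reproducible from the printed means only for rows where
#' the publication rounded consistently (see `consistent`).
#'
#' @return a tibble with columns `panel`, `variable`, `plexus`, `region`,
#'   `control_mean`, `control_sd`, `case_mean`, `case_sd`,
#'   `printed_difference`, `printed_p`, and the derived logical
#'   `consistent` (printed difference equals the subtraction of printed
#'   means to printed precision).
#' @export
reference_summaries <- function() {
  path <- system.file("extdata", "reference_summaries.csv", package = "octaquant")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$consistent <- abs((d$control_mean - d$case_mean) - d$printed_difference) < 0.005
  tibble::as_tibble(d)
}

#' Reconstruct a sample with exact mean and SD
#'
#' Builds a deterministic n-vector whose sample mean and SD equal the given
#' summary statistics exactly (an equally spaced base sample is centred and
#' rescaled), so reporting functions can be exercised against published
#' summary rows.
#'
#' @param mean,sd target sample statistics (`sd` with the n-1 denominator).
#' @param n sample size (>= 2).
#' @return numeric vector of length `n`.
#' @export
sample_with_moments <- function(mean, sd, n = 20L) {
  if (n < 2) stop("`n` must be >= 2")
  z <- seq_len(n) - (n + 1) / 2
  z <- z / stats::sd(z)
  mean + sd * z
}
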