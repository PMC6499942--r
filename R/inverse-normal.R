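#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their shifted ranks,
#' `qnorm((r - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default. Ties receive averaged ranks (heavy ties arise by design when
#' unaffected individuals have onset age set to 0). Variance-component
#' models are sensitive to kurtosis, so quantitative outcomes are
#' transformed before fitting.
#'
#' @param x numeric vector (length at least 2, not all equal).
#' @param c rank offset constant (Blom: 3/8).
#' @return numeric vector of normal scores, rank-preserving.
#' @export
inverse_normal <- function(x, c = 3 / 8) {
  if (length(x) < 2) stop("inverse_normal: need at least 2 values")
  if (anyNA(x)) stop("inverse_normal: missing values not allowed")
  if (all(x == x[1])) stop("inverse_normal: all values identical, no ranking possible")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - c) / (length(x) - 2 * c + 1))
}
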