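# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (so 86.5 -> 87
#' and -86.5 -> -87), the convention used for all cohort percentages. Base
#' `round()` uses banker's rounding and would give 86.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 86.49, 86.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Dirichlet sampler via normalized gammas; alpha is the concentration vector.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "tmshet_input_error")
}

# Validate and renormalize a 4-bin staining-intensity fraction vector.
check_fractions <- function(p, arg = "fractions") {
  if (!is.numeric(p) || length(p) != 4L) {
    stop_input("`%s` must be a numeric vector of length 4 (intensities 0/+/++/+++).", arg)
  }
  if (anyNA(p) || any(!is.finite(p))) {
    stop_input("`%s` contains missing or non-finite values.", arg)
  }
  if (any(p < 0)) {
    stop_input("`%s` must be nonnegative.", arg)
  }
  s <- sum(p)
  if (s <= 0) {
    stop_input("`%s` sums to zero; an empty intensity profile cannot be scored.", arg)
  }
  p / s
}
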