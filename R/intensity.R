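# Per-sample staining-intensity scoring: fractions, H-score, Shannon
# diversity, observer consensus, and the per-sample heterogeneity call.
#
# An intensity profile is a length-4 fraction vector p = (p0, p1, p2, p3)
# over the ordinal staining grades 0/+/++/+++; fractions are nonnegative and
# renormalized to sum to 1 on entry everywhere.

#' Convert cell counts per staining intensity into fractions
#'
#' @param counts Numeric vector of 4 nonnegative cell counts, one per
#'   intensity grade 0/+/++/+++.
#' @return Numeric fraction vector summing to 1.
#' @export
#' @examples
#' intensity_fractions(c(50, 30, 15, 5))
intensity_fractions <- function(counts) {
  if (!is.numeric(counts) || length(counts) != 4L) {
    stop_input("`counts` must be a numeric vector of length 4.")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_input("`counts` must be nonnegative and complete.")
  }
  if (sum(counts) == 0) {
    stop_input("all counts are zero: empty sample, no cells to score.")
  }
  counts / sum(counts)
}

#' H-score of a staining-intensity profile
#'
#' The semi-quantitative immunohistochemistry score: each intensity grade
#' (0, 1, 2, 3) is weighted by the percentage of cells at that grade, giving
#' a value on the 0-300 scale: `100 * (0*p0 + 1*p1 + 2*p2 + 3*p3)`.
#'
#' @param fractions Length-4 fraction vector (renormalized if needed).
#' @return H-score in \[0, 300\].
#' @export
#' @examples
#' h_score(c(0.10, 0.20, 0.30, 0.40)) # 200
h_score <- function(fractions) {
  p <- check_fractions(fractions)
  100 * sum((0:3) * p)
}

#' Shannon Diversity Index of a staining-intensity profile
#'
#' Entropy `-sum(p_i * ln p_i)` of the intensity distribution, with the
#' convention `0 * ln 0 = 0`. Ranges from 0 (all cells at one grade,
#' homogeneous staining) to `ln 4 ~ 1.386` (uniform over the 4 grades,
#' maximal intratumoural heterogeneity).
#'
#' @inheritParams h_score
#' @return SDI value in \[0, ln 4\].
#' @export
#' @examples
#' shannon_diversity(c(0.25, 0.25, 0.25, 0.25)) # log(4)
shannon_diversity <- function(fractions) {
  p <- check_fractions(fractions)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Consensus profile across independent observers
#'
#' Combines the intensity profiles recorded by independent observers for the
#' same sample and marker into one profile by element-wise averaging of the
#' fraction vectors (renormalized). Accepts either a numeric matrix with one
#' row per observer and 4 columns, or a data frame with columns `p0..p3`
#' (and optionally `sample_id`/`marker`, which must then be constant).
#'
#' @param profiles Matrix or data frame of observer profiles.
#' @return Length-4 consensus fraction vector.
#' @export
#' @examples
#' consensus_profile(rbind(c(0.6, 0.4, 0, 0), c(0.4, 0.4, 0.2, 0)))
consensus_profile <- function(profiles) {
  if (is.data.frame(profiles)) {
    for (id in c("sample_id", "marker")) {
      if (id %in% names(profiles) && length(unique(profiles[[id]])) > 1L) {
        stop_input("profiles mix more than one `%s`; consensus is per sample and marker.", id)
      }
    }
    profiles <- as.matrix(profiles[, c("p0", "p1", "p2", "p3")])
  }
  if (is.numeric(profiles) && is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1)
  }
  if (!is.matrix(profiles) || ncol(profiles) != 4L || nrow(profiles) < 1L) {
    stop_input("`profiles` must have one row per observer and 4 fraction columns.")
  }
  rows <- t(apply(profiles, 1L, check_fractions))
  check_fractions(colMeans(rows))
}

#' Per-sample intratumoural heterogeneity call
#'
#' A sample's staining is called heterogeneous when at least two intensity
#' grades each hold a non-trivial share of the cells: `>= 2` bins with
#' fraction `>= min_minor_fraction`. The default 0.10 is robust to single
#' stray cells while still catching genuine mixed-intensity staining.
#'
#' @inheritParams h_score
#' @param min_minor_fraction Minimum fraction a bin must hold to count as
#'   occupied, in (0, 0.5\].
#' @return Logical: is the sample heterogeneous?
#' @export
#' @examples
#' call_sample_heterogeneity(c(0.95, 0.05, 0, 0)) # FALSE
#' call_sample_heterogeneity(c(0.5, 0.5, 0, 0))   # TRUE
call_sample_heterogeneity <- function(fractions, min_minor_fraction = 0.10) {
  if (!is.numeric(min_minor_fraction) || length(min_minor_fraction) != 1L ||
      is.na(min_minor_fraction) ||
      min_minor_fraction <= 0 || min_minor_fraction > 0.5) {
    stop_input("`min_minor_fraction` must be a single value in (0, 0.5].")
  }
  p <- check_fractions(fractions)
  sum(p >= min_minor_fraction) >= 2L
}
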