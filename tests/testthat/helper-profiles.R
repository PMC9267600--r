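# Shared fixtures built in code.

# Random intensity profiles (uniform on the simplex) for property tests.
random_profiles <- function(n, seed = 42) {
  set.seed(seed)
  x <- matrix(rgamma(n * 4, 1), ncol = 4)
  x / rowSums(x)
}

# Independent entropy oracle: explicit term-by-term summation.
entropy_oracle <- function(p) {
  s <- 0
  for (x in p) {
    if (x > 0) s <- s - x * log(x)
  }
  s
}

# A small observer-level cohort tibble with known consensus values.
toy_cohort <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s1", "s2"), 2),
    marker = "GLS",
    subtype = rep(c("LumA", "LumA", "LumB"), 2),
    observer = rep(c("obs1", "obs2", "obs1"), c(1, 1, 1))[c(1, 2, 3, 1, 2, 3)],
    p0 = c(0.6, 0.4, 1, 0.6, 0.4, 1),
    p1 = c(0.4, 0.4, 0, 0.4, 0.4, 0),
    p2 = c(0, 0.2, 0, 0, 0.2, 0),
    p3 = c(0, 0, 0, 0, 0, 0),
    n_cells = 100
  )[1:3, ]
}

# Logical per-sample calls with k heterogeneous out of n.
calls_of <- function(k, n) c(rep(TRUE, k), rep(FALSE, n - k))
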