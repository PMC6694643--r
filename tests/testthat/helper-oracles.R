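# Independent oracles used across the suite.

# Threshold deviate by root-finding on the normal CDF (independent of the
# quantile routine the implementation uses).
oracle_deviates <- function(q) {
  x <- stats::uniroot(function(z) stats::pnorm(z) - (1 - q),
                      c(-10, 10), tol = 1e-14)$root
  list(x = x, a = stats::dnorm(x) / q)
}

# Expected per-sibship (T, R, J, Q) under ascertainment, by complete
# enumeration of the affected count a ~ Binomial(size, theta).
oracle_sibship_expectation <- function(size, theta, ascertainment, pi) {
  a <- 0:size
  pa <- stats::dbinom(a, size, theta)
  w <- if (ascertainment == "complete") 1 - (1 - pi)^a else pi * a
  keep <- pa * w                      # P(a and ascertained)
  p_asc <- sum(keep)
  cond <- keep / p_asc                # P(a | ascertained)
  list(
    ET = size,
    ER = sum(a * cond),
    EJ = sum((a == 1) * cond),
    EQ = sum((a == 2) * cond),
    p_ascertained = p_asc
  )
}

# Random valid roster for round-trip property tests.
random_roster <- function(n, seed) {
  set.seed(seed)
  classes <- relative_classes()$relative_class
  tibble::tibble(
    family_id = sprintf("f%03d", sample.int(50, n, replace = TRUE)),
    group = sample(c("case", "control"), n, replace = TRUE),
    relative_class = sample(classes, n, replace = TRUE),
    affected = sample(0:1, n, replace = TRUE)
  )
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "famline")
}
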