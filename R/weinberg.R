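#' Modified-Weinberg (singles) segregation ratio
#'
#' The ascertainment-corrected segregation ratio p = (R - J) / (T - J)
#' over the ascertained sibships: T total siblings, R total affected, J
#' sibships with exactly one affected member. Removing the single-case
#' sibships from numerator and denominator is the Weinberg "singles"
#' correction for ascertainment through affected members.
#'
#' @param table A `sibship_table`.
#' @return The segregation ratio, an exact rational of the totals.
#' @examples
#' segregation_ratio(sibship_from_totals(2013, 891, 580))
#' @export
segregation_ratio <- function(table) {
  tot <- sibship_totals(table)
  # zero numerator short-circuits: with no sibship beyond its single case
  # there are no secondary cases, so p = 0 even when T = J (all-singleton
  # sibships make the ratio 0/0 otherwise)
  if (tot$R == tot$J) return(0)
  if (tot$T == tot$J) {
    rlang::abort("segregation ratio undefined: T = J (no non-proband siblings)",
                 class = "famline_domain_error")
  }
  (tot$R - tot$J) / (tot$T - tot$J)
}

#' Standard error of the segregation ratio
#'
#' Two conventions are provided because published method sections and the
#' arithmetic actually carried out sometimes disagree in the exponent of
#' (T - J) in the first term:
#'
#' * `"as_computed"` (default):
#'   sqrt( (R-J)(T-R)/(T-J)^3 + 2Q(T-R)^2/(T-J)^4 ) — the binomial-style
#'   variance; this is the form whose intermediate terms match published
#'   worked examples.
#' * `"as_printed"`:
#'   sqrt( (R-J)(T-R)/(T-J)^2 + 2Q(T-R)^2/(T-J)^4 ) — the formula as it
#'   sometimes appears in print; its first term is not divided by the
#'   effective sample size and yields implausibly large errors.
#'
#' Q is the number of sibships with exactly two affected members.
#'
#' @param table A `sibship_table` (its stored Q is used unless overridden).
#' @param se_mode `"as_computed"` or `"as_printed"`.
#' @param Q Optional override for the two-case sibship count.
#' @return The standard error (scalar).
#' @export
segregation_se <- function(table, se_mode = c("as_computed", "as_printed"),
                           Q = NULL) {
  se_mode <- match.arg(se_mode)
  tot <- sibship_totals(table)
  Qv <- if (!is.null(Q)) Q else tot$Q
  if (is.null(Qv) || is.na(Qv)) {
    rlang::abort(
      "Q (two-case sibship count) is required for the standard error; supply households_two_cases or Q=",
      class = "famline_validation_error"
    )
  }
  if (tot$T == tot$J) {
    rlang::abort("standard error undefined: T = J",
                 class = "famline_domain_error")
  }
  TJ <- tot$T - tot$J
  first_exp <- if (se_mode == "as_computed") 3 else 2
  sqrt((tot$R - tot$J) * (tot$T - tot$R) / TJ^first_exp +
         2 * Qv * (tot$T - tot$R)^2 / TJ^4)
}

#' Normal-theory 95% confidence interval for the segregation ratio
#' @param p Point estimate.
#' @param se Standard error (>= 0).
#' @return Numeric length-2 vector `(p - 1.96 se, p + 1.96 se)`.
#' @export
segregation_ci <- function(p, se) {
  if (is.na(se) || se < 0) {
    rlang::abort("`se` must be non-negative", class = "famline_domain_error")
  }
  c(p - 1.96 * se, p + 1.96 * se)
}

#' Classify the inheritance pattern from a segregation ratio
#'
#' Under classical genetic theory the segregation ratio is 0.50 for
#' monogenic dominant and 0.25 for monogenic recessive inheritance. The
#' rule: a pattern is "matched" if its theoretical ratio falls inside the
#' 95% CI (dominant, recessive), or if the whole CI lies below 0.25
#' (multigene — polygenic liability dilutes the per-sibling recurrence
#' below the single-gene floor). Exactly one match classifies; zero or
#' several matches are inconclusive.
#'
#' @param p Segregation ratio point estimate.
#' @param ci95 Length-2 confidence interval.
#' @return One of `"consistent_dominant"`, `"consistent_recessive"`,
#'   `"below_recessive_multigene"`, `"inconclusive"`.
#' @examples
#' classify_inheritance(0.217, c(0.188, 0.245))  # multigene
#' classify_inheritance(0.50, c(0.45, 0.55))     # dominant
#' @export
classify_inheritance <- function(p, ci95) {
  stopifnot(length(ci95) == 2L, ci95[1] <= ci95[2])
  matches <- c(
    consistent_dominant = ci95[1] <= 0.50 && 0.50 <= ci95[2],
    consistent_recessive = ci95[1] <= 0.25 && 0.25 <= ci95[2],
    below_recessive_multigene = ci95[2] < 0.25
  )
  if (sum(matches) == 1L) names(matches)[matches] else "inconclusive"
}

#' Full modified-Weinberg segregation analysis
#'
#' Point estimate, standard error, 95% CI and inheritance-pattern
#' classification from a sibship table, in one fitted object.
#'
#' @inheritParams segregation_se
#' @return An object of class `weinberg_fit`; see [tidy.weinberg_fit()].
#' @examples
#' fit <- weinberg_segregation(sibship_from_totals(2013, 891, 580, 163))
#' fit
#' @export
weinberg_segregation <- function(table,
                                 se_mode = c("as_computed", "as_printed"),
                                 Q = NULL) {
  se_mode <- match.arg(se_mode)
  p <- segregation_ratio(table)
  se <- segregation_se(table, se_mode = se_mode, Q = Q)
  ci <- segregation_ci(p, se)
  structure(
    list(
      p = p, se = se, ci95 = ci,
      classification = classify_inheritance(p, ci),
      se_mode = se_mode,
      totals = sibship_totals(table)
    ),
    class = "weinberg_fit"
  )
}

#' @export
print.weinberg_fit <- function(x, ...) {
  cat(sprintf(
    "<weinberg_fit> p = %.3f, SE = %.3f (%s), 95%% CI (%.3f, %.3f)\n  %s\n",
    x$p, x$se, x$se_mode, x$ci95[1], x$ci95[2], x$classification))
  invisible(x)
}

#' Tidy a segregation-ratio fit
#' @param x A `weinberg_fit`.
#' @param ... Unused.
#' @return A one-row tibble with estimate, SE, CI and classification.
#' @export
tidy.weinberg_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$p, std.error = x$se,
    conf.low = x$ci95[1], conf.high = x$ci95[2],
    classification = x$classification, se_mode = x$se_mode
  )
}

#' Glance at a segregation-ratio fit
#' @param x A `weinberg_fit`.
#' @param ... Unused.
#' @return A one-row tibble including the table totals.
#' @export
glance.weinberg_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(p = x$p, se = x$se, classification = x$classification),
    x$totals
  )
}
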