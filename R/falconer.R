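resolve_deviates <- function(q, deviates, table, tol) {
  if (deviates == "exact") {
    threshold_deviates(q)
  } else {
    if (is.null(table)) {
      rlang::abort("deviates = \"table\" requires a lookup `table`",
                   class = "famline_lookup_error")
    }
    deviates_from_table(q, table, tol = tol)
  }
}

#' Falconer liability-threshold heritability from relative prevalences
#'
#' Estimates the heritability of liability from the prevalence of a binary
#' trait among relatives of cases (`q1`) versus relatives of controls
#' (`q0`), following Falconer's regression of relative liability on proband
#' liability. The control arm supplies the reference threshold: with
#' p0 = 1 - q0, threshold deviates x0, x1 and mean deviate a0, the
#' regression coefficient is
#'
#'   b = p0 (x0 - x1) / a0
#'
#' and heritability is h^2 = b / r (with r the genetic similarity
#' coefficient of the relative class: 1/2, 1/4 or 1/8). Some published
#' analyses instead multiply b by a fixed 2 for every degree of relatedness;
#' `multiplier = "paper_fixed_2"` reproduces that convention (identical to
#' `"one_over_r"` at r = 0.5).
#'
#' The standard error follows the formula
#' SE(h^2) = m * sqrt( p1 / (A a1^2) * (p0 / a0)^2 ), with m the same
#' multiplier applied to b, A the number of case probands and a1 the mean
#' deviate at q1. The 95% interval is h^2 +/- 1.96 SE.
#'
#' Estimates outside \[0, 1\] are never clamped — they are returned as-is
#' with a quality flag, since truncation would hide model misfit.
#'
#' @param q0 Prevalence among control-family relatives, in (0, 1).
#' @param q1 Prevalence among case-family relatives, in (0, 1).
#' @param r Genetic similarity coefficient: 0.5, 0.25 or 0.125.
#' @param A Number of case probands, used for the standard error; `NULL`
#'   skips SE and CI.
#' @param deviates `"exact"` computes x and a from normal theory (default);
#'   `"table"` looks them up in `table` (reproducing a published lookup).
#' @param table Deviate lookup table (`q`, `x`, `a`) for table mode.
#' @param tol Lookup tolerance passed to [deviates_from_table()].
#' @param multiplier `"one_over_r"` (default) or `"paper_fixed_2"`.
#' @return An object of class `falconer_h2` with elements `h2`, `se`,
#'   `ci95`, `modes`, `flags` and the resolved deviates; see
#'   [tidy.falconer_h2()].
#' @examples
#' # exact normal-theory deviates
#' estimate_h2(q0 = 0.2643, q1 = 0.4264, r = 0.5, A = 342)
#' @export
estimate_h2 <- function(q0, q1, r, A = NULL,
                        deviates = c("exact", "table"), table = NULL,
                        tol = 1e-8,
                        multiplier = c("one_over_r", "paper_fixed_2")) {
  deviates <- match.arg(deviates)
  multiplier <- match.arg(multiplier)
  for (q in c(q0, q1)) {
    if (!is.numeric(q) || is.na(q) || q <= 0 || q >= 1) {
      rlang::abort("prevalences must lie strictly inside (0, 1)",
                   class = "famline_domain_error")
    }
  }
  if (!isTRUE(all.equal(r, 0.5)) && !isTRUE(all.equal(r, 0.25)) &&
      !isTRUE(all.equal(r, 0.125))) {
    rlang::abort("`r` must be one of 0.5, 0.25, 0.125",
                 class = "famline_domain_error")
  }
  d0 <- resolve_deviates(q0, deviates, table, tol)
  d1 <- resolve_deviates(q1, deviates, table, tol)
  p0 <- 1 - q0
  p1 <- 1 - q1
  b <- p0 * (d0$x - d1$x) / d0$a
  m <- if (multiplier == "one_over_r") 1 / r else 2
  h2 <- m * b

  flags <- character(0)
  if (d0$x < d1$x) flags <- c(flags, "negative_h2")
  if (h2 < 0 || h2 > 1) flags <- c(flags, "out_of_range")

  se <- NA_real_
  ci95 <- c(NA_real_, NA_real_)
  if (!is.null(A)) {
    se <- h2_standard_error(q1, A, a1 = d1$a, p0 = p0, a0 = d0$a,
                            multiplier_value = m)
    ci95 <- h2_confidence_interval(h2, se)
  }

  structure(
    list(
      h2 = h2, se = se, ci95 = ci95,
      q0 = q0, q1 = q1, r = r, A = A,
      deviates0 = d0, deviates1 = d1,
      modes = list(deviates = deviates, multiplier = multiplier),
      flags = flags
    ),
    class = "falconer_h2"
  )
}

#' Standard error of the Falconer heritability estimate
#'
#' Literal evaluation of SE(h^2) = m * sqrt( p1 / (A a1^2) * (p0/a0)^2 ),
#' with p1 = 1 - q1 and m the heritability multiplier (1/r, or the fixed 2
#' of some published conventions). Decreases as 1/sqrt(A).
#'
#' @param q1 Case-arm relative prevalence.
#' @param A Number of case probands (> 0).
#' @param a1 Mean deviate of affected at q1.
#' @param p0 Non-affection probability in the control arm, 1 - q0.
#' @param a0 Mean deviate of affected at q0.
#' @param multiplier_value The numeric multiplier m (e.g. `1/r` or `2`).
#' @return The standard error (scalar).
#' @export
h2_standard_error <- function(q1, A, a1, p0, a0, multiplier_value) {
  if (is.null(A) || is.na(A) || A <= 0) {
    rlang::abort("`A` (case count) must be a positive number",
                 class = "famline_domain_error")
  }
  p1 <- 1 - q1
  multiplier_value * sqrt(p1 / (A * a1^2) * (p0 / a0)^2)
}

#' Normal-theory 95% confidence interval
#' @param h2 Point estimate.
#' @param se Standard error (>= 0).
#' @return Numeric length-2 vector `(h2 - 1.96 se, h2 + 1.96 se)`.
#' @export
h2_confidence_interval <- function(h2, se) {
  if (is.na(se)) return(c(NA_real_, NA_real_))
  if (se < 0) {
    rlang::abort("`se` must be non-negative", class = "famline_domain_error")
  }
  c(h2 - 1.96 * se, h2 + 1.96 * se)
}

#' Falconer heritability for each degree of relatedness
#'
#' Convenience wrapper: takes a by-group degree-level prevalence table,
#' pairs the control-arm prevalence (q0) with the case-arm prevalence (q1)
#' within each degree, applies the degree's genetic similarity coefficient
#' (0.5, 0.25, 0.125) and estimates h^2 per degree.
#'
#' @param prevalence A `prevalence_table` at `level = "degree"` with
#'   `by_group = TRUE`.
#' @inheritParams estimate_h2
#' @return A named list of `falconer_h2` objects keyed `degree_1` ...;
#'   combine with [tidy_heritability()].
#' @export
falconer_by_degree <- function(prevalence, A = NULL,
                               deviates = c("exact", "table"), table = NULL,
                               tol = 1e-8,
                               multiplier = c("one_over_r", "paper_fixed_2")) {
  stopifnot(inherits(prevalence, "prevalence_table"))
  if (attr(prevalence, "level") != "degree" ||
      !isTRUE(attr(prevalence, "by_group"))) {
    rlang::abort("need a by-group prevalence table at level = \"degree\"",
                 class = "famline_validation_error")
  }
  deviates <- match.arg(deviates)
  multiplier <- match.arg(multiplier)
  r_by_degree <- c(degree_1 = 0.5, degree_2 = 0.25, degree_3 = 0.125)
  wide <- tibble::as_tibble(prevalence) |>
    tidyr::pivot_wider(id_cols = "stratum", names_from = "group",
                       values_from = "q")
  fits <- purrr::pmap(
    list(wide$stratum, wide$control, wide$case),
    function(stratum, q0, q1) {
      estimate_h2(q0 = q0, q1 = q1, r = unname(r_by_degree[stratum]),
                  A = A, deviates = deviates, table = table, tol = tol,
                  multiplier = multiplier)
    }
  )
  names(fits) <- wide$stratum
  fits
}

#' Combine per-degree heritability fits into one tibble
#' @param fits A named list of `falconer_h2` objects, as returned by
#'   [falconer_by_degree()].
#' @return A tibble with one row per fit.
#' @export
tidy_heritability <- function(fits) {
  purrr::imap(fits, function(f, nm) {
    dplyr::mutate(generics::tidy(f), stratum = nm, .before = 1)
  }) |> purrr::list_rbind()
}

#' @export
print.falconer_h2 <- function(x, ...) {
  cat(sprintf(
    "<falconer_h2> h2 = %.4f (%.2f%%)", x$h2, 100 * x$h2))
  if (!is.na(x$se)) {
    cat(sprintf(", SE = %.4f, 95%% CI (%.4f, %.4f)",
                x$se, x$ci95[1], x$ci95[2]))
  }
  cat(sprintf("\n  r = %s, deviates = %s, multiplier = %s\n",
              format(x$r), x$modes$deviates, x$modes$multiplier))
  if (length(x$flags) > 0) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a Falconer heritability fit
#' @param x A `falconer_h2` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, plus inputs and mode flags.
#' @export
tidy.falconer_h2 <- function(x, ...) {
  tibble::tibble(
    estimate = x$h2, std.error = x$se,
    conf.low = x$ci95[1], conf.high = x$ci95[2],
    q0 = x$q0, q1 = x$q1, r = x$r,
    deviates = x$modes$deviates, multiplier = x$modes$multiplier,
    flags = paste(x$flags, collapse = ",")
  )
}

#' Glance at a Falconer heritability fit
#' @param x A `falconer_h2` object.
#' @param ... Unused.
#' @return A one-row tibble with the estimate and quality flags.
#' @export
glance.falconer_h2 <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2, se = x$se,
    out_of_range = "out_of_range" %in% x$flags,
    negative = "negative_h2" %in% x$flags
  )
}
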