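#' Liability-threshold normal deviates for a given prevalence
#'
#' Under the liability-threshold model a binary trait appears when an
#' unobserved standard-normal liability exceeds a threshold. For a
#' prevalence q the threshold deviate is the upper-tail quantile
#' x = Phi^-1(1 - q), and the mean deviate of affected individuals is
#' a = phi(x) / q, the mean of the standard normal truncated above x.
#' These are the quantities classically read off a Falconer table; here
#' they are computed exactly from normal theory.
#'
#' @param q Prevalence fraction(s), each strictly inside (0, 1).
#' @return A tibble with columns `q`, `x`, `a` (one row per input).
#' @examples
#' threshold_deviates(0.5)    # x = 0, a = sqrt(2/pi)
#' threshold_deviates(c(0.25, 0.2322))
#' @export
threshold_deviates <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q <= 0) || any(q >= 1)) {
    rlang::abort("prevalence `q` must lie strictly inside (0, 1)",
                 class = "famline_domain_error")
  }
  x <- stats::qnorm(q, lower.tail = FALSE)
  tibble::tibble(q = q, x = x, a = stats::dnorm(x) / q)
}

#' Threshold deviates from an explicit lookup table
#'
#' Returns the (x, a) pair mapped to a prevalence by a user-supplied table —
#' for example the printed values of a published "simplified Falconer
#' table" — verbatim, bypassing exact computation. Intended to reproduce
#' published analyses bit-for-bit, including any lookup granularity the
#' original table had. There is no interpolation: a prevalence absent from
#' the table is an error, so lookup discrepancies surface instead of being
#' smoothed over.
#'
#' @param q Prevalence fraction(s) to look up.
#' @param table A data frame with columns `q`, `x`, `a`.
#' @param tol Matching tolerance on q; default effectively exact. Set to
#'   half the table's key resolution (e.g. `5e-5` for 4-decimal keys) to
#'   match prevalences quoted at the table's printed precision.
#' @return A tibble with columns `q`, `x`, `a` (the table's values; `q` as
#'   supplied).
#' @examples
#' tab <- tibble::tibble(q = 0.2643, x = 0.681, a = 1.278)
#' deviates_from_table(0.2643, tab)
#' @export
deviates_from_table <- function(q, table, tol = 1e-8) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("q", "x", "a") %in% names(table)))
  if (!is.numeric(q) || anyNA(q)) {
    rlang::abort("`q` must be numeric", class = "famline_domain_error")
  }
  idx <- vapply(q, function(qi) {
    hit <- which(abs(table$q - qi) <= tol)
    if (length(hit) == 0L) {
      rlang::abort(
        sprintf("prevalence %g not present in the deviate table (no interpolation)",
                qi),
        class = "famline_lookup_error"
      )
    }
    hit[[1L]]
  }, integer(1))
  tibble::tibble(q = q, x = table$x[idx], a = table$a[idx])
}

#' Read a deviate lookup table from tab-delimited text
#'
#' @param path TSV file with columns `q`, `x`, `a` (prevalence as a
#'   fraction).
#' @return A tibble usable as the `table` argument of
#'   [deviates_from_table()].
#' @export
read_deviate_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("deviate table not found: %s", path),
                 class = "famline_io_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("q", "x", "a") %in% names(tab)))
  tibble::as_tibble(tab)
}
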