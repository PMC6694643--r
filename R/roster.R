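#' Relative-class vocabulary
#'
#' The closed vocabulary of relative classes used throughout the package,
#' with the degree of relatedness and the genetic similarity coefficient
#' (expected fraction of alleles shared identical by descent) for each
#' class. First-degree relatives (parents, siblings, offspring) share
#' r = 1/2, second-degree relatives (paternal and maternal siblings, i.e.
#' aunts/uncles) r = 1/4, and third-degree relatives (cousins) r = 1/8.
#'
#' The vocabulary is closed on purpose: an unrecognised class label in a
#' roster is an error, never a silently mis-weighted stratum. Use
#' [register_relative_class()] to extend it explicitly.
#'
#' @return A tibble with columns `relative_class`, `degree`, `relatedness_r`.
#' @examples
#' relative_classes()
#' @export
relative_classes <- function() {
  .famline_classes_env$table
}

.famline_default_classes <- tibble::tibble(
  relative_class = c(
    "parent", "sibling", "offspring",
    "paternal_sibling", "maternal_sibling",
    "paternal_cousin", "maternal_cousin"
  ),
  degree = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
  relatedness_r = c(0.5, 0.5, 0.5, 0.25, 0.25, 0.125, 0.125)
)

.famline_classes_env <- new.env(parent = emptyenv())
.famline_classes_env$table <- .famline_default_classes

#' Register an additional relative class
#'
#' Extends the closed relative-class vocabulary with an explicit degree and
#' relatedness coefficient. Registration is deliberate friction: it prevents
#' a typo'd class label from being dropped or mis-weighted silently.
#'
#' @param relative_class Character scalar, the new class label.
#' @param degree Integer degree of relatedness (1, 2 or 3).
#' @param relatedness_r Genetic similarity coefficient; must agree with the
#'   degree (0.5, 0.25, 0.125).
#' @return The updated vocabulary tibble, invisibly.
#' @export
register_relative_class <- function(relative_class, degree, relatedness_r) {
  stopifnot(is.character(relative_class), length(relative_class) == 1L)
  degree <- as.integer(degree)
  expected_r <- c(`1` = 0.5, `2` = 0.25, `3` = 0.125)
  if (!degree %in% 1:3) {
    rlang::abort("`degree` must be 1, 2 or 3.", class = "famline_class_error")
  }
  if (!isTRUE(all.equal(relatedness_r, unname(expected_r[as.character(degree)])))) {
    rlang::abort(
      sprintf("degree %d implies relatedness_r = %s", degree,
              expected_r[as.character(degree)]),
      class = "famline_class_error"
    )
  }
  tab <- .famline_classes_env$table
  if (relative_class %in% tab$relative_class) {
    rlang::abort(sprintf("class '%s' is already registered", relative_class),
                 class = "famline_class_error")
  }
  .famline_classes_env$table <- dplyr::bind_rows(
    tab,
    tibble::tibble(relative_class = relative_class, degree = degree,
                   relatedness_r = relatedness_r)
  )
  invisible(.famline_classes_env$table)
}

#' Reset the relative-class vocabulary to its default
#' @return The default vocabulary tibble, invisibly.
#' @export
reset_relative_classes <- function() {
  .famline_classes_env$table <- .famline_default_classes
  invisible(.famline_default_classes)
}

validate_roster <- function(records, call = rlang::caller_env()) {
  required <- c("family_id", "group", "relative_class", "affected")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    rlang::abort(
      sprintf("roster is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      class = "famline_format_error", call = call
    )
  }
  bad_group <- which(!records$group %in% c("case", "control"))
  if (length(bad_group) > 0L) {
    rlang::abort(
      sprintf("invalid group value(s) at row(s) %s (must be 'case' or 'control')",
              paste(utils::head(bad_group, 5L), collapse = ", ")),
      class = "famline_validation_error", call = call
    )
  }
  known <- relative_classes()$relative_class
  bad_class <- which(!records$relative_class %in% known)
  if (length(bad_class) > 0L) {
    rlang::abort(
      sprintf("unknown relative_class value(s) at row(s) %s: %s",
              paste(utils::head(bad_class, 5L), collapse = ", "),
              paste(unique(records$relative_class[bad_class]), collapse = ", ")),
      class = "famline_validation_error", call = call
    )
  }
  aff <- records$affected
  if (is.logical(aff)) aff <- as.integer(aff)
  if (!is.numeric(aff) || anyNA(aff) || !all(aff %in% c(0L, 1L))) {
    bad <- which(is.na(aff) | !(aff %in% c(0, 1)))
    rlang::abort(
      sprintf("`affected` must be binary 0/1; invalid at row(s) %s",
              paste(utils::head(bad, 5L), collapse = ", ")),
      class = "famline_validation_error", call = call
    )
  }
  records$affected <- as.integer(aff)
  records$family_id <- as.character(records$family_id)
  tibble::as_tibble(records[required])
}

#' Read a family roster from a delimited file
#'
#' A roster holds one row per surveyed relative of one proband family:
#' `family_id`, `group` (`case` or `control`), `relative_class` (one of the
#' closed vocabulary, see [relative_classes()]) and `affected` (0/1, prior
#' clinical diagnosis). Every row is validated; unknown class labels and
#' non-binary affection values are rejected with the offending row numbers.
#'
#' @param path Path to a delimited text file with a header row naming the
#'   four required columns.
#' @param delim Field delimiter, default comma.
#' @return A validated roster tibble (possibly zero rows).
#' @seealso [write_roster()], [prevalence_by_stratum()]
#' @export
read_roster <- function(path, delim = ",") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("roster file not found: %s", path),
                 class = "famline_io_error")
  }
  records <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if ("affected" %in% names(records)) {
    suppressWarnings(records$affected <- as.numeric(records$affected))
  }
  validate_roster(records)
}

#' Write a family roster to CSV
#'
#' The inverse of [read_roster()]: `read_roster(write_roster(x, path))`
#' returns `x` unchanged. `affected` is encoded 0/1.
#'
#' @param records A valid roster tibble.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_roster <- function(records, path) {
  records <- validate_roster(records)
  readr::write_csv(records, path, progress = FALSE)
  invisible(records)
}

#' Construct a sibship table from per-sibship rows
#'
#' A sibship table aggregates, over the households entering the segregation
#' analysis, the quantities the modified-Weinberg estimator needs:
#' T (total siblings), R (total affected siblings), J (households with
#' exactly one affected sibling) and Q (households with exactly two).
#'
#' @param rows A data frame with columns `size` (siblings per household),
#'   `households`, `cases_among_siblings`, `households_single_case` and
#'   optionally `households_two_cases` (see `q_absent`).
#' @param q_absent If `TRUE`, the per-row two-case column is not required and
#'   is set to 0; supply the study-level total via `Q` instead.
#' @param Q Optional study-level total of two-case households, overriding the
#'   per-row sum (used when the source table does not print per-row counts).
#' @return An object of class `sibship_table`: the row tibble with totals
#'   `T`, `R`, `J`, `Q` stored as attributes and accessible via
#'   [sibship_totals()].
#' @examples
#' tab <- sibship_table(data.frame(
#'   size = c(3, 2), households = c(1, 1),
#'   cases_among_siblings = c(2, 1),
#'   households_single_case = c(0, 1),
#'   households_two_cases = c(1, 0)
#' ))
#' sibship_totals(tab)
#' @export
sibship_table <- function(rows, q_absent = FALSE, Q = NULL) {
  rows <- tibble::as_tibble(rows)
  required <- c("size", "households", "cases_among_siblings",
                "households_single_case")
  if (!q_absent) required <- c(required, "households_two_cases")
  missing <- setdiff(required, names(rows))
  if (length(missing) > 0L) {
    rlang::abort(
      sprintf("sibship table is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      class = "famline_format_error"
    )
  }
  if (q_absent && !"households_two_cases" %in% names(rows)) {
    rows$households_two_cases <- 0L
  }
  num_cols <- c(required, "households_two_cases")
  for (col in unique(num_cols)) {
    v <- rows[[col]]
    if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
      rlang::abort(sprintf("column '%s' must hold non-negative integers", col),
                   class = "famline_validation_error")
    }
  }
  if (any(rows$size < 1 & rows$households > 0)) {
    rlang::abort("sibship size must be >= 1", class = "famline_validation_error")
  }
  if (any(rows$cases_among_siblings > rows$size * rows$households)) {
    rlang::abort("cases_among_siblings exceeds size * households in some row",
                 class = "famline_validation_error")
  }
  if (any(rows$households_single_case + rows$households_two_cases >
            rows$households)) {
    rlang::abort("single-case plus two-case households exceed households",
                 class = "famline_validation_error")
  }
  T_tot <- sum(rows$size * rows$households)
  R_tot <- sum(rows$cases_among_siblings)
  J_tot <- sum(rows$households_single_case)
  Q_tot <- if (!is.null(Q)) Q else sum(rows$households_two_cases)
  if (J_tot > R_tot || R_tot > T_tot) {
    rlang::abort(
      sprintf("inconsistent sibship totals: need J <= R <= T, got J=%d R=%d T=%d",
              J_tot, R_tot, T_tot),
      class = "famline_consistency_error"
    )
  }
  structure(rows, class = c("sibship_table", class(rows)),
            T = T_tot, R = R_tot, J = J_tot, Q = Q_tot)
}

#' Construct a sibship table directly from its totals
#'
#' Some published segregation tables print only aggregate totals (or print
#' per-row values too garbled to trust); this constructor accepts the totals
#' directly as a single pseudo-row.
#'
#' @param T_total Total number of siblings.
#' @param R_total Total affected siblings.
#' @param J_total Households with exactly one affected sibling.
#' @param Q_total Households with exactly two affected siblings (needed for
#'   the standard error; default `NA` if unknown).
#' @return A `sibship_table`.
#' @examples
#' sibship_totals(sibship_from_totals(2013, 891, 580, 163))
#' @export
sibship_from_totals <- function(T_total, R_total, J_total, Q_total = NA) {
  if (J_total > R_total || R_total > T_total) {
    rlang::abort(
      sprintf("inconsistent sibship totals: need J <= R <= T, got J=%d R=%d T=%d",
              J_total, R_total, T_total),
      class = "famline_consistency_error"
    )
  }
  rows <- tibble::tibble(
    size = T_total, households = 1L,
    cases_among_siblings = R_total,
    households_single_case = J_total,
    households_two_cases = 0L
  )
  structure(rows, class = c("sibship_table", class(rows)),
            T = T_total, R = R_total, J = J_total,
            Q = if (is.na(Q_total)) NA_integer_ else Q_total)
}

#' Totals of a sibship table
#' @param table A `sibship_table`.
#' @return A one-row tibble with columns `T`, `R`, `J`, `Q`.
#' @export
sibship_totals <- function(table) {
  stopifnot(inherits(table, "sibship_table"))
  tibble::tibble(
    T = attr(table, "T"), R = attr(table, "R"),
    J = attr(table, "J"), Q = attr(table, "Q")
  )
}

#' Read a sibship table from tab-delimited text
#'
#' Expects columns `size`, `households`, `cases_among_siblings`,
#' `households_single_case` and (unless `q_absent`) `households_two_cases`.
#' Totals T, R, J, Q are aggregated and the consistency invariant
#' J <= R <= T enforced.
#'
#' @inheritParams sibship_table
#' @param path Path to the TSV file.
#' @return A `sibship_table`.
#' @export
read_sibship_table <- function(path, q_absent = FALSE, Q = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("sibship file not found: %s", path),
                 class = "famline_io_error")
  }
  rows <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sibship_table(rows, q_absent = q_absent, Q = Q)
}

#' Write a sibship table to tab-delimited text
#' @param table A `sibship_table`.
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_sibship_table <- function(table, path) {
  stopifnot(inherits(table, "sibship_table"))
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(table)
}

#' @export
print.sibship_table <- function(x, ...) {
  tot <- sibship_totals(x)
  cat(sprintf("<sibship_table: %d row(s); T=%d R=%d J=%d Q=%s>\n",
              nrow(x), tot$T, tot$R, tot$J,
              ifelse(is.na(tot$Q), "NA", as.character(tot$Q))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
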