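#' Prevalence of the trait by group and relative stratum
#'
#' Collapses a roster into a prevalence table: for each stratum (relative
#' class, degree of relatedness, or all relatives pooled) the number of
#' relatives, the number affected, and the prevalence q = affected / total.
#' Prevalences are exact rationals of the two counts; rounding happens only
#' at display time.
#'
#' Strata with no relatives are reported with `n_total = 0` and `q = NA`
#' (flagged in `empty`), never as a silent 0/0.
#'
#' @param records A roster tibble (see [read_roster()]).
#' @param level Stratification level: `"class"` (the seven relative classes),
#'   `"degree"` (first/second/third degree) or `"all"` (one pooled stratum).
#' @param by_group If `TRUE` (default) strata are computed separately for the
#'   case-family and control-family arms; if `FALSE` the arms are pooled.
#' @return A tibble of class `prevalence_table` with columns `group` (unless
#'   pooled), `stratum`, `n_total`, `n_affected`, `q`, `empty`.
#' @examples
#' roster <- tibble::tibble(
#'   family_id = c("f1", "f1", "f2"), group = c("case", "case", "control"),
#'   relative_class = c("parent", "sibling", "parent"),
#'   affected = c(1L, 0L, 0L)
#' )
#' prevalence_by_stratum(roster, level = "degree")
#' @export
prevalence_by_stratum <- function(records,
                                  level = c("class", "degree", "all"),
                                  by_group = TRUE) {
  level <- match.arg(level)
  records <- validate_roster(records)
  if (nrow(records) == 0L) {
    rlang::abort("roster is empty: no relatives to aggregate",
                 class = "famline_empty_error")
  }
  classes <- relative_classes()
  records <- dplyr::left_join(records, classes, by = "relative_class")
  records$stratum <- switch(
    level,
    class  = records$relative_class,
    degree = paste0("degree_", records$degree),
    all    = "all"
  )
  stratum_levels <- switch(
    level,
    class  = classes$relative_class,
    degree = paste0("degree_", sort(unique(classes$degree))),
    all    = "all"
  )
  group_vars <- if (by_group) c("group", "stratum") else "stratum"
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_affected = sum(.data$affected),
      .groups = "drop"
    )
  # report empty strata explicitly rather than dropping them
  frame <- if (by_group) {
    tidyr::expand_grid(group = c("control", "case"), stratum = stratum_levels)
  } else {
    tibble::tibble(stratum = stratum_levels)
  }
  out <- dplyr::left_join(frame, out, by = group_vars) |>
    dplyr::mutate(
      n_total = dplyr::coalesce(.data$n_total, 0L),
      n_affected = dplyr::coalesce(.data$n_affected, 0L),
      q = dplyr::if_else(.data$n_total > 0L,
                         .data$n_affected / .data$n_total, NA_real_),
      empty = .data$n_total == 0L
    )
  structure(out, class = c("prevalence_table", class(out)),
            level = level, by_group = by_group)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' The uncorrected Pearson statistic N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)),
#' optionally with the Yates continuity correction (|ad - bc| reduced by
#' N/2, floored at zero). The p-value comes from the chi-square distribution
#' with one degree of freedom.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = affected / not.
#' @param yates Apply the Yates continuity correction?
#' @return A one-row tibble with `statistic` and `p_value`.
#' @examples
#' pearson_chi2_2x2(50, 50, 50, 50)   # statistic 0, p 1
#' pearson_chi2_2x2(10, 0, 0, 10)     # perfect association
#' @export
pearson_chi2_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) {
    rlang::abort("cell counts must be non-negative",
                 class = "famline_validation_error")
  }
  N <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    rlang::abort("chi-square test undefined: a table margin is zero",
                 class = "famline_test_error")
  }
  diff <- abs(a * d - b * c)
  if (yates) diff <- max(0, diff - N / 2)
  stat <- N * diff^2 / prod(margins)
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare case-arm and control-arm prevalence per stratum
#'
#' Reshapes a by-group prevalence table to one row per stratum with the two
#' arms side by side and a Pearson chi-square test (affected vs unaffected by
#' arm) per stratum. This is the usual familial-aggregation contrast: a
#' higher prevalence among relatives of cases than relatives of controls.
#'
#' @param prevalence A `prevalence_table` computed with `by_group = TRUE`.
#' @param yates Apply the Yates continuity correction?
#' @return A tibble with one row per stratum: counts and prevalence for each
#'   arm, `statistic`, `p_value`.
#' @export
compare_groups <- function(prevalence, yates = FALSE) {
  stopifnot(inherits(prevalence, "prevalence_table"))
  if (!isTRUE(attr(prevalence, "by_group"))) {
    rlang::abort("compare_groups() needs a by-group prevalence table",
                 class = "famline_validation_error")
  }
  wide <- tibble::as_tibble(prevalence) |>
    tidyr::pivot_wider(
      id_cols = "stratum",
      names_from = "group",
      values_from = c("n_total", "n_affected", "q")
    )
  tests <- purrr::pmap(
    list(wide$n_affected_control, wide$n_total_control,
         wide$n_affected_case, wide$n_total_case),
    function(d0, n0, d1, n1) {
      if (n0 == 0L || n1 == 0L) {
        return(tibble::tibble(statistic = NA_real_, p_value = NA_real_))
      }
      pearson_chi2_2x2(d0, n0 - d0, d1, n1 - d1, yates = yates)
    }
  ) |> purrr::list_rbind()
  dplyr::bind_cols(wide, tests)
}

#' McNemar test for matched-pair discordance
#'
#' The matched-pair variant of the association test, provided for designs
#' where pair identifiers survive aggregation. Off the main analysis path:
#' class-level prevalence tables carry no pair structure.
#'
#' @param b,c Discordant-pair counts (case-exposed only, control-exposed only).
#' @param correct Apply the continuity correction?
#' @return A one-row tibble with `statistic` and `p_value`.
#' @export
mcnemar_2x2 <- function(b, c, correct = TRUE) {
  if (b < 0 || c < 0) {
    rlang::abort("discordant counts must be non-negative",
                 class = "famline_validation_error")
  }
  if (b + c == 0) {
    rlang::abort("McNemar test undefined: no discordant pairs",
                 class = "famline_test_error")
  }
  res <- stats::mcnemar.test(matrix(c(0, c, b, 0), 2), correct = correct)
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = unname(res$p.value))
}

#' Mean number of surveyed relatives per family
#'
#' Total surveyed relatives divided by the number of distinct families
#' (probands themselves are not roster rows and so are excluded).
#'
#' @param records A roster tibble.
#' @param by_group If `TRUE`, one mean per arm; otherwise a single mean.
#' @return A tibble with `n_relatives`, `n_families`, `mean_size` (and
#'   `group` if `by_group`).
#' @export
mean_family_size <- function(records, by_group = FALSE) {
  records <- validate_roster(records)
  if (by_group) {
    records |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n_relatives = dplyr::n(),
        n_families = dplyr::n_distinct(.data$family_id),
        mean_size = .data$n_relatives / .data$n_families,
        .groups = "drop"
      )
  } else {
    records |>
      dplyr::summarise(
        n_relatives = dplyr::n(),
        n_families = dplyr::n_distinct(.data$family_id),
        mean_size = .data$n_relatives / .data$n_families
      )
  }
}

#' Expand aggregate stratum counts into an individual-level roster
#'
#' Reconstructs a roster from per-(group, class) totals: `n_affected` rows
#' with `affected = 1` and the rest with 0 per stratum, assigned round-robin
#' to `n_families` synthetic family ids per arm. Stratum counts and the
#' relatives-per-family mean are preserved exactly; the within-family
#' arrangement is synthetic (aggregate tables do not record it).
#'
#' @param counts A data frame with columns `group`, `relative_class`,
#'   `n_total`, `n_affected`.
#' @param n_families Families per arm used for synthetic ids.
#' @return A roster tibble.
#' @export
roster_from_counts <- function(counts, n_families = 342L) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("group", "relative_class", "n_total", "n_affected") %in%
                  names(counts)))
  rows <- purrr::pmap(
    counts,
    function(group, relative_class, n_total, n_affected, ...) {
      tibble::tibble(
        group = group,
        relative_class = relative_class,
        affected = c(rep(1L, n_affected), rep(0L, n_total - n_affected))
      )
    }
  ) |> purrr::list_rbind()
  roster <- rows |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      family_id = sprintf("%s_%03d", .data$group,
                          (dplyr::row_number() - 1L) %% n_families + 1L)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("family_id", "group", "relative_class", "affected")
  validate_roster(roster)
}
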