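test_that("relative-class vocabulary ties class, degree and relatedness together", {
  classes <- relative_classes()
  expect_setequal(
    classes$relative_class,
    c("parent", "sibling", "offspring", "paternal_sibling",
      "maternal_sibling", "paternal_cousin", "maternal_cousin")
  )
  expect_equal(
    classes$relatedness_r,
    c(`1` = 0.5, `2` = 0.25, `3` = 0.125)[as.character(classes$degree)],
    ignore_attr = TRUE
  )
})

test_that("a one-record-per-class file maps onto the expected degrees", {
  path <- withr::local_tempfile(fileext = ".csv")
  classes <- relative_classes()$relative_class
  writeLines(c(
    "family_id,group,relative_class,affected",
    sprintf("f1,case,%s,0", classes)
  ), path)
  roster <- read_roster(path)
  expect_equal(nrow(roster), 7L)
  degrees <- relative_classes()$degree[
    match(roster$relative_class, relative_classes()$relative_class)]
  expect_equal(sort(degrees), c(1L, 1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("an empty file with a valid header yields an empty roster", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("family_id,group,relative_class,affected", path)
  expect_equal(nrow(read_roster(path)), 0L)
})

test_that("malformed rosters fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("family_id,group,relative_class", "f1,case,parent"), path)
  expect_error(read_roster(path), "affected", class = "famline_format_error")

  writeLines(c("family_id,group,relative_class,affected",
               "f1,case,parent,1", "f1,case,stepparent,0"), path)
  expect_error(read_roster(path), "stepparent",
               class = "famline_validation_error")

  writeLines(c("family_id,group,relative_class,affected",
               "f1,case,parent,2"), path)
  expect_error(read_roster(path), "binary",
               class = "famline_validation_error")

  writeLines(c("family_id,group,relative_class,affected",
               "f1,neither,parent,1"), path)
  expect_error(read_roster(path), "group",
               class = "famline_validation_error")
})

test_that("write then read is the identity on random rosters", {
  for (seed in 1:5) {
    roster <- random_roster(100, seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_roster(roster, path)
    expect_equal(read_roster(path), roster)
  }
  # degenerate rosters round-trip too
  all_aff <- random_roster(20, 99) |> dplyr::mutate(affected = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_roster(all_aff, path)
  back <- read_roster(path)
  expect_true(all(back$affected == 1L))
  empty <- random_roster(5, 1)[0, ]
  write_roster(empty, path)
  expect_equal(nrow(read_roster(path)), 0L)
})

test_that("sibship aggregation produces the study totals", {
  # totals of the published segregation table
  tab <- sibship_from_totals(2013L, 891L, 580L, 163L)
  expect_equal(sibship_totals(tab),
               tibble::tibble(T = 2013L, R = 891L, J = 580L, Q = 163L))
  # size-1 sibships: every case is its own single-case household
  single <- sibship_table(tibble::tibble(
    size = 1L, households = 167L, cases_among_siblings = 167L,
    households_single_case = 167L, households_two_cases = 0L
  ))
  tot <- sibship_totals(single)
  expect_equal(c(tot$T, tot$R, tot$J), c(167L, 167L, 167L))
  # hand-summed two-row table
  two <- sibship_table(tibble::tibble(
    size = c(3L, 2L), households = c(1L, 1L),
    cases_among_siblings = c(2L, 1L),
    households_single_case = c(0L, 1L),
    households_two_cases = c(1L, 0L)
  ))
  expect_equal(sibship_totals(two),
               tibble::tibble(T = 5L, R = 3L, J = 1L, Q = 1L))
})

test_that("sibship totals are invariant to row order and row splitting", {
  set.seed(7)
  rows <- tibble::tibble(
    size = sample(1:5, 8, replace = TRUE),
    households = sample(1:20, 8, replace = TRUE)
  ) |>
    dplyr::mutate(
      cases_among_siblings = pmin(size * households,
                                  sample(0:30, 8, replace = TRUE)),
      households_single_case = pmin(households, cases_among_siblings),
      households_two_cases = pmax(
        0L, pmin(households - households_single_case,
                 (cases_among_siblings - households_single_case) %/% 2L))
    )
  base <- sibship_totals(sibship_table(rows))
  shuffled <- sibship_totals(sibship_table(rows[sample(nrow(rows)), ]))
  expect_equal(shuffled, base)
  # padding with empty rows leaves totals unchanged; stacking doubles them
  padded <- dplyr::bind_rows(
    rows,
    tibble::tibble(size = 4L, households = 0L, cases_among_siblings = 0L,
                   households_single_case = 0L, households_two_cases = 0L)
  )
  expect_equal(sibship_totals(sibship_table(padded)), base)
  doubled <- sibship_totals(sibship_table(dplyr::bind_rows(rows, rows)))
  expect_equal(doubled, dplyr::mutate(base, dplyr::across(dplyr::everything(),
                                                          ~ .x * 2L)))
})

test_that("sibship loader enforces the consistency invariant and q_absent mode", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("size\thouseholds\tcases_among_siblings\thouseholds_single_case\thouseholds_two_cases",
               "2\t10\t5\t7\t0"), path)  # J=7 > R=5
  expect_error(read_sibship_table(path), class = "famline_consistency_error")

  tab <- read_sibship_table(fixture_path("sibships_example.tsv"),
                            q_absent = TRUE, Q = 163L)
  tot <- sibship_totals(tab)
  expect_equal(c(tot$T, tot$R, tot$J, tot$Q), c(493L, 321L, 296L, 163L))
})

test_that("sibship tables round-trip through TSV", {
  tab <- sibship_table(tibble::tibble(
    size = c(1L, 2L, 3L), households = c(5L, 4L, 3L),
    cases_among_siblings = c(5L, 6L, 4L),
    households_single_case = c(5L, 2L, 2L),
    households_two_cases = c(0L, 2L, 1L)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sibship_table(tab, path)
  expect_equal(sibship_totals(read_sibship_table(path)), sibship_totals(tab))
})

test_that("vocabulary extension requires a consistent degree and r", {
  withr::defer(reset_relative_classes())
  expect_error(register_relative_class("half_sibling", 2, 0.5),
               class = "famline_class_error")
  register_relative_class("half_sibling", 2, 0.25)
  expect_true("half_sibling" %in% relative_classes()$relative_class)
  reset_relative_classes()
  expect_false("half_sibling" %in% relative_classes()$relative_class)
})
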