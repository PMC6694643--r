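test_that("the same seed reproduces the study byte-for-byte", {
  a <- simulate_study(n_case = 50, n_control = 50, h2 = 0.5, seed = 7)
  b <- simulate_study(n_case = 50, n_control = 50, h2 = 0.5, seed = 7)
  expect_identical(a$roster, b$roster)
  expect_identical(sibship_totals(a$sibships), sibship_totals(b$sibships))
  c_ <- simulate_study(n_case = 50, n_control = 50, h2 = 0.5, seed = 8)
  expect_false(identical(a$roster, c_$roster))
})

test_that("per-family substreams keep existing families stable as the study grows", {
  small <- simulate_study(n_case = 30, n_control = 0, h2 = 0.5, seed = 3)
  big <- simulate_study(n_case = 60, n_control = 0, h2 = 0.5, seed = 3)
  n <- nrow(small$roster)
  expect_identical(big$roster$affected[seq_len(n)], small$roster$affected)
})

test_that("probands honour the arm definitions in the derived sibships", {
  st <- simulate_study(n_case = 200, n_control = 200, h2 = 0.4, seed = 2)
  per_family <- st$roster |>
    dplyr::group_by(family_id, group) |>
    dplyr::summarise(aff_sibs = sum(affected[relative_class == "sibling"]),
                     .groups = "drop")
  tot <- sibship_totals(st$sibships)
  # every case proband is an affected sibship member, no control proband is
  expect_equal(tot$R, sum(per_family$aff_sibs) + 200L)
  expect_equal(tot$T, nrow(per_family) * (1L + 2L))  # 2 siblings + proband
})

test_that("with h2 = 0 both arms revert to the population prevalence", {
  K <- 0.2322
  st <- simulate_study(n_case = 8000, n_control = 8000, K = K, h2 = 0,
                       seed = 11)
  prev <- prevalence_by_stratum(st$roster, "all")
  mc_se <- sqrt(K * (1 - K) / prev$n_total)
  expect_true(all(abs(prev$q - K) < 3 * mc_se))
})

test_that("simulated prevalences agree with the quadrature companion", {
  K <- 0.2322; h2 <- 0.5
  st <- simulate_study(n_case = 15000, n_control = 15000, K = K, h2 = h2,
                       seed = 5)
  prev <- prevalence_by_stratum(st$roster, "degree")
  r_by_deg <- c(degree_1 = 0.5, degree_2 = 0.25, degree_3 = 0.125)
  for (i in seq_len(nrow(prev))) {
    expected <- expected_relative_prevalence(
      K, h2, r_by_deg[[prev$stratum[i]]], arm = prev$group[i])
    mc_se <- sqrt(expected * (1 - expected) / prev$n_total[i])
    expect_lt(abs(prev$q[i] - expected), 3.5 * mc_se)
  }
})

test_that("extreme-heritability case-arm prevalence matches the quadrature oracle", {
  # h2 = 1, K = 0.5, parents (r = 0.5): strong proband-relative coupling
  st <- simulate_study(n_case = 10000, n_control = 0, K = 0.5, h2 = 1,
                       seed = 13,
                       structure = c(parent = 2L))
  prev <- prevalence_by_stratum(st$roster, "class")
  obs <- prev$q[prev$group == "case" & prev$stratum == "parent"]
  expected <- expected_relative_prevalence(0.5, 1, 0.5, "case")
  mc_se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(obs - expected), 3.5 * mc_se)
})

test_that("the closed-form prevalence has the right limits and ordering", {
  K <- 0.2322
  expect_equal(expected_relative_prevalence(K, 0, 0.5, "case"), K)
  expect_equal(expected_relative_prevalence(K, 0, 0.5, "control"), K)
  # monotone in rho: closer relatives of cases are at higher risk
  expect_gt(expected_relative_prevalence(K, 0.6, 0.5, "case"),
            expected_relative_prevalence(K, 0.6, 0.25, "case"))
  # case arm above K, control arm below, for any positive h2
  for (h2 in c(0.2, 0.5, 0.8)) {
    expect_gt(expected_relative_prevalence(K, h2, 0.5, "case"), K)
    expect_lt(expected_relative_prevalence(K, h2, 0.5, "control"), K)
  }
})

test_that("simulated studies show the familial-aggregation orderings", {
  st <- simulate_study(n_case = 6000, n_control = 6000, h2 = 0.6, seed = 21)
  prev <- tibble::as_tibble(prevalence_by_stratum(st$roster, "degree"))
  wide <- tidyr::pivot_wider(prev, id_cols = "stratum",
                             names_from = "group", values_from = "q")
  # case arm exceeds control arm in every degree
  expect_true(all(wide$case > wide$control))
  # case-arm prevalence declines with degree of relatedness
  q_case <- wide$case[order(wide$stratum)]
  expect_true(all(diff(q_case) < 0))
})

test_that("the joint-liability family model behaves like the conditional one at the margins", {
  cond <- simulate_study(n_case = 4000, n_control = 4000, h2 = 0.5, seed = 9,
                         relative_model = "conditional_on_proband")
  mvn <- simulate_study(n_case = 4000, n_control = 4000, h2 = 0.5, seed = 9,
                        relative_model = "full_mvn")
  pc <- prevalence_by_stratum(cond$roster, "degree")
  pm <- prevalence_by_stratum(mvn$roster, "degree")
  # marginal proband-relative association is the same in both models
  mc_se <- sqrt(pc$q * (1 - pc$q) / pc$n_total)
  expect_true(all(abs(pc$q - pm$q) < 4 * mc_se))
})

test_that("sibship simulation honours the ascertainment definitions", {
  # complete ascertainment with pi = 1: every affected count >= 1 enters
  tab <- simulate_sibships(2000, size = 3, K = 0.3, h2 = 0,
                           ascertainment = "complete", pi = 1, seed = 4)
  tot <- sibship_totals(tab)
  expect_equal(tot$T, sum(tab$size * tab$households))
  expect_gte(tot$R, tot$J)
  # size-1 sibships force R = J, hence p = 0
  tab1 <- simulate_sibships(1000, size = 1, K = 0.3, h2 = 0, seed = 6)
  expect_equal(segregation_ratio(tab1), 0)
  expect_error(
    simulate_sibships(100, size = 3, K = 0.3, ascertainment = "single",
                      pi = 0.5, seed = 1),
    class = "famline_domain_error"
  )
})

test_that("ascertained pattern frequencies match complete enumeration (size 2)", {
  theta <- 0.3
  n <- 20000
  tab <- simulate_sibships(n, size = 2, K = theta, h2 = 0,
                           ascertainment = "complete", pi = 1, seed = 17)
  tot <- sibship_totals(tab)
  n_asc <- sum(tab$households)
  o <- oracle_sibship_expectation(2, theta, "complete", 1)
  # ascertainment rate
  expect_lt(abs(n_asc / n - o$p_ascertained),
            3 * sqrt(o$p_ascertained * (1 - o$p_ascertained) / n))
  # per-sibship expected affected and single-case counts
  expect_lt(abs(tot$R / n_asc - o$ER), 3 * sqrt(0.25 / n_asc) + 0.01)
  expect_lt(abs(tot$J / n_asc - o$EJ),
            3 * sqrt(o$EJ * (1 - o$EJ) / n_asc))
  expect_lt(abs(tot$Q / n_asc - o$EQ),
            3 * sqrt(o$EQ * (1 - o$EQ) / n_asc))
})
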