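#' Default per-family relative structure
#'
#' Named counts of surveyed relatives per proband family, chosen to mirror
#' the degree-level mean family sizes of a typical nuclear-family survey
#' (about 5 first-degree, 4.5 second-degree and 3 third-degree relatives
#' per family): 2 parents, 2 siblings, 1 offspring, 2 + 2 aunts/uncles,
#' 1 + 2 cousins.
#'
#' @return A named integer vector keyed by relative class.
#' @export
default_structure <- function() {
  c(parent = 2L, sibling = 2L, offspring = 1L,
    paternal_sibling = 2L, maternal_sibling = 2L,
    paternal_cousin = 1L, maternal_cousin = 2L)
}

# Pairwise relatedness among family members (proband first) for the
# full_mvn model. Parent slot 1 is the father, slot 2 the mother; cousins
# are children of the same-side aunts/uncles. Pairs not covered by a rule
# are treated as unrelated.
relatedness_matrix <- function(structure) {
  classes <- rep(names(structure), times = structure)
  members <- c("proband", classes)
  n <- length(members)
  # disambiguate the two parents
  parent_idx <- which(members == "parent")
  if (length(parent_idx) >= 1) members[parent_idx[1]] <- "father"
  if (length(parent_idx) >= 2) members[parent_idx[2]] <- "mother"
  pair_r <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    switch(
      key,
      "father|proband" = , "mother|proband" = , "proband|sibling" = ,
      "offspring|proband" = 0.5,
      "paternal_sibling|proband" = , "maternal_sibling|proband" = 0.25,
      "paternal_cousin|proband" = , "maternal_cousin|proband" = 0.125,
      "father|mother" = 0,
      "father|sibling" = , "mother|sibling" = 0.5,
      "sibling|sibling" = 0.5,
      "father|offspring" = , "mother|offspring" = 0.25,
      "offspring|sibling" = 0.25,
      "offspring|offspring" = 0.5,
      "father|paternal_sibling" = , "maternal_sibling|mother" = 0.5,
      "maternal_sibling|paternal_sibling" = 0,
      "paternal_sibling|paternal_sibling" = ,
      "maternal_sibling|maternal_sibling" = 0.5,
      "paternal_sibling|sibling" = , "maternal_sibling|sibling" = 0.25,
      "maternal_sibling|offspring" = , "offspring|paternal_sibling" = 0.125,
      "father|paternal_cousin" = , "maternal_cousin|mother" = 0.25,
      "paternal_cousin|paternal_sibling" = ,
      "maternal_cousin|maternal_sibling" = 0.25,
      "paternal_cousin|sibling" = , "maternal_cousin|sibling" = 0.125,
      "paternal_cousin|paternal_cousin" = ,
      "maternal_cousin|maternal_cousin" = 0.25,
      0
    )
  }
  R <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      R[i, j] <- R[j, i] <- pair_r(members[i], members[j])
    }
  }
  dimnames(R) <- list(members, members)
  R
}

draw_truncated_probands <- function(u, t, arm, K) {
  # inverse-CDF draws from the standard normal truncated at t
  if (arm == "case") stats::qnorm(1 - K * u) else stats::qnorm((1 - K) * u)
}

family_seed <- function(seed, index) {
  # deterministic per-family substream seed below 2^31
  (as.double(seed) * 1009 + index * 97) %% 2147483647
}

#' Simulate a matched case-control family study under the liability model
#'
#' Generates a roster of relatives for `n_case` families ascertained through
#' an affected proband and `n_control` families through an unaffected
#' proband, under the liability-threshold model: liabilities are standard
#' normal, the trait threshold t is the upper-tail quantile at population
#' prevalence `K`, and a relative with genetic similarity r to the proband
#' has liability correlation rho = r * `h2` with the proband.
#'
#' Two relative models are available. `"conditional_on_proband"` (default)
#' draws each relative from N(rho * L_p, 1 - rho^2) independently given the
#' proband — exactly the regression model under which the Falconer estimator
#' is unbiased, which makes parameter-recovery tests sharp.  `"full_mvn"`
#' draws each family jointly with pairwise liability correlation
#' r_ij * `h2` from a fixed within-family relatedness matrix, so that e.g.
#' siblings are also correlated with each other, not only with the proband.
#'
#' One root seed derives an independent substream per family, so changing
#' the family structure or count does not perturb other families' draws.
#' Probands are not roster rows (a roster records surveyed relatives).
#'
#' @param n_case,n_control Families per arm.
#' @param K Population prevalence in (0, 1).
#' @param h2 True heritability of liability in \[0, 1\].
#' @param structure Named counts of relatives per family (see
#'   [default_structure()]).
#' @param seed Root seed; fixes the entire output stream.
#' @param relative_model `"conditional_on_proband"` or `"full_mvn"`.
#' @return An object of class `simulated_study`: a list with the `roster`
#'   tibble, a `sibships` table derived from the roster (see
#'   [derive_sibships()]), and `truth` echoing the configuration.
#' @examples
#' study <- simulate_study(n_case = 200, n_control = 200, h2 = 0.5, seed = 1)
#' prevalence_by_stratum(study$roster, level = "degree")
#' @export
simulate_study <- function(n_case = 342L, n_control = 342L,
                           K = 0.2322, h2 = 0.5,
                           structure = default_structure(),
                           seed = 1L,
                           relative_model = c("conditional_on_proband",
                                              "full_mvn")) {
  relative_model <- match.arg(relative_model)
  if (K <= 0 || K >= 1) {
    rlang::abort("K must lie strictly inside (0, 1)",
                 class = "famline_domain_error")
  }
  if (h2 < 0 || h2 > 1) {
    rlang::abort("h2 must lie in [0, 1]", class = "famline_domain_error")
  }
  known <- relative_classes()
  if (!all(names(structure) %in% known$relative_class)) {
    rlang::abort("structure names must be registered relative classes",
                 class = "famline_validation_error")
  }
  structure <- structure[structure > 0]
  classes <- rep(names(structure), times = structure)
  r_vec <- known$relatedness_r[match(classes, known$relative_class)]
  n_rel <- length(classes)
  t_thr <- stats::qnorm(K, lower.tail = FALSE)

  cond_transform <- NULL
  if (relative_model == "full_mvn") {
    R <- relatedness_matrix(structure)
    Sigma <- h2 * R + (1 - h2) * diag(nrow(R))
    rel_idx <- 2:nrow(Sigma)
    rho_vec <- Sigma[rel_idx, 1]                 # = h2 * r_vec
    cond_cov <- Sigma[rel_idx, rel_idx] - tcrossprod(rho_vec)
    ch <- tryCatch(chol(cond_cov), error = function(e) {
      rlang::abort(
        "full_mvn relatedness matrix is not positive semi-definite",
        class = "famline_config_error"
      )
    })
    cond_transform <- list(rho = rho_vec, chol_t = t(ch))
  }

  arms <- c(rep("case", n_case), rep("control", n_control))
  n_fam <- length(arms)
  u <- numeric(n_fam)
  Z <- matrix(0, nrow = n_rel, ncol = n_fam)
  for (i in seq_len(n_fam)) {
    set.seed(family_seed(seed, i))
    u[i] <- stats::runif(1)
    Z[, i] <- stats::rnorm(n_rel)
  }
  Lp <- ifelse(arms == "case",
               stats::qnorm(1 - K * u), stats::qnorm((1 - K) * u))

  if (relative_model == "conditional_on_proband") {
    rho <- r_vec * h2
    L <- outer(rho, Lp) + sqrt(1 - rho^2) * Z
  } else {
    L <- outer(cond_transform$rho, Lp) + cond_transform$chol_t %*% Z
  }

  roster <- tibble::tibble(
    family_id = rep(sprintf("%s_%05d", arms, seq_len(n_fam)), each = n_rel),
    group = rep(arms, each = n_rel),
    relative_class = rep(classes, times = n_fam),
    affected = as.integer(as.vector(L) > t_thr)
  )
  truth <- list(K = K, h2 = h2, n_case = n_case, n_control = n_control,
                structure = structure, seed = seed,
                relative_model = relative_model, threshold = t_thr)
  study <- list(roster = roster, sibships = derive_sibships(roster),
                truth = truth)
  class(study) <- "simulated_study"
  study
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d case + %d control families, K = %.4f, true h2 = %.2f (%s), seed %s\n",
    x$truth$n_case, x$truth$n_control, x$truth$K, x$truth$h2,
    x$truth$relative_model, format(x$truth$seed)))
  cat(sprintf("  roster: %d relatives; sibships: T=%d R=%d J=%d Q=%d\n",
              nrow(x$roster), attr(x$sibships, "T"), attr(x$sibships, "R"),
              attr(x$sibships, "J"), attr(x$sibships, "Q")))
  invisible(x)
}

#' Derive a sibship table from a roster
#'
#' Builds the segregation-analysis sibship table from the roster's sibling
#' records: each family contributes one sibship consisting of the proband
#' (affected in the case arm, unaffected in the control arm) plus the
#' surveyed siblings. Families with no sibling rows contribute a sibship of
#' size one (the proband alone).
#'
#' @param roster A roster tibble.
#' @return A `sibship_table` with one row per observed (size, affected
#'   count) pattern.
#' @export
derive_sibships <- function(roster) {
  roster <- validate_roster(roster)
  fams <- roster |>
    dplyr::group_by(.data$family_id, .data$group) |>
    dplyr::summarise(
      n_sibs = sum(.data$relative_class == "sibling"),
      aff_sibs = sum(.data$affected[.data$relative_class == "sibling"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      size = .data$n_sibs + 1L,
      affected = .data$aff_sibs + as.integer(.data$group == "case")
    )
  rows <- fams |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      households = dplyr::n(),
      cases_among_siblings = sum(.data$affected),
      households_single_case = sum(.data$affected == 1L),
      households_two_cases = sum(.data$affected == 2L),
      .groups = "drop"
    )
  sibship_table(rows)
}

#' Expected relative prevalence under the liability model
#'
#' Closed-form companion to [simulate_study()]: the probability that a
#' relative with liability correlation rho = r * h2 to the proband is
#' affected, given that the proband is affected (case arm) or unaffected
#' (control arm). Computed by one-dimensional quadrature of
#' Phi((rho l - t) / sqrt(1 - rho^2)) against the standard normal density
#' truncated above (case) or below (control) the threshold t.
#'
#' @param K Population prevalence.
#' @param h2 Heritability of liability.
#' @param r Genetic similarity coefficient.
#' @param arm `"case"` or `"control"`.
#' @return The expected prevalence among such relatives.
#' @examples
#' expected_relative_prevalence(0.2322, 0.5, 0.5, "case")
#' @export
expected_relative_prevalence <- function(K, h2, r,
                                         arm = c("case", "control")) {
  arm <- match.arg(arm)
  if (K <= 0 || K >= 1) {
    rlang::abort("K must lie strictly inside (0, 1)",
                 class = "famline_domain_error")
  }
  rho <- r * h2
  if (rho == 0) return(K)
  t_thr <- stats::qnorm(K, lower.tail = FALSE)
  integrand <- function(l) {
    stats::pnorm((rho * l - t_thr) / sqrt(1 - rho^2)) * stats::dnorm(l)
  }
  if (arm == "case") {
    stats::integrate(integrand, lower = t_thr, upper = Inf,
                     rel.tol = 1e-10)$value / K
  } else {
    stats::integrate(integrand, lower = -Inf, upper = t_thr,
                     rel.tol = 1e-10)$value / (1 - K)
  }
}

#' Simulate ascertained sibships for segregation analysis
#'
#' Generates sibships under the liability model (siblings pairwise
#' liability-correlated at 0.5 * `h2` via a shared family factor; with
#' `h2 = 0` each sibling is an independent Bernoulli(K) draw) and applies
#' an ascertainment rule:
#'
#' * `"complete"`: each affected sibling is independently detected with
#'   probability `pi`; the sibship enters the table if at least one is
#'   detected (`pi = 1`: every sibship with an affected member enters).
#' * `"single"`: the small-`pi` limit — a sibship enters with probability
#'   `pi` times its affected count (so entry is proportional to the number
#'   of affected members and carries exactly one proband). Requires
#'   `pi * max(size) <= 1`.
#'
#' @param n_sibships Number of sibships generated before ascertainment.
#' @param size Sibship size(s); recycled across sibships.
#' @param K Population prevalence (per-sibling risk when `h2 = 0`).
#' @param h2 Heritability of liability controlling sibling-sibling
#'   correlation.
#' @param ascertainment `"complete"` or `"single"`.
#' @param pi Per-affected ascertainment probability in (0, 1].
#' @param seed Seed for the draw.
#' @return A `sibship_table` over the ascertained sibships.
#' @examples
#' tab <- simulate_sibships(500, size = 3, K = 0.25, h2 = 0, seed = 2)
#' segregation_ratio(tab)
#' @export
simulate_sibships <- function(n_sibships, size, K = 0.2322, h2 = 0,
                              ascertainment = c("complete", "single"),
                              pi = 1, seed = 1L) {
  ascertainment <- match.arg(ascertainment)
  if (pi <= 0 || pi > 1) {
    rlang::abort("pi must lie in (0, 1]", class = "famline_domain_error")
  }
  sizes <- rep_len(as.integer(size), n_sibships)
  if (ascertainment == "single" && pi * max(sizes) > 1) {
    rlang::abort("single ascertainment needs pi * max(size) <= 1",
                 class = "famline_domain_error")
  }
  t_thr <- stats::qnorm(K, lower.tail = FALSE)
  rho_s <- 0.5 * h2
  set.seed(seed)
  aff <- vapply(sizes, function(s) {
    f <- stats::rnorm(1)
    l <- sqrt(rho_s) * f + sqrt(1 - rho_s) * stats::rnorm(s)
    sum(l > t_thr)
  }, integer(1))
  enter <- if (ascertainment == "complete") {
    stats::runif(n_sibships) < 1 - (1 - pi)^aff
  } else {
    stats::runif(n_sibships) < pi * aff
  }
  keep <- tibble::tibble(size = sizes[enter], affected = aff[enter])
  if (nrow(keep) == 0L) {
    rlang::abort("no sibships ascertained; increase n_sibships or pi",
                 class = "famline_empty_error")
  }
  rows <- keep |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      households = dplyr::n(),
      cases_among_siblings = sum(.data$affected),
      households_single_case = sum(.data$affected == 1L),
      households_two_cases = sum(.data$affected == 2L),
      .groups = "drop"
    )
  sibship_table(rows)
}
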