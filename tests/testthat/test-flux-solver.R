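test_that("the LP has one split-variable pair per reaction plus the growth variable", {
  cm <- build_community(list(toy_producer("S1")), 1)
  lp <- formulate_pfba(cm)
  expect_length(lp$var_ids, 2L * nrow(cm$reactions) + 1L)
  expect_error(formulate_pfba(cm, parsimony_coef = -1), "non-negative")
})

test_that("the toy producer solves to the hand-derived optimum", {
  cm <- build_community(list(toy_producer("S1")), 1)
  sol <- solve_pfba(formulate_pfba(cm))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$mu, 10, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes["EX_but"]), 10, tolerance = 1e-6)
  # five reactions each carrying |flux| 10 under a 1e-5 penalty
  expect_equal(sol$objective, 10 - 1e-5 * 50, tolerance = 1e-6)
  expect_equal(butyrate_rate(sol), 1, tolerance = 1e-6)
})

test_that("closing the carbon source yields zero growth, not an error", {
  s1 <- toy_producer("S1")
  s1$reactions$lower_bound[s1$reactions$id == "EX_glc"] <- 0
  cm <- build_community(list(s1), 1)
  sol <- solve_pfba(formulate_pfba(cm))
  expect_equal(sol$status, "zero_growth")
  expect_message(r <- butyrate_rate(sol), "undefined")
  expect_true(is.na(r))
})

test_that("a producer/non-producer pair splits the shared glucose pool", {
  cm <- build_community(list(toy_producer("S1"), toy_nonproducer("S2")),
                        c(0.5, 0.5))
  sol <- solve_pfba(formulate_pfba(cm))
  expect_equal(sol$mu, 10, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes["EX_but"]), 5, tolerance = 1e-6)
  expect_equal(butyrate_rate(sol), 0.5, tolerance = 1e-6)
})

test_that("butyrate_rate guards its inputs", {
  cm <- build_community(list(toy_producer("S1")), 1)
  sol <- solve_pfba(formulate_pfba(cm))
  expect_error(butyrate_rate(sol, "EX_nothing"), "unknown")
  expect_equal(butyrate_rate(sol, "EX_glc") * sol$mu,
               unname(sol$fluxes["EX_glc"]), tolerance = 1e-8)
})

test_that("parsimony leaves growth intact and drains redundant pathways", {
  cm <- build_community(list(toy_redundant_producer("S3")), 1)
  sol0 <- solve_pfba(formulate_pfba(cm, parsimony_coef = 0))
  sol <- solve_pfba(formulate_pfba(cm, parsimony_coef = 1e-5))
  total0 <- sum(abs(sol0$fluxes))
  expect_lte(abs(sol$mu - sol0$mu), 1e-5 * total0 + 1e-9)
  # the two-step export path carries no flux under the penalty
  expect_equal(unname(sol$fluxes["S3|T_but_a"]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["S3|T_but_b"]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["S3|T_but"]), 10, tolerance = 1e-6)
  # pFBA total flux is minimal among alternative optima
  expect_lte(sum(abs(sol$fluxes)), total0 + 1e-6)
})

test_that("growth converges to the pure-FBA optimum as the penalty vanishes", {
  cm <- build_community(list(toy_producer("S1"), toy_nonproducer("S2")),
                        c(0.4, 0.6))
  mu0 <- solve_pfba(formulate_pfba(cm, parsimony_coef = 0))$mu
  total0 <- sum(abs(solve_pfba(formulate_pfba(cm, parsimony_coef = 0))$fluxes))
  for (lam in c(1e-3, 1e-5, 1e-7)) {
    mu <- solve_pfba(formulate_pfba(cm, parsimony_coef = lam))$mu
    expect_lte(mu0 - mu, lam * total0 + 1e-9)
    expect_lte(mu, mu0 + 1e-9)
  }
})

test_that("doubling all exchange bounds doubles growth and leaves the rate unchanged", {
  s1 <- toy_producer("S1")
  s1d <- toy_producer("S1", uptake = 20)
  r1 <- solve_pfba(formulate_pfba(build_community(list(s1), 1)))
  r2 <- solve_pfba(formulate_pfba(build_community(list(s1d), 1)))
  expect_equal(r2$mu, 2 * r1$mu, tolerance = 1e-8)
  expect_equal(butyrate_rate(r2), butyrate_rate(r1), tolerance = 1e-8)
})

test_that("mass balance and coupling hold on random synthetic communities", {
  set.seed(31)
  reg <- make_species_models(20, 0.4, seed = 31)
  for (i in 1:25) {
    comm <- random_community(reg)
    cm <- build_community(comm$models, comm$weights)
    sol <- solve_pfba(formulate_pfba(cm))
    expect_equal(sol$status, "optimal")
    expect_lte(mass_balance_residual(cm, sol), 1e-8)
    expect_lte(coupling_residual(cm, sol), 1e-8)
    if ("EX_but" %in% names(sol$fluxes)) {
      expect_gte(butyrate_rate(sol), 0)
    }
  }
})

test_that("sample-level capacity matches the hand-solved communities", {
  reg <- list(S1 = toy_producer("S1"), S2 = toy_nonproducer("S2"))
  ab <- tibble::tibble(
    sample_id = c("a", "b", "b"),
    taxon_id = c("S1", "S1", "S2"),
    rel_abundance = c(1, 0.5, 0.5)
  )
  got_a <- sample_butyrate_capacity(ab, "a", reg)
  expect_equal(got_a$butyrate_rate, 1, tolerance = 1e-6)
  got_b <- sample_butyrate_capacity(ab, "b", reg)
  expect_equal(got_b$butyrate_rate, 0.5, tolerance = 1e-6)
  expect_equal(got_b$n_members, 2L)
})

test_that("unresolved taxa are dropped with their mass excluded before renormalisation", {
  reg <- list(S1 = toy_producer("S1"), S2 = toy_nonproducer("S2"))
  ab <- tibble::tibble(
    sample_id = "a",
    taxon_id = c("S1", "S2", "mystery"),
    rel_abundance = c(0.4, 0.4, 0.2)
  )
  expect_warning(got <- sample_butyrate_capacity(ab, "a", reg), "dropped")
  expect_equal(got$dropped_mass, 0.2)
  expect_equal(got$n_members, 2L)
  expect_equal(got$butyrate_rate, 0.5, tolerance = 1e-6)
})

test_that("a sample with no model-resolvable taxa yields an empty community", {
  reg <- list(S1 = toy_producer("S1"))
  ab <- tibble::tibble(sample_id = "a", taxon_id = "unknown",
                       rel_abundance = 1)
  expect_warning(got <- sample_butyrate_capacity(ab, "a", reg), "dropped")
  expect_equal(got$status, "empty_community")
  expect_true(is.na(got$butyrate_rate))
})

test_that("the cohort fast path equals the per-sample path", {
  reg <- make_species_models(10, 0.4, seed = 33)
  cohort <- make_cohort(sim_config(n_responders = 4, n_nonresponders = 2,
                                   v2_retained = c(responders = 3,
                                                   nonresponders = 2),
                                   n_species = 10, seed = 33), reg)
  fast <- suppressWarnings(predict_cohort_rates(
    cohort$abundances, reg$registry, mapping = cohort$otu_truth))
  for (s in fast$sample_id) {
    slow <- suppressWarnings(sample_butyrate_capacity(
      cohort$abundances, s, reg$registry, mapping = cohort$otu_truth))
    expect_equal(fast$butyrate_rate[fast$sample_id == s],
                 slow$butyrate_rate, tolerance = 1e-12)
  }
})

test_that("a community without producers has rate zero, not undefined", {
  reg <- list(S2 = nonproducer_model("S2"), S4 = nonproducer_model("S4"))
  ab <- tibble::tibble(sample_id = "a", taxon_id = c("S2", "S4"),
                       rel_abundance = c(0.5, 0.5))
  got <- sample_butyrate_capacity(ab, "a", reg)
  expect_equal(got$status, "optimal")
  expect_equal(got$butyrate_rate, 0)
})
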