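test_that("response labelling applies the >=50% Lichtiger decrease rule", {
  expect_equal(label_response(10, 5), "responder")     # exactly 50%
  expect_equal(label_response(10, 6), "nonresponder")  # 40%
  expect_equal(label_response(12, 3), "responder")     # 75%
  expect_equal(label_response(c(10, 10), c(5, 6)),
               c("responder", "nonresponder"))
  expect_error(label_response(3, 1), "eligible")
  expect_error(label_response(10, 25), "0-21")
  expect_error(label_response(10.5, 5), "integers")
})

test_that("rank-sum exact p matches the worked separable cases", {
  t1 <- wilcoxon_rank_sum_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$p_value, 0.1)
  expect_equal(t1$method, "exact")
  t2 <- wilcoxon_rank_sum_exact(c(1, 2), c(3, 4))
  expect_equal(t2$p_value, 1 / 3)
  t3 <- wilcoxon_rank_sum_exact(5, 5)
  expect_equal(t3$p_value, 1)
})

test_that("signed-rank exact p matches the worked cases incl. ties and zeros", {
  expect_equal(wilcoxon_signed_rank_exact(differences = c(1, 2, 3))$p_value,
               0.25)
  expect_equal(wilcoxon_signed_rank_exact(differences = c(1, -1))$p_value, 1)
  expect_equal(wilcoxon_signed_rank_exact(differences = c(0, 0, 2))$p_value,
               1)
  z <- suppressMessages(
    wilcoxon_signed_rank_exact(differences = c(0, 0, 0))
  )
  expect_equal(z$p_value, 1)
  expect_equal(unname(z$n["n_zero"]), 3L)
})

test_that("rank-sum matches brute-force enumeration for all small inputs incl. ties", {
  set.seed(51)
  for (i in 1:40) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    pool <- sample(1:4, nx + ny, replace = TRUE) # heavy ties
    x <- pool[seq_len(nx)]; y <- pool[nx + seq_len(ny)]
    for (alt in c("two.sided", "less", "greater")) {
      got <- wilcoxon_rank_sum_exact(x, y, alternative = alt)
      expect_equal(got$p_value, oracle_rank_sum_p(x, y, alt),
                   info = paste("case", i, alt))
    }
  }
})

test_that("signed-rank matches brute-force enumeration for all small inputs", {
  set.seed(52)
  for (i in 1:40) {
    m <- sample(1:8, 1)
    d <- sample(c(-3, -2, -1, 0, 1, 2, 3), m, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    for (alt in c("two.sided", "less", "greater")) {
      got <- suppressMessages(
        wilcoxon_signed_rank_exact(differences = d, alternative = alt)
      )
      expect_equal(got$p_value, oracle_signed_rank_p(d, alt),
                   info = paste("case", i, alt))
    }
  }
})

test_that("exact tests agree with wilcox.test on tie-free data", {
  set.seed(53)
  for (i in 1:10) {
    x <- sample(1:100, 6); y <- sample(101:200, 5) - runif(5)
    got <- wilcoxon_rank_sum_exact(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(unname(got$statistic), unname(ref$statistic))

    d <- sample(1:50, 7) * sample(c(-1, 1), 7, replace = TRUE)
    got2 <- wilcoxon_signed_rank_exact(differences = d)
    ref2 <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(got2$p_value, unname(ref2$p.value), tolerance = 1e-12)
  }
})

test_that("two-sided p is symmetric under group swap and sign flip", {
  set.seed(54)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(wilcoxon_rank_sum_exact(x, y)$p_value,
               wilcoxon_rank_sum_exact(y, x)$p_value)
  d <- rnorm(7)
  expect_equal(wilcoxon_signed_rank_exact(differences = d)$p_value,
               wilcoxon_signed_rank_exact(differences = -d)$p_value)
})

test_that("p decreases monotonically along a location-shift family", {
  set.seed(55)
  x <- rnorm(8)
  y0 <- rnorm(8)
  ps <- vapply(c(0, 0.5, 1, 2, 4), function(shift) {
    wilcoxon_rank_sum_exact(x, y0 + shift)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(56)
  x <- rnorm(20); y <- rnorm(15)
  expect_message(got <- wilcoxon_rank_sum_exact(x, y), "approximation")
  expect_equal(got$method, "approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-9)

  d <- rnorm(25)
  expect_message(got2 <- wilcoxon_signed_rank_exact(differences = d),
                 "approximation")
  ref2 <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got2$p_value, unname(ref2$p.value), tolerance = 1e-9)
})

make_test_cohort_tables <- function() {
  # 4 responders, 3 nonresponders; one responder misses V2
  md <- tibble::tibble(
    sample_id = c(outer(paste0("p", 1:7), c("_V1", "_V2"), paste0)),
    patient_id = rep(paste0("p", 1:7), 2),
    visit = rep(c("V1", "V2"), each = 7),
    lichtiger = c(rep(10, 7), c(4, 5, 3, 5, 8, 9, 7))
  )
  rates <- tibble::tibble(
    sample_id = setdiff(md$sample_id, "p2_V2"),
    butyrate_rate = c(0.2, 0.3, 0.25, 0.4, 0.5, 0.45, 0.35,
                      0.6, 0.55, 0.62, 0.48, 0.52, 0.41)
  )
  list(md = md, rates = rates)
}

test_that("the four cohort tests are assembled with the right groups and ns", {
  tc <- make_test_cohort_tables()
  res <- run_cohort_tests(tc$rates, tc$md)
  expect_s3_class(res, "gf_cohort_result")
  expect_setequal(res$tests$test,
                  c("rs_V1", "rs_V2", "sr_responders", "sr_nonresponders"))
  # V1: all 7 patients; V2: 6 samples (p2 missing)
  expect_equal(res$tests$n[res$tests$test == "rs_V1"], 7L)
  expect_equal(res$tests$n[res$tests$test == "rs_V2"], 6L)
  # paired tests: responders p1,p3,p4 (p2 lacks V2 rate), nonresponders 3
  expect_equal(res$tests$n[res$tests$test == "sr_responders"], 3L)
  expect_equal(res$tests$n[res$tests$test == "sr_nonresponders"], 3L)
  expect_true(all(res$tests$p_value >= 0 & res$tests$p_value <= 1))
  # rank-sum p at V1 equals a direct call on the same groups
  resp <- c("p1", "p2", "p3", "p4")
  v1 <- tc$rates[match(paste0(paste0("p", 1:7), "_V1"),
                       tc$rates$sample_id), ]$butyrate_rate
  direct <- wilcoxon_rank_sum_exact(v1[1:4], v1[5:7])
  expect_equal(res$tests$p_value[res$tests$test == "rs_V1"],
               direct$p_value)
})

test_that("a single nonresponder pair gives p = 1 and missing groups degrade gracefully", {
  md <- tibble::tibble(
    sample_id = c("q1_V1", "q1_V2"),
    patient_id = "q1", visit = c("V1", "V2"), lichtiger = c(10, 8)
  )
  rates <- tibble::tibble(sample_id = c("q1_V1", "q1_V2"),
                          butyrate_rate = c(0.2, 0.9))
  res <- suppressMessages(run_cohort_tests(rates, md))
  expect_equal(res$tests$p_value[res$tests$test == "sr_nonresponders"], 1)
  expect_equal(res$tests$method[res$tests$test == "rs_V1"],
               "not_computable")
})

test_that("samples with undefined rates are excluded and counted", {
  tc <- make_test_cohort_tables()
  tc$rates$butyrate_rate[1] <- NA_real_
  res <- run_cohort_tests(tc$rates, tc$md)
  expect_equal(res$excluded$undefined_rate, 1L)
  expect_equal(res$tests$n[res$tests$test == "rs_V1"], 6L)
})

test_that("tidy, glance and autoplot work on a cohort result", {
  tc <- make_test_cohort_tables()
  res <- run_cohort_tests(tc$rates, tc$md)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("p_rs_V1", "p_sr_responders") %in% names(gl)))
  p1 <- ggplot2::autoplot(res, type = "group")
  p2 <- ggplot2::autoplot(res, type = "paired")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
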