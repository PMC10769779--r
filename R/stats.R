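#' Label therapy response from Lichtiger scores
#'
#' Response to corticosteroid treatment is a decrease of the Lichtiger score
#' of at least 50% from baseline (V1) to week 4 (V2).  Patients must have
#' active disease at baseline (Lichtiger score >= 4) to be eligible; scores
#' outside 0-21 are errors.  Vectorised over patients.
#'
#' @param lichtiger_v1,lichtiger_v2 Integer Lichtiger scores (0-21) at the
#'   two visits.
#' @return Character vector, `"responder"` or `"nonresponder"`.
#' @export
#' @examples
#' label_response(10, 5)  # exactly 50% decrease -> responder
#' label_response(10, 6)  # 40% -> nonresponder
label_response <- function(lichtiger_v1, lichtiger_v2) {
  ok_range <- function(x) !is.na(x) & x >= 0 & x <= 21 & x == round(x)
  if (!all(ok_range(lichtiger_v1)) || !all(ok_range(lichtiger_v2))) {
    abort("Lichtiger scores must be integers in 0-21")
  }
  if (any(lichtiger_v1 < 4)) {
    abort("baseline Lichtiger score < 4: patient not eligible (no active disease)")
  }
  ifelse((lichtiger_v1 - lichtiger_v2) / lichtiger_v1 >= 0.5,
         "responder", "nonresponder")
}

# Exact distribution machinery -------------------------------------------
#
# Mid-ranks are multiples of 1/2, so doubling them gives integers and the
# permutation distribution of a rank-sum statistic becomes a subset-sum
# count, computed by dynamic programming.  This is exact under ties: the
# reference distribution is the permutation distribution of the observed
# (tied) ranks.

# Number of k-subsets of `vals` (non-negative integers) attaining each
# possible sum; returns matrix count[k+1, s+1].
subset_sum_counts <- function(vals, k_max) {
  s_max <- sum(vals)
  cnt <- matrix(0, nrow = k_max + 1L, ncol = s_max + 1L)
  cnt[1L, 1L] <- 1
  for (v in vals) {
    for (k in seq.int(k_max, 1L)) {
      if (v + 1L <= s_max + 1L) {
        src <- seq_len(s_max + 1L - v)
        cnt[k + 1L, src + v] <- cnt[k + 1L, src + v] + cnt[k, src]
      }
    }
  }
  cnt
}

# Two-sided p from lower/upper tail probabilities: double the smaller tail,
# capped at 1.
two_sided <- function(p_lower, p_upper, alternative) {
  switch(alternative,
         two.sided = min(1, 2 * min(p_lower, p_upper)),
         less = p_lower,
         greater = p_upper)
}

#' Exact Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum test with an exact permutation p-value:
#' the proportion of all `choose(nx+ny, nx)` assignments of the pooled
#' mid-ranks to group x whose rank sum is at least as extreme as observed.
#' Ties are handled with mid-ranks, and the reference distribution is the
#' permutation distribution of the observed ranks, so the test stays exact
#' under ties.  The two-sided p doubles the smaller one-sided tail (capped
#' at 1).  When the combined sample size exceeds `exact_cap` the normal
#' approximation with tie correction and continuity correction is used and a
#' notice is emitted.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (tail of the first group).
#' @param exact_cap Largest combined `nx + ny` for which the exact
#'   enumeration is used (default 25).
#' @return A list: `statistic` (Mann-Whitney U for group x), `p_value`, `n`
#'   (per-group sizes), `method` (`"exact"` or `"approx"`).
#' @export
#' @examples
#' wilcoxon_rank_sum_exact(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
wilcoxon_rank_sum_exact <- function(x, y,
                                    alternative = c("two.sided", "less",
                                                    "greater"),
                                    exact_cap = 25) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort("both groups must be non-empty")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))           # mid-ranks
  rx <- sum(r[seq_len(nx)])
  u_stat <- rx - nx * (nx + 1) / 2
  if (n <= exact_cap) {
    vals <- as.integer(round(2 * r))
    w_obs <- as.integer(round(2 * rx))
    cnt <- subset_sum_counts(vals, nx)
    dist <- cnt[nx + 1L, ]
    total <- sum(dist)           # == choose(n, nx)
    sums <- seq_along(dist) - 1L
    p_lower <- sum(dist[sums <= w_obs]) / total
    p_upper <- sum(dist[sums >= w_obs]) / total
    p <- two_sided(p_lower, p_upper, alternative)
    method <- "exact"
  } else {
    inform(paste0("rank-sum: combined n = ", n, " exceeds exact cap ",
                  exact_cap, "; using normal approximation"))
    mu_u <- nx * ny / 2
    ties <- table(r)
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z_num <- u_stat - mu_u
    cc <- sign(z_num) * 0.5
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    method <- "approx"
  }
  list(statistic = u_stat, p_value = p, n = c(nx = nx, ny = ny),
       method = method)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired signed-rank test with an exact p-value: zero differences are
#' dropped (classical Wilcoxon convention, count reported), the absolute
#' differences receive mid-ranks, and the p-value enumerates all `2^m` sign
#' assignments of the m nonzero differences, counting those whose positive
#' rank sum W is at least as extreme as observed.  Two-sided p doubles the
#' smaller tail, capped at 1.  Above `exact_cap` nonzero differences the
#' normal approximation with tie and continuity correction is used with a
#' notice.  If all differences are zero, `p = 1` with a notice.
#'
#' @param pairs Two-column matrix/data frame of (v1, v2) pairs, or a numeric
#'   vector of differences `v2 - v1` via `differences`.
#' @param differences Optional numeric vector of paired differences; used
#'   when `pairs` is missing.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_cap Largest number of nonzero differences for the exact
#'   enumeration (default 20).
#' @return A list: `statistic` (positive-rank sum W), `p_value`, `n`
#'   (`m` nonzero and `n_zero` dropped), `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(differences = c(1, 2, 3))$p_value  # 0.25
wilcoxon_signed_rank_exact <- function(pairs = NULL, differences = NULL,
                                       alternative = c("two.sided", "less",
                                                       "greater"),
                                       exact_cap = 20) {
  alternative <- match.arg(alternative)
  if (is.null(differences)) {
    if (is.null(pairs)) abort("supply either pairs or differences")
    pairs <- as.matrix(as.data.frame(pairs))
    differences <- pairs[, 2] - pairs[, 1]
  }
  d <- differences[!is.na(differences)]
  if (length(d) == 0L) abort("no pairs with defined differences")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    inform("signed-rank: all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1,
                n = c(m = 0L, n_zero = n_zero), method = "exact"))
  }
  r <- rank(abs(d))            # mid-ranks of |d|
  w_obs <- sum(r[d > 0])
  if (m <= exact_cap) {
    vals <- as.integer(round(2 * r))
    w2 <- as.integer(round(2 * w_obs))
    # distribution of W over all 2^m sign assignments: subset sums with any
    # subset size
    cnt <- subset_sum_counts(vals, m)
    dist <- colSums(cnt)
    total <- sum(dist)           # == 2^m
    sums <- seq_along(dist) - 1L
    p_lower <- sum(dist[sums <= w2]) / total
    p_upper <- sum(dist[sums >= w2]) / total
    p <- two_sided(p_lower, p_upper, alternative)
    method <- "exact"
  } else {
    inform(paste0("signed-rank: m = ", m, " exceeds exact cap ", exact_cap,
                  "; using normal approximation"))
    mu_w <- sum(r) / 2
    ties <- table(r)
    sigma2 <- sum(r^2) / 4
    z_num <- w_obs - mu_w
    cc <- sign(z_num) * 0.5
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    method <- "approx"
  }
  list(statistic = w_obs, p_value = p, n = c(m = m, n_zero = n_zero),
       method = method)
}

#' Run the four cohort comparisons of butyrate production rate
#'
#' Reproduces the two-visit statistical design: cross-sectional Wilcoxon
#' rank-sum tests comparing responders and nonresponders at V1 and at V2
#' (unpaired, all samples with a defined rate at that visit), and
#' longitudinal Wilcoxon signed-rank tests comparing V1 to V2 within
#' responders and within nonresponders (patients with both visits only).
#' Response labels are derived per patient from the Lichtiger scores with
#' [label_response()]; metadata rows may describe clinical visits without a
#' microbiome sample, so a patient can contribute a V1 rate and a response
#' label while missing a V2 rate.  Samples with undefined rates are excluded
#' and counted.
#'
#' @param rates Tibble from [predict_cohort_rates()] (needs `sample_id`,
#'   `butyrate_rate`).
#' @param metadata Tibble with `sample_id`, `patient_id`, `visit`,
#'   `lichtiger` covering both visits.
#' @param exact_cap_rank_sum,exact_cap_signed_rank Exact-enumeration caps
#'   passed to the two tests.
#' @return An object of class `gf_cohort_result`: `per_sample` (sample-level
#'   rates with visit and response group), `tests` (tibble `test`,
#'   `statistic`, `p_value`, `n`, `method`), and `excluded` counts.
#'   `tidy()`, `glance()` and `autoplot()` methods are available.
#' @export
run_cohort_tests <- function(rates, metadata, exact_cap_rank_sum = 25,
                             exact_cap_signed_rank = 20) {
  metadata <- validate_metadata(as_tibble(metadata))
  scores <- metadata |>
    dplyr::select("patient_id", "visit", "lichtiger") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "lichtiger")
  labelled <- scores |>
    dplyr::filter(!is.na(.data$V1), !is.na(.data$V2)) |>
    dplyr::mutate(response_group = label_response(.data$V1, .data$V2)) |>
    dplyr::select("patient_id", "response_group")
  n_unlabelled <- nrow(scores) - nrow(labelled)

  per_sample <- metadata |>
    dplyr::inner_join(as_tibble(rates), by = "sample_id") |>
    dplyr::left_join(labelled, by = "patient_id") |>
    dplyr::select("sample_id", "patient_id", "visit", "response_group",
                  "butyrate_rate")
  n_undefined <- sum(is.na(per_sample$butyrate_rate))
  usable <- per_sample |>
    dplyr::filter(!is.na(.data$butyrate_rate), !is.na(.data$response_group))

  grp <- function(visit, group) {
    usable$butyrate_rate[usable$visit == visit &
                           usable$response_group == group]
  }
  rs_test <- function(visit) {
    x <- grp(visit, "responder"); y <- grp(visit, "nonresponder")
    if (length(x) == 0L || length(y) == 0L) {
      return(tibble(statistic = NA_real_, p_value = NA_real_,
                    n = length(x) + length(y), method = "not_computable"))
    }
    t <- suppressMessages(
      wilcoxon_rank_sum_exact(x, y, exact_cap = exact_cap_rank_sum)
    )
    tibble(statistic = t$statistic, p_value = t$p_value,
           n = sum(t$n), method = t$method)
  }
  sr_test <- function(group) {
    wide <- usable |>
      dplyr::filter(.data$response_group == group) |>
      dplyr::select("patient_id", "visit", "butyrate_rate") |>
      tidyr::pivot_wider(names_from = "visit",
                         values_from = "butyrate_rate")
    if (!all(c("V1", "V2") %in% names(wide))) {
      return(tibble(statistic = NA_real_, p_value = NA_real_, n = 0L,
                    method = "not_computable"))
    }
    wide <- dplyr::filter(wide, !is.na(.data$V1), !is.na(.data$V2))
    if (nrow(wide) == 0L) {
      return(tibble(statistic = NA_real_, p_value = NA_real_, n = 0L,
                    method = "not_computable"))
    }
    t <- suppressMessages(
      wilcoxon_signed_rank_exact(differences = wide$V2 - wide$V1,
                                 exact_cap = exact_cap_signed_rank)
    )
    tibble(statistic = t$statistic, p_value = t$p_value, n = nrow(wide),
           method = t$method)
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(rs_test("V1"), test = "rs_V1", .before = 1),
    dplyr::mutate(rs_test("V2"), test = "rs_V2", .before = 1),
    dplyr::mutate(sr_test("responder"), test = "sr_responders", .before = 1),
    dplyr::mutate(sr_test("nonresponder"), test = "sr_nonresponders",
                  .before = 1)
  )
  structure(
    list(per_sample = per_sample, tests = tests,
         excluded = list(undefined_rate = n_undefined,
                         unlabelled_patients = n_unlabelled)),
    class = "gf_cohort_result"
  )
}

#' @exportS3Method base::print
print.gf_cohort_result <- function(x, ...) {
  cat("<gf_cohort_result>", nrow(x$per_sample), "samples;",
      x$excluded$undefined_rate, "with undefined rate\n")
  print(x$tests)
  invisible(x)
}
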