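test_that("identical sequences align at 100% identity and coverage", {
  set.seed(1)
  q <- random_dna_chr(100)
  a <- align_pair(q, q)
  expect_equal(a$identity_pct, 100)
  expect_equal(a$query_coverage_pct, 100)
  expect_equal(a$aligned_length, 100L)
})

test_that("three substitutions in 100 nt give 97% identity at full coverage", {
  set.seed(2)
  q <- random_dna_chr(100)
  r <- strsplit(q, "", fixed = TRUE)[[1]]
  for (pos in c(30, 55, 80)) {
    r[pos] <- setdiff(c("A", "C", "G", "T"), r[pos])[1]
  }
  a <- align_pair(q, paste(r, collapse = ""))
  expect_equal(a$identity_pct, 97)
  expect_equal(a$query_coverage_pct, 100)
})

test_that("a foreign query tail caps coverage below 90%", {
  set.seed(40)
  core <- random_dna_chr(90)
  tail10 <- "CCCCCCCCCC"  # reference is A/G-rich so the tail cannot extend
  ref <- gsub("C", "A", random_dna_chr(60))
  ref <- paste0(ref, core)
  q <- paste0(tail10, core)
  a <- align_pair(q, ref)
  expect_lte(a$query_coverage_pct, 90)
  o <- oracle_align(q, ref)
  expect_equal(a$query_coverage_pct, o$query_coverage_pct)
  expect_equal(a$identity_pct, o$identity_pct)
})

test_that("alignment agrees with the independent Gotoh oracle on short sequences", {
  set.seed(7)
  for (i in 1:30) {
    ref <- random_dna_chr(sample(25:40, 1))
    # query: mutated substring of the reference, sometimes reverse strand
    start <- sample(1:10, 1)
    q <- substr(ref, start, min(nchar(ref), start + sample(12:25, 1)))
    q <- mutate_dna_chr(q, 0.05)
    if (runif(1) < 0.3) q <- revcomp_chr(q)
    a <- align_pair(q, ref)
    o <- oracle_align(q, ref)
    expect_equal(a$score, o$score, info = paste("case", i))
    expect_equal(a$identity_pct, o$identity_pct, tolerance = 1e-12,
                 info = paste("case", i))
    expect_equal(a$query_coverage_pct, o$query_coverage_pct,
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("empty or non-ACGTN sequences are rejected", {
  expect_error(align_pair("", "ACGT"), "non-empty")
  expect_error(align_pair("ACGT", "ACXT"), "non-ACGTN")
})

test_that("N never counts as a match", {
  a <- align_pair("ACGNNACGT", "ACGNNACGT")
  expect_lt(a$identity_pct, 100)
})

test_that("a dominant hit is retained and assigned", {
  set.seed(8)
  r1 <- random_dna_chr(120)
  r2 <- mutate_dna_chr(r1, 0.10)
  refs <- tibble::tibble(id = c("R1", "R2"), sequence = c(r1, r2))
  m <- map_otu(list(id = "q", sequence = r1), refs)
  expect_equal(m$status, "mapped")
  expect_equal(m$assigned_reference, "R1")
  expect_equal(nrow(m$retained_hits), 1L)
})

test_that("queries below the identity threshold are unmapped", {
  set.seed(9)
  r1 <- random_dna_chr(150)
  q <- mutate_dna_chr(r1, 0.08)   # ~92% identity, below 97%
  refs <- tibble::tibble(id = "R1", sequence = r1)
  m <- map_otu(list(id = "q", sequence = q), refs)
  expect_equal(m$status, "unmapped")
  expect_true(is.na(m$assigned_reference))
})

test_that("equal-identity hits both survive the filter and tie-break lexicographically", {
  set.seed(10)
  r <- random_dna_chr(100)
  refs <- tibble::tibble(id = c("R2", "R1"), sequence = c(r, r))
  expect_warning(
    m <- map_otu(list(id = "q", sequence = r), refs),
    "tie"
  )
  expect_equal(sort(m$retained_hits$reference_id), c("R1", "R2"))
  expect_equal(m$assigned_reference, "R1")
})

test_that("map_all assigns mutated OTUs to their sources and reports unmapped", {
  set.seed(12)
  refs <- tibble::tibble(
    id = sprintf("R%d", 1:3),
    sequence = vapply(rep(200, 3), random_dna_chr, "")
  )
  otus <- tibble::tibble(
    id = c("o1", "o2", "o3"),
    sequence = c(mutate_dna_chr(refs$sequence[1], 0.01),
                 mutate_dna_chr(refs$sequence[2], 0.02),
                 random_dna_chr(200))  # unrelated -> unmapped
  )
  res <- map_all(otus, refs)
  expect_equal(res$status, c("mapped", "mapped", "unmapped"))
  expect_equal(res$assigned_reference[1:2], c("R1", "R2"))
  expect_true(is.na(res$assigned_reference[3]))
})

test_that("map_all rejects duplicate OTU ids and handles an empty query set", {
  refs <- tibble::tibble(id = "R1", sequence = "ACGTACGTAC")
  expect_error(
    map_all(tibble::tibble(id = c("a", "a"), sequence = c("ACGT", "ACGT")),
            refs),
    "duplicate"
  )
  res <- map_all(tibble::tibble(id = character(), sequence = character()),
                 refs)
  expect_equal(nrow(res), 0L)
})

test_that("with thresholds disabled every OTU is assigned to its best reference", {
  set.seed(13)
  refs <- tibble::tibble(
    id = sprintf("R%d", 1:3),
    sequence = vapply(rep(150, 3), random_dna_chr, "")
  )
  otus <- tibble::tibble(id = c("o1", "o2"),
                         sequence = c(mutate_dna_chr(refs$sequence[2], 0.3),
                                      random_dna_chr(150)))
  res <- suppressWarnings(map_all(otus, refs, min_identity = 0,
                                  min_coverage = 0))
  expect_true(all(res$status == "mapped"))
})

test_that("mapping is deterministic and monotone in the thresholds", {
  set.seed(14)
  refs <- tibble::tibble(
    id = sprintf("R%d", 1:4),
    sequence = vapply(rep(120, 4), random_dna_chr, "")
  )
  q <- list(id = "q", sequence = mutate_dna_chr(refs$sequence[2], 0.04))
  m1 <- map_otu(q, refs, min_identity = 90, min_coverage = 80)
  m2 <- map_otu(q, refs, min_identity = 90, min_coverage = 80)
  expect_identical(m1$retained_hits, m2$retained_hits)
  # tightening thresholds can only shrink the retained set
  for (ident in c(0, 50, 90, 95, 99)) {
    loose <- map_otu(q, refs, min_identity = ident, min_coverage = 0)
    tight <- map_otu(q, refs, min_identity = ident + 1, min_coverage = 0)
    expect_true(all(tight$retained_hits$reference_id %in%
                      loose$retained_hits$reference_id))
  }
})

test_that("batched map_all agrees with per-query map_otu", {
  set.seed(78)
  reg <- make_species_models(8, 0.5, seed = 78)
  otus <- tibble::tibble(
    id = sprintf("o%02d", 1:8),
    sequence = vapply(reg$references$sequence, mutate_dna_chr, "",
                      rate = 0.02)
  )
  otus$sequence[5] <- random_dna_chr(250)  # unmappable
  res <- suppressWarnings(map_all(otus, reg$references))
  for (i in seq_len(nrow(otus))) {
    m <- suppressWarnings(
      map_otu(list(id = otus$id[i], sequence = otus$sequence[i]),
              reg$references)
    )
    expect_identical(m$status, res$status[i])
    expect_identical(m$assigned_reference, res$assigned_reference[i])
    if (m$status == "mapped") {
      expect_equal(res$identity_pct[i], m$retained_hits$identity_pct[1])
    }
  }
})
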