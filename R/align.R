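#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment
#'   reverseComplement
NULL

# BLASTN-like nucleotide scoring matrix over the ACGTN alphabet.  The
# ambiguity code N always scores as a mismatch, including against itself.
score_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

check_seq <- function(x, what) {
  if (!is_scalar_chr(x) || !nzchar(x)) {
    abort(paste0(what, " sequence must be a non-empty string"))
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    abort(paste0(what, " sequence contains non-ACGTN symbols"))
  }
  x
}

# Identity/coverage statistics from one pairwiseAlignment fit where the
# *references* are the patterns and the single query is the subject (this
# orientation lets one call score a query against many references).
# Alignment columns and matches come from the cheap accessors: with this
# orientation, insertion() ranges are gap columns on the query side and
# deletion() ranges gap columns on the reference side, so
# columns = nmatch + nmismatch + gaps and query span = columns - query gaps.
# nmatch() counts letter equality, which would count N-N as a match, so
# pairs containing N take a slow path that recounts from the aligned
# strings with N forced to mismatch.
align_stats_from_pa <- function(pa, query_len, has_n = FALSE,
                                query_is_pattern = FALSE) {
  n_match <- Biostrings::nmatch(pa)
  n_mis <- Biostrings::nmismatch(pa)
  ins_w <- vapply(Biostrings::insertion(pa), function(r) sum(Biostrings::width(r)),
                  numeric(1))
  del_w <- vapply(Biostrings::deletion(pa), function(r) sum(Biostrings::width(r)),
                  numeric(1))
  cols <- n_match + n_mis + ins_w + del_w
  # insertion() = gap columns in the subject, deletion() = in the pattern
  span <- cols - (if (query_is_pattern) del_w else ins_w)
  if (has_n) {
    qa <- as.character(Biostrings::alignedSubject(pa))
    ra <- as.character(Biostrings::alignedPattern(pa))
    n_match <- purrr::map2_int(qa, ra, function(a, b) {
      ca <- strsplit(a, "", fixed = TRUE)[[1]]
      cb <- strsplit(b, "", fixed = TRUE)[[1]]
      sum(ca == cb & ca != "-" & ca != "N")
    })
  }
  tibble(
    identity_pct = ifelse(cols > 0, 100 * n_match / cols, 0),
    query_coverage_pct = 100 * span / query_len,
    aligned_length = as.integer(cols),
    score = Biostrings::score(pa)
  )
}

# Score one query (both orientations) against many references; returns one
# row per reference with the better-scoring orientation kept.
align_query_to_refs <- function(query, ref_seqs, scoring) {
  mat <- score_matrix(scoring$match, scoring$mismatch)
  refs <- DNAStringSet(ref_seqs)
  qlen <- nchar(query)
  has_n <- grepl("N", query, fixed = TRUE) ||
    any(grepl("N", ref_seqs, fixed = TRUE))
  fits <- purrr::map(
    c(fwd = query,
      rev = as.character(reverseComplement(DNAString(query)))),
    function(q) {
      pa <- pairwiseAlignment(
        pattern = refs, subject = DNAString(q), type = "local",
        substitutionMatrix = mat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
      )
      align_stats_from_pa(pa, qlen, has_n = has_n)
    }
  )
  take_rev <- fits$rev$score > fits$fwd$score
  out <- fits$fwd
  out[take_rev, ] <- fits$rev[take_rev, ]
  out$strand <- ifelse(take_rev, "-", "+")
  out
}

#' Align two DNA sequences (local, affine gaps)
#'
#' Exact Smith-Waterman local alignment with affine gap penalties and
#' BLASTN-like default scores (match +2, mismatch -3, gap open 5, gap
#' extend 2).  Percent identity uses the BLAST convention
#' `100 * matches / alignment columns` with gap columns included in the
#' denominator; query coverage is `100 * aligned query span / query length`.
#' The query is also aligned reverse-complemented and the better-scoring
#' orientation is reported.  `N` scores as a mismatch and never counts as a
#' match.
#'
#' @param query,reference DNA sequences (strings over ACGTN).
#' @param query_id,reference_id Optional ids carried into the result.
#' @param scoring Named list `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @return A one-row tibble: `query_id`, `reference_id`, `identity_pct`,
#'   `query_coverage_pct`, `aligned_length`, `score`, `strand`.
#' @export
#' @examples
#' align_pair("ACGTACGTAC", "ACGTACGTAC")
align_pair <- function(query, reference, query_id = "query",
                       reference_id = "reference",
                       scoring = list(match = 2, mismatch = -3,
                                      gap_open = 5, gap_extend = 2)) {
  query <- check_seq(query, "query")
  reference <- check_seq(reference, "reference")
  out <- align_query_to_refs(query, reference, scoring)
  dplyr::bind_cols(tibble(query_id = query_id, reference_id = reference_id),
                   out)
}

#' Map one OTU sequence onto reference 16S sequences
#'
#' Aligns the query against every reference, discards hits below the identity
#' or query-coverage thresholds, and among survivors keeps only hits within a
#' small tie tolerance of the maximum identity.  When several references tie
#' at the maximum identity, all are retained in `retained_hits` but a single
#' deterministic assignment is made to the lexicographically smallest
#' reference id (with a warning), since each OTU feeds exactly one species
#' model downstream.
#'
#' @param query One-row tibble (or list) with `id` and `sequence`.
#' @param references Tibble with columns `id`, `sequence`.
#' @param min_identity Minimum percent identity (default 97).
#' @param min_coverage Minimum percent query coverage (default 95).
#' @param tie_tol Identity tie tolerance (default 1e-9).
#' @param scoring Alignment scoring parameters, see [align_pair()].
#' @return A list of class `gf_mapping` with elements `query_id`,
#'   `retained_hits` (tibble of `AlignmentStats` rows), `assigned_reference`
#'   (`NA_character_` when unmapped) and `status` (`"mapped"`/`"unmapped"`).
#' @export
map_otu <- function(query, references, min_identity = 97,
                    min_coverage = 95, tie_tol = 1e-9,
                    scoring = list(match = 2, mismatch = -3,
                                   gap_open = 5, gap_extend = 2)) {
  if (nrow(as_tibble(references)) == 0L) abort("references must be non-empty")
  qid <- query$id
  qseq <- check_seq(query$sequence, paste0("query ", qid))
  refs <- as_tibble(references)
  stats <- align_query_to_refs(qseq, refs$sequence, scoring)
  stats <- dplyr::bind_cols(
    tibble(query_id = qid, reference_id = refs$id), stats
  )
  mapping_from_stats(qid, stats, min_identity, min_coverage, tie_tol)
}

# Shared filter/retention logic: drop hits failing either threshold, keep
# hits within tie_tol of the maximum identity, assign the lexicographically
# smallest retained reference.
mapping_from_stats <- function(qid, stats, min_identity, min_coverage,
                               tie_tol) {
  pass <- stats$identity_pct >= min_identity &
    stats$query_coverage_pct >= min_coverage
  surv <- stats[pass, , drop = FALSE]
  if (nrow(surv) == 0L) {
    return(structure(
      list(query_id = qid, retained_hits = surv,
           assigned_reference = NA_character_, status = "unmapped"),
      class = "gf_mapping"
    ))
  }
  max_id <- max(surv$identity_pct)
  retained <- surv[surv$identity_pct >= max_id - tie_tol, , drop = FALSE]
  retained <- dplyr::arrange(retained, .data$reference_id)
  if (nrow(retained) > 1L) {
    warn(paste0("OTU ", qid, ": ", nrow(retained),
                " references tie at maximum identity; assigning '",
                retained$reference_id[1], "'"))
  }
  structure(
    list(query_id = qid, retained_hits = retained,
         assigned_reference = retained$reference_id[1], status = "mapped"),
    class = "gf_mapping"
  )
}

#' Map all OTUs onto reference sequences
#'
#' Applies [map_otu()] to every query and returns the mapping summary table:
#' one row per OTU (mapped or not) with the assigned reference, the identity
#' and coverage of the retained hit, the number of tied best hits, and the
#' mapping status.
#'
#' @param otus Tibble of OTU records (`id`, `sequence`); ids must be unique.
#' @inheritParams map_otu
#' @return A tibble `otu_id`, `assigned_reference`, `identity_pct`,
#'   `query_coverage_pct`, `n_tied_hits`, `status`, carrying the full list of
#'   `gf_mapping` results in attribute `"mappings"`.
#' @export
map_all <- function(otus, references, min_identity = 97, min_coverage = 95,
                    tie_tol = 1e-9,
                    scoring = list(match = 2, mismatch = -3,
                                   gap_open = 5, gap_extend = 2)) {
  otus <- as_tibble(otus)
  if (anyDuplicated(otus$id)) {
    abort(paste0("duplicate OTU id(s): ",
                 paste(unique(otus$id[duplicated(otus$id)]), collapse = ", ")))
  }
  refs <- as_tibble(references)
  if (nrow(refs) == 0L) abort("references must be non-empty")
  n_q <- nrow(otus)
  maps <- list()
  if (n_q > 0L) {
    # batched alignment: one pairwiseAlignment call per reference and
    # strand, with all queries as patterns
    qseq <- vapply(seq_len(n_q), function(i) {
      check_seq(otus$sequence[i], paste0("query ", otus$id[i]))
    }, "")
    qlens <- nchar(qseq)
    mat <- score_matrix(scoring$match, scoring$mismatch)
    q_fwd <- DNAStringSet(qseq)
    q_rev <- reverseComplement(q_fwd)
    has_n <- any(grepl("N", qseq, fixed = TRUE)) ||
      any(grepl("N", refs$sequence, fixed = TRUE))
    id_m <- cov_m <- len_m <- sc_m <-
      matrix(NA_real_, n_q, nrow(refs))
    for (j in seq_len(nrow(refs))) {
      subj <- DNAString(check_seq(refs$sequence[j], paste0("reference ",
                                                           refs$id[j])))
      best <- NULL
      for (qs in list(q_fwd, q_rev)) {
        pa <- pairwiseAlignment(
          pattern = qs, subject = subj, type = "local",
          substitutionMatrix = mat,
          gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
        )
        st <- align_stats_from_pa(pa, qlens, has_n = has_n,
                                  query_is_pattern = TRUE)
        if (is.null(best)) {
          best <- st
        } else {
          take <- st$score > best$score
          best[take, ] <- st[take, ]
        }
      }
      id_m[, j] <- best$identity_pct
      cov_m[, j] <- best$query_coverage_pct
      len_m[, j] <- best$aligned_length
      sc_m[, j] <- best$score
    }
    maps <- lapply(seq_len(n_q), function(i) {
      stats <- tibble(
        query_id = otus$id[i], reference_id = refs$id,
        identity_pct = id_m[i, ], query_coverage_pct = cov_m[i, ],
        aligned_length = as.integer(len_m[i, ]), score = sc_m[i, ]
      )
      mapping_from_stats(otus$id[i], stats, min_identity, min_coverage,
                         tie_tol)
    })
  }
  summary <- purrr::map_dfr(maps, function(m) {
    hit <- m$retained_hits
    tibble(
      otu_id = m$query_id,
      assigned_reference = m$assigned_reference,
      identity_pct = if (nrow(hit) > 0) hit$identity_pct[1] else NA_real_,
      query_coverage_pct = if (nrow(hit) > 0) {
        hit$query_coverage_pct[hit$reference_id == m$assigned_reference][1]
      } else NA_real_,
      n_tied_hits = nrow(hit),
      status = m$status
    )
  })
  if (nrow(summary) == 0L) {
    summary <- tibble(otu_id = character(), assigned_reference = character(),
                      identity_pct = numeric(),
                      query_coverage_pct = numeric(),
                      n_tied_hits = integer(), status = character())
  }
  attr(summary, "mappings") <- rlang::set_names(maps, otus$id)
  summary
}
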