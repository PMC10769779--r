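#' Read a species metabolic model from JSON
#'
#' The schema has top-level keys `species_id`, `metabolites` (array of
#' `{id, name, compartment}`), `reactions` (array of `{id, stoichiometry,
#' lower_bound, upper_bound, is_exchange, is_biomass}`) and
#' `biomass_reaction_id`; `stoichiometry` maps metabolite ids to real
#' coefficients (negative = consumed).  Files are UTF-8 with sorted keys,
#' as produced by [write_model_json()].
#'
#' @param path Path to a model JSON file.
#' @return A validated [metabolic_model()].
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("malformed JSON in ", path, ": ",
                                     conditionMessage(e)))
  )
  need <- c("species_id", "metabolites", "reactions", "biomass_reaction_id")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    abort(paste0("model JSON ", path, " lacks key(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_chr <- function(x, key) {
    if (!is.character(x) && !is.null(x)) x <- as.character(x)
    if (length(x) != 1L || is.na(x)) {
      abort(paste0("model JSON ", path, ": key '", key,
                   "' must be a single string"))
    }
    x
  }
  mets <- purrr::map(raw$metabolites, function(m) {
    tibble(
      id = as_chr(m$id, "metabolites.id"),
      name = as_chr(m$name %||% "", "metabolites.name"),
      compartment = as_chr(m$compartment, "metabolites.compartment")
    )
  })
  rxns <- purrr::map(raw$reactions, function(r) {
    s <- unlist(r$stoichiometry)
    if (is.null(s) || !is.numeric(s)) {
      abort(paste0("model JSON ", path, ": reaction '", r$id %||% "?",
                   "' has a malformed 'stoichiometry' key"))
    }
    tibble(
      id = as_chr(r$id, "reactions.id"),
      stoichiometry = list(s),
      lower_bound = as.numeric(r$lower_bound),
      upper_bound = as.numeric(r$upper_bound),
      is_exchange = isTRUE(r$is_exchange),
      is_biomass = isTRUE(r$is_biomass)
    )
  })
  metabolic_model(
    species_id = as_chr(raw$species_id, "species_id"),
    metabolites = dplyr::bind_rows(mets),
    reactions = dplyr::bind_rows(rxns),
    biomass_reaction_id = as_chr(raw$biomass_reaction_id,
                                 "biomass_reaction_id")
  )
}

#' Write a species metabolic model to JSON
#'
#' Serialisation is deterministic: entries and keys are sorted, numbers are
#' written at full precision, and two serialisations of the same model are
#' byte-identical.
#'
#' @param model A validated [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  validate_model(model)
  mets <- purrr::pmap(model$metabolites[, c("id", "name", "compartment")],
                      function(id, name, compartment) {
    list(compartment = compartment, id = id, name = name)
  })
  rxns <- purrr::pmap(
    model$reactions[, c("id", "stoichiometry", "lower_bound", "upper_bound",
                        "is_exchange", "is_biomass")],
    function(id, stoichiometry, lower_bound, upper_bound, is_exchange,
             is_biomass) {
      list(
        id = id,
        is_biomass = is_biomass,
        is_exchange = is_exchange,
        lower_bound = lower_bound,
        stoichiometry = as.list(stoichiometry[order(names(stoichiometry))]),
        upper_bound = upper_bound
      )
    }
  )
  obj <- list(
    biomass_reaction_id = model$biomass_reaction_id,
    metabolites = mets,
    reactions = rxns,
    species_id = model$species_id
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = 2),
    con = con, useBytes = TRUE
  )
  invisible(path)
}

#' Read a long-format relative-abundance table
#'
#' Expects a TSV with header `sample_id`, `taxon_id`, `rel_abundance`.
#' Abundances must be non-negative, unique per (sample, taxon), and sum to 1
#' per sample within `tol`; they are renormalised to sum to exactly 1.
#'
#' @param path Path to the TSV file.
#' @param tol Permitted deviation of per-sample sums from 1 (default `1e-6`,
#'   absorbing count-to-fraction rounding).
#' @return A tibble with columns `sample_id`, `taxon_id`, `rel_abundance`.
#' @export
read_abundances <- function(path, tol = 1e-6) {
  if (!file.exists(path)) abort(paste0("abundance file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "taxon_id", "rel_abundance")
  if (!identical(names(tbl)[seq_along(need)], need)) {
    abort(paste0("abundance table must have header ",
                 paste(need, collapse = ", ")))
  }
  validate_abundances(tbl[, need], tol = tol)
}

#' Validate and renormalise an abundance table
#'
#' @param tbl Tibble with columns `sample_id`, `taxon_id`, `rel_abundance`.
#' @inheritParams read_abundances
#' @return The validated tibble with per-sample sums renormalised to 1.
#' @export
validate_abundances <- function(tbl, tol = 1e-6) {
  tbl <- as_tibble(tbl)
  if (any(is.na(tbl$rel_abundance)) || any(tbl$rel_abundance < 0)) {
    abort("negative or missing relative abundance")
  }
  dup <- duplicated(tbl[, c("sample_id", "taxon_id")])
  if (any(dup)) {
    abort(paste0("duplicated (sample, taxon) row(s): ",
                 paste(unique(paste(tbl$sample_id[dup], tbl$taxon_id[dup],
                                    sep = "/")), collapse = ", ")))
  }
  sums <- tapply(tbl$rel_abundance, tbl$sample_id, sum)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    abort(paste0("per-sample abundances do not sum to 1 for sample(s): ",
                 paste(names(sums)[off], collapse = ", ")))
  }
  dplyr::mutate(dplyr::group_by(tbl, .data$sample_id),
                rel_abundance = .data$rel_abundance /
                  sum(.data$rel_abundance)) |>
    dplyr::ungroup()
}

#' Read sample metadata
#'
#' Expects a TSV with header `sample_id`, `patient_id`, `visit`, `lichtiger`.
#' `visit` must be `V1` or `V2`; the Lichtiger clinical activity score is an
#' integer in 0-21 (0 = no activity, 21 = maximal activity); at most one row
#' per (patient, visit).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the four columns above.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "patient_id", "visit", "lichtiger")
  if (!all(need %in% names(tbl))) {
    abort(paste0("metadata must have columns ", paste(need, collapse = ", ")))
  }
  tbl <- as_tibble(tbl)[, need]
  validate_metadata(tbl)
}

validate_metadata <- function(tbl) {
  f <- character()
  if (!all(tbl$visit %in% c("V1", "V2"))) {
    f <- c(f, "visit must be V1 or V2")
  }
  bad <- is.na(tbl$lichtiger) | tbl$lichtiger < 0 | tbl$lichtiger > 21 |
    tbl$lichtiger != round(tbl$lichtiger)
  if (any(bad)) {
    f <- c(f, paste0("Lichtiger score out of 0-21 for sample(s): ",
                     paste(tbl$sample_id[bad], collapse = ", ")))
  }
  dup <- duplicated(tbl[, c("patient_id", "visit")])
  if (any(dup)) {
    f <- c(f, paste0("more than one sample per (patient, visit): ",
                     paste(unique(paste(tbl$patient_id[dup], tbl$visit[dup],
                                        sep = "/")), collapse = ", ")))
  }
  if (anyDuplicated(tbl$sample_id)) f <- c(f, "duplicate sample_id")
  fail_all(f, "sample metadata")
  tbl
}

#' Read a DNA FASTA file
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A tibble with columns `id` and `sequence` (uppercase, alphabet
#'   ACGTN), record order preserved.  Duplicate ids and empty sequences are
#'   errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for FASTA record(s): ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGTN symbols in FASTA record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write a DNA FASTA file
#'
#' @param records Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  lines <- purrr::map2(records$id, records$sequence, function(id, s) {
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), width),
                pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unlist(lines), con = con, useBytes = TRUE)
  invisible(path)
}
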