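#' Construct a species metabolic model
#'
#' A `gf_model` is a small genome-scale metabolic model: a set of metabolites
#' distributed over one shared extracellular compartment (`"lumen"`) and one
#' species cytosol (`"c:<species_id>"`), a set of bounded reactions given as
#' sparse stoichiometries, and exactly one biomass reaction whose flux is the
#' species' growth rate.  Exchange reactions move single lumen metabolites
#' across the system boundary; by convention they are written
#' `metabolite -> (out)` so that positive flux is outflow and a negative lower
#' bound permits uptake.
#'
#' @param species_id Scalar character identifier of the species.
#' @param metabolites Tibble/data frame with columns `id`, `name`,
#'   `compartment`.  Compartments must be `"lumen"` or `"c:<species_id>"`.
#' @param reactions Tibble/data frame with columns `id`, `stoichiometry`
#'   (list column of named numeric vectors, negative = consumed),
#'   `lower_bound`, `upper_bound`, `is_exchange`, `is_biomass`.
#' @param biomass_reaction_id Id of the single biomass reaction.
#'
#' @return A validated `gf_model` object.  Metabolites, reactions and
#'   stoichiometry keys are stored sorted by id so that two models with the
#'   same content are identical objects and serialise identically.
#' @seealso [read_model_json()], [write_model_json()], [validate_model()]
#' @export
metabolic_model <- function(species_id, metabolites, reactions,
                            biomass_reaction_id) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  model <- structure(
    list(
      species_id = species_id,
      metabolites = dplyr::arrange(metabolites, .data$id),
      reactions = dplyr::arrange(
        dplyr::mutate(
          reactions,
          stoichiometry = purrr::map(.data$stoichiometry, ~ .x[order(names(.x))])
        ),
        .data$id
      ),
      biomass_reaction_id = biomass_reaction_id
    ),
    class = "gf_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks every structural invariant of a [metabolic_model()]: unique
#' metabolite and reaction ids, well-formed compartment tags, resolvable and
#' non-zero stoichiometry entries, ordered finite-or-infinite bounds, exchange
#' reactions touching only lumen metabolites, and the presence of exactly one
#' biomass reaction matching `biomass_reaction_id`.  All violations are
#' reported together.
#'
#' @param model A `gf_model` object.
#' @return The model, invisibly, if valid; otherwise an error listing all
#'   violations.
#' @export
validate_model <- function(model) {
  f <- character()
  if (!is_scalar_chr(model$species_id) || !nzchar(model$species_id)) {
    f <- c(f, "species_id must be a non-empty string")
  }
  m <- model$metabolites
  r <- model$reactions
  need_m <- c("id", "name", "compartment")
  need_r <- c("id", "stoichiometry", "lower_bound", "upper_bound",
              "is_exchange", "is_biomass")
  if (!all(need_m %in% names(m))) {
    f <- c(f, paste0("metabolites must have columns ",
                     paste(need_m, collapse = ", ")))
    return(fail_all(f, "metabolic model"))
  }
  if (!all(need_r %in% names(r))) {
    f <- c(f, paste0("reactions must have columns ",
                     paste(need_r, collapse = ", ")))
    return(fail_all(f, "metabolic model"))
  }
  if (anyDuplicated(m$id)) {
    f <- c(f, paste0("duplicate metabolite id(s): ",
                     paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  }
  if (anyDuplicated(r$id)) {
    f <- c(f, paste0("duplicate reaction id(s): ",
                     paste(unique(r$id[duplicated(r$id)]), collapse = ", ")))
  }
  ok_comp <- m$compartment == "lumen" |
    m$compartment == paste0("c:", model$species_id)
  if (!all(ok_comp)) {
    f <- c(f, paste0("malformed compartment tag for metabolite(s): ",
                     paste(m$id[!ok_comp], collapse = ", ")))
  }
  if (nrow(r) == 0L) f <- c(f, "model has no reactions")
  lumen_ids <- m$id[m$compartment == "lumen"]
  for (i in seq_len(nrow(r))) {
    s <- r$stoichiometry[[i]]
    rid <- r$id[i]
    if (length(s) == 0L) {
      f <- c(f, paste0("reaction ", rid, " has empty stoichiometry"))
      next
    }
    if (is.null(names(s)) || any(!nzchar(names(s)))) {
      f <- c(f, paste0("reaction ", rid, " has unnamed stoichiometry entries"))
      next
    }
    if (any(s == 0)) {
      f <- c(f, paste0("reaction ", rid, " stores zero coefficients"))
    }
    missing <- setdiff(names(s), m$id)
    if (length(missing) > 0L) {
      f <- c(f, paste0("reaction ", rid, " references unknown metabolite(s): ",
                       paste(missing, collapse = ", ")))
    }
    if (isTRUE(r$is_exchange[i]) && !all(names(s) %in% lumen_ids)) {
      f <- c(f, paste0("exchange reaction ", rid,
                       " touches non-lumen metabolite(s)"))
    }
  }
  bad_bounds <- r$lower_bound > r$upper_bound
  if (any(bad_bounds)) {
    f <- c(f, paste0("lower_bound > upper_bound for reaction(s): ",
                     paste(r$id[bad_bounds], collapse = ", ")))
  }
  n_bio <- sum(r$is_biomass)
  if (n_bio != 1L) {
    f <- c(f, paste0("model must have exactly one biomass reaction, found ",
                     n_bio))
  }
  if (!model$biomass_reaction_id %in% r$id) {
    f <- c(f, paste0("biomass_reaction_id '", model$biomass_reaction_id,
                     "' not among reactions"))
  } else if (!isTRUE(r$is_biomass[r$id == model$biomass_reaction_id])) {
    f <- c(f, paste0("biomass_reaction_id '", model$biomass_reaction_id,
                     "' is not flagged is_biomass"))
  }
  fail_all(f, "metabolic model")
  invisible(model)
}

#' @exportS3Method base::print
print.gf_model <- function(x, ...) {
  cat("<gf_model> species", x$species_id, "\n")
  cat("  metabolites:", nrow(x$metabolites),
      "| reactions:", nrow(x$reactions),
      "| biomass:", x$biomass_reaction_id, "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model or community
#'
#' @param x A `gf_model` or `gf_community`.
#' @return A sparse `dgCMatrix` S with metabolites as rows and reactions as
#'   columns; `S v = 0` is the steady-state mass balance.
#' @export
stoichiometric_matrix <- function(x) {
  stopifnot(inherits(x, c("gf_model", "gf_community")))
  mets <- x$metabolites$id
  rxns <- x$reactions$id
  st <- x$reactions$stoichiometry
  ns <- lengths(st)
  Matrix::sparseMatrix(
    i = match(unlist(lapply(st, names), use.names = FALSE), mets),
    j = rep.int(seq_along(st), ns),
    x = unlist(st, use.names = FALSE),
    dims = c(length(mets), length(rxns)),
    dimnames = list(mets, rxns)
  )
}
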