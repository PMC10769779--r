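#' Filter and renormalise sample members by abundance
#'
#' Keeps taxa whose relative abundance is strictly greater than `threshold`
#' (default 0.1%), then renormalises the survivors' abundances to sum to 1 so
#' they can serve as community weights.  Order is deterministic: descending
#' weight, ties broken by taxon id.
#'
#' @param table Abundance tibble (`sample_id`, `taxon_id`, `rel_abundance`).
#' @param sample_id Sample to extract.
#' @param threshold Strict lower abundance cutoff on the original relative
#'   abundance (default `0.001`).
#' @return Tibble `taxon_id`, `weight` with `sum(weight) == 1`.
#' @export
filter_members <- function(table, sample_id, threshold = 0.001) {
  tbl <- dplyr::filter(as_tibble(table), .data$sample_id == !!sample_id)
  if (nrow(tbl) == 0L) {
    abort(paste0("sample not present in abundance table: ", sample_id))
  }
  kept <- dplyr::filter(tbl, .data$rel_abundance > threshold)
  if (nrow(kept) == 0L) {
    abort(paste0("empty community: no taxon above abundance threshold ",
                 threshold, " in sample ", sample_id))
  }
  kept |>
    dplyr::transmute(
      taxon_id = .data$taxon_id,
      weight = .data$rel_abundance / sum(.data$rel_abundance)
    ) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$taxon_id)
}

#' Merge species models into an abundance-coupled community model
#'
#' Builds a multispecies model sharing one extracellular lumen compartment:
#'
#' * each member's non-lumen metabolites and non-exchange reactions are
#'   namespaced with a `"<species_id>|"` prefix;
#' * lumen metabolites are pooled and deduplicated by id;
#' * member boundary exchange reactions are absorbed into one community
#'   exchange reaction per lumen metabolite (id `EX_<metabolite>`, written
#'   `metabolite -> (out)`, positive flux = outflow), whose bounds are the
#'   element-wise widest bounds over the members exchanging that metabolite
#'   (closed, `[0, 0]`, for lumen metabolites no member exchanges);
#' * each member's biomass flux is hard-coupled to the single community
#'   growth variable mu in proportion to its abundance weight:
#'   `v_biomass,i = w_i * mu`.
#'
#' @param models List of [metabolic_model()] objects with distinct species
#'   ids.
#' @param weights Numeric member weights in (0, 1], summing to 1 (tolerance
#'   1e-9); typically the output of [filter_members()].
#' @param sample_id Optional sample label carried on the community.
#' @return A `gf_community` object with fields `sample_id`, `members`,
#'   `metabolites`, `reactions`, `coupling` and `community_growth_id`.
#' @export
build_community <- function(models, weights, sample_id = NA_character_) {
  if (length(models) != length(weights)) {
    abort("models and weights must have the same length")
  }
  if (length(models) == 0L) abort("empty community: no member models")
  purrr::walk(models, validate_model)
  parts <- lapply(models, model_merge_parts)
  community_from_parts(parts, weights, sample_id = sample_id)
}

# Precompute everything about one member model that the merge needs and that
# does not depend on the sample: namespaced metabolites and non-exchange
# reactions, the biomass reaction id, and the outflow-oriented bounds of its
# boundary exchanges.  Registries are reused across many samples, so this is
# computed once per model (see registry_parts()).
model_merge_parts <- function(model) {
  sid <- model$species_id
  is_lumen <- model$metabolites$compartment == "lumen"
  lumen_ids <- model$metabolites$id[is_lumen]
  int_mets <- model$metabolites[!is_lumen, ]
  int_mets$id <- paste0(sid, "|", int_mets$id)

  ex <- model$reactions$is_exchange
  exr <- model$reactions[ex, ]
  ex_met <- character(nrow(exr)); ex_lb <- ex_ub <- numeric(nrow(exr))
  for (i in seq_len(nrow(exr))) {
    s <- exr$stoichiometry[[i]]
    if (length(s) != 1L) {
      abort(paste0("member ", sid, ": exchange reaction ", exr$id[i],
                   " must touch exactly one lumen metabolite"))
    }
    coef <- unname(s)
    # normalise to outflow-positive orientation with |coef| = 1
    lb <- exr$lower_bound[i] / abs(coef)
    ub <- exr$upper_bound[i] / abs(coef)
    if (coef > 0) { tmp <- lb; lb <- -ub; ub <- -tmp }
    ex_met[i] <- names(s); ex_lb[i] <- lb; ex_ub[i] <- ub
  }

  inr <- model$reactions[!ex, ]
  stoich <- lapply(inr$stoichiometry, function(s) {
    nm <- names(s)
    int <- !(nm %in% lumen_ids)
    names(s)[int] <- paste0(sid, "|", nm[int])
    s
  })
  list(
    species_id = sid,
    lumen_mets = model$metabolites[is_lumen, ],
    int_mets = int_mets,
    rxn_id = paste0(sid, "|", inr$id),
    stoich = stoich,
    lb = inr$lower_bound, ub = inr$upper_bound,
    is_biomass = inr$is_biomass,
    biomass_rxn = paste0(sid, "|", model$biomass_reaction_id),
    ex_met = ex_met, ex_lb = ex_lb, ex_ub = ex_ub
  )
}

# Validate a registry once and precompute merge parts for every model.
registry_parts <- function(registry) {
  purrr::walk(registry, validate_model)
  parts <- lapply(registry, model_merge_parts)
  names(parts) <- purrr::map_chr(registry, "species_id")
  parts
}

# Assemble a community from precomputed member parts (the hot path).
community_from_parts <- function(parts, weights, sample_id = NA_character_) {
  if (abs(sum(weights) - 1) > 1e-9) {
    abort(paste0("member weights must sum to 1, got ", sum(weights)))
  }
  if (any(weights <= 0)) abort("member weights must be positive")
  ids <- vapply(parts, `[[`, "", "species_id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate species_id among members: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  lumen <- dplyr::bind_rows(lapply(parts, `[[`, "lumen_mets"))
  lumen <- lumen[!duplicated(lumen$id), ]
  lumen <- lumen[order(lumen$id), ]

  ex_met <- unlist(lapply(parts, `[[`, "ex_met"), use.names = FALSE)
  ex_lb <- unlist(lapply(parts, `[[`, "ex_lb"), use.names = FALSE)
  ex_ub <- unlist(lapply(parts, `[[`, "ex_ub"), use.names = FALSE)
  # widest member bounds per lumen metabolite; [0, 0] if never exchanged
  lb_by_met <- tapply(ex_lb, ex_met, min)
  ub_by_met <- tapply(ex_ub, ex_met, max)
  exch_lb <- unname(ifelse(lumen$id %in% names(lb_by_met),
                           lb_by_met[lumen$id], 0))
  exch_ub <- unname(ifelse(lumen$id %in% names(ub_by_met),
                           ub_by_met[lumen$id], 0))

  int_rxn_id <- unlist(lapply(parts, `[[`, "rxn_id"), use.names = FALSE)
  rxn_tbl <- tibble::new_tibble(list(
    id = c(int_rxn_id, paste0("EX_", lumen$id)),
    stoichiometry = c(
      unlist(lapply(parts, `[[`, "stoich"), recursive = FALSE,
             use.names = FALSE),
      lapply(lumen$id, function(m) stats::setNames(-1, m))
    ),
    lower_bound = c(unlist(lapply(parts, `[[`, "lb"), use.names = FALSE),
                    exch_lb),
    upper_bound = c(unlist(lapply(parts, `[[`, "ub"), use.names = FALSE),
                    exch_ub),
    is_exchange = c(rep(FALSE, length(int_rxn_id)), rep(TRUE, nrow(lumen))),
    is_biomass = c(unlist(lapply(parts, `[[`, "is_biomass"),
                          use.names = FALSE),
                   rep(FALSE, nrow(lumen)))
  ), nrow = length(int_rxn_id) + nrow(lumen))
  structure(
    list(
      sample_id = sample_id,
      members = tibble::new_tibble(
        list(species_id = unname(ids), weight = unname(weights)),
        nrow = length(ids)
      ),
      metabolites = dplyr::bind_rows(
        dplyr::bind_rows(lapply(parts, `[[`, "int_mets")), lumen
      ),
      reactions = rxn_tbl,
      coupling = tibble::new_tibble(list(
        species_id = unname(ids),
        reaction_id = unname(vapply(parts, `[[`, "", "biomass_rxn")),
        weight = unname(weights)
      ), nrow = length(ids)),
      community_growth_id = "community_biomass"
    ),
    class = "gf_community"
  )
}

#' @exportS3Method base::print
print.gf_community <- function(x, ...) {
  cat("<gf_community>", if (!is.na(x$sample_id)) x$sample_id else "", "\n")
  cat("  members:", nrow(x$members),
      "| metabolites:", nrow(x$metabolites),
      "| reactions:", nrow(x$reactions), "\n")
  invisible(x)
}

#' Validate a community model
#'
#' Checks the structural invariants of a [build_community()] result: member
#' weights sum to 1, metabolite and reaction ids are unique, every
#' stoichiometry entry resolves to a metabolite, bounds are ordered, each
#' member contributes exactly one coupled biomass reaction, and exchange
#' reactions touch only lumen-side metabolites.  Failures are reported, not
#' raised.
#'
#' @param cm A `gf_community`.
#' @return A tibble `check`, `ok`, `detail`; an all-`TRUE` `ok` column means
#'   the community is valid.
#' @export
validate_community <- function(cm) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, ok = ok,
                                             detail = detail)
  }
  wsum <- sum(cm$members$weight)
  add("weights_normalized", abs(wsum - 1) <= 1e-9,
      if (abs(wsum - 1) > 1e-9) paste0("weights not normalized: sum = ", wsum)
      else "")
  add("weights_positive", all(cm$members$weight > 0), "")
  dup_m <- anyDuplicated(cm$metabolites$id) > 0
  add("metabolite_ids_unique", !dup_m,
      if (dup_m) paste("duplicate:",
                       cm$metabolites$id[duplicated(cm$metabolites$id)][1])
      else "")
  dup_r <- anyDuplicated(cm$reactions$id) > 0
  add("reaction_ids_unique", !dup_r, "")
  dangling <- setdiff(unique(unlist(purrr::map(cm$reactions$stoichiometry,
                                               names))),
                      cm$metabolites$id)
  add("stoichiometry_resolves", length(dangling) == 0L,
      if (length(dangling) > 0L) paste0("dangling metabolite id(s): ",
                                        paste(dangling, collapse = ", "))
      else "")
  add("bounds_ordered",
      all(cm$reactions$lower_bound <= cm$reactions$upper_bound), "")
  add("coupling_complete",
      nrow(cm$coupling) == nrow(cm$members) &&
        setequal(cm$coupling$species_id, cm$members$species_id) &&
        all(cm$coupling$reaction_id %in% cm$reactions$id), "")
  dplyr::bind_rows(checks)
}

#' Serialise a community model to JSON
#'
#' Uses the species-model schema plus a `community` extensions block holding
#' the member weights, the biomass coupling and the community growth
#' variable id.  [read_community_json()] restores the object.
#'
#' @param cm A `gf_community`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_json <- function(cm, path) {
  rxns <- purrr::pmap(
    cm$reactions[, c("id", "stoichiometry", "lower_bound", "upper_bound",
                     "is_exchange", "is_biomass")],
    function(id, stoichiometry, lower_bound, upper_bound, is_exchange,
             is_biomass) {
      list(id = id, is_biomass = is_biomass, is_exchange = is_exchange,
           lower_bound = lower_bound,
           stoichiometry = as.list(stoichiometry[order(names(stoichiometry))]),
           upper_bound = upper_bound)
    }
  )
  obj <- list(
    community = list(
      community_growth_id = cm$community_growth_id,
      coupling = purrr::pmap(cm$coupling, function(species_id, reaction_id,
                                                   weight) {
        list(reaction_id = reaction_id, species_id = species_id,
             weight = weight)
      }),
      members = purrr::pmap(cm$members, function(species_id, weight) {
        list(species_id = species_id, weight = weight)
      }),
      sample_id = cm$sample_id
    ),
    metabolites = purrr::pmap(cm$metabolites[, c("id", "name", "compartment")],
                              function(id, name, compartment) {
      list(compartment = compartment, id = id, name = name)
    }),
    reactions = rxns
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = 2, null = "null"),
             con = con, useBytes = TRUE)
  invisible(path)
}

#' Read a community model from JSON
#'
#' @param path Path written by [write_community_json()].
#' @return A `gf_community`.
#' @export
read_community_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$community)) {
    abort(paste0("not a community model (no 'community' block): ", path))
  }
  mets <- purrr::map_dfr(raw$metabolites, function(m) {
    tibble(id = m$id, name = m$name %||% "", compartment = m$compartment)
  })
  rxns <- purrr::map_dfr(raw$reactions, function(r) {
    tibble(id = r$id, stoichiometry = list(unlist(r$stoichiometry)),
           lower_bound = as.numeric(r$lower_bound),
           upper_bound = as.numeric(r$upper_bound),
           is_exchange = isTRUE(r$is_exchange),
           is_biomass = isTRUE(r$is_biomass))
  })
  structure(
    list(
      sample_id = raw$community$sample_id %||% NA_character_,
      members = purrr::map_dfr(raw$community$members, function(m) {
        tibble(species_id = m$species_id, weight = as.numeric(m$weight))
      }),
      metabolites = mets,
      reactions = rxns,
      coupling = purrr::map_dfr(raw$community$coupling, function(cp) {
        tibble(species_id = cp$species_id, reaction_id = cp$reaction_id,
               weight = as.numeric(cp$weight))
      }),
      community_growth_id = raw$community$community_growth_id
    ),
    class = "gf_community"
  )
}
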