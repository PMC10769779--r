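#' Simulation configuration for a synthetic two-visit cohort
#'
#' The defaults mirror the study design the pipeline targets: 93 patients
#' with active ulcerative colitis sampled before corticosteroid therapy (V1),
#' 69 of whom respond by week 4 (V2); 85 V2 samples remain after dropout
#' (63 responders, 22 nonresponders).  Responder communities gain
#' `producer_enrichment_delta` of absolute abundance mass on
#' butyrate-producing taxa at V2 on top of a common compositional drift;
#' nonresponders only drift.
#'
#' @param n_responders,n_nonresponders Patients per response group
#'   (defaults 69 and 24).
#' @param v2_retained Named counts of patients per group with a V2 microbiome
#'   sample (defaults `c(responders = 63, nonresponders = 22)`); clinical
#'   Lichtiger scores exist at both visits for everyone.
#' @param n_species Number of species in the synthetic registry (default 20).
#' @param fraction_producers Fraction of species that are butyrate producers
#'   (default 0.4).
#' @param producer_enrichment_delta Absolute abundance mass moved onto
#'   producer taxa at V2 in responders (default 0.15); 0 gives a null cohort
#'   in which the groups are exchangeable.
#' @param abundance_concentration Dirichlet concentration of baseline
#'   abundances (default 1, a flat simplex prior).
#' @param v2_jitter_concentration Concentration of the Dirichlet drift from
#'   V1 to V2 (default 100: V2 is centred on V1 with a standard deviation of
#'   roughly 5 percentage points on a 40% abundance share, a modest
#'   week-scale compositional change).
#' @param seq_length Length of the synthetic 16S stand-in sequences
#'   (default 250 nt).
#' @param mutation_rate_within Per-site substitution rate between a species'
#'   reference sequence and its OTU representative (default 0.01, keeping
#'   OTUs above the 97% identity threshold by construction).
#' @param seed Integer master seed; every random stream is derived from it.
#' @return A validated list of class `gf_sim_config`.
#' @export
sim_config <- function(n_responders = 69, n_nonresponders = 24,
                       v2_retained = c(responders = 63, nonresponders = 22),
                       n_species = 20, fraction_producers = 0.4,
                       producer_enrichment_delta = 0.15,
                       abundance_concentration = 1,
                       v2_jitter_concentration = 100,
                       seq_length = 250, mutation_rate_within = 0.01,
                       seed = 1) {
  cfg <- structure(
    list(n_responders = n_responders, n_nonresponders = n_nonresponders,
         v2_retained = v2_retained, n_species = n_species,
         fraction_producers = fraction_producers,
         producer_enrichment_delta = producer_enrichment_delta,
         abundance_concentration = abundance_concentration,
         v2_jitter_concentration = v2_jitter_concentration,
         seq_length = seq_length,
         mutation_rate_within = mutation_rate_within,
         seed = seed),
    class = "gf_sim_config"
  )
  f <- character()
  pos_int <- function(x) is_scalar_num(x) && x >= 1 && x == round(x)
  if (!pos_int(cfg$n_responders)) f <- c(f, "n_responders must be a positive integer")
  if (!pos_int(cfg$n_nonresponders)) f <- c(f, "n_nonresponders must be a positive integer")
  if (length(cfg$v2_retained) != 2L ||
      !all(c("responders", "nonresponders") %in% names(cfg$v2_retained))) {
    f <- c(f, "v2_retained must be named counts for responders and nonresponders")
  } else {
    if (cfg$v2_retained[["responders"]] > cfg$n_responders ||
        cfg$v2_retained[["nonresponders"]] > cfg$n_nonresponders ||
        any(cfg$v2_retained < 0)) {
      f <- c(f, "v2_retained counts must be between 0 and the group sizes")
    }
  }
  if (!pos_int(cfg$n_species) || cfg$n_species < 2) {
    f <- c(f, "n_species must be an integer >= 2")
  }
  in01 <- function(x) is_scalar_num(x) && x >= 0 && x <= 1
  if (!in01(cfg$fraction_producers)) f <- c(f, "fraction_producers must be in [0, 1]")
  if (!in01(cfg$producer_enrichment_delta)) {
    f <- c(f, "producer_enrichment_delta must be in [0, 1]")
  }
  if (!is_scalar_num(cfg$abundance_concentration) ||
      cfg$abundance_concentration <= 0) {
    f <- c(f, "abundance_concentration must be positive")
  }
  if (!is_scalar_num(cfg$v2_jitter_concentration) ||
      cfg$v2_jitter_concentration <= 0) {
    f <- c(f, "v2_jitter_concentration must be positive")
  }
  if (!pos_int(cfg$seq_length) || cfg$seq_length < 20) {
    f <- c(f, "seq_length must be an integer >= 20")
  }
  if (!in01(cfg$mutation_rate_within)) {
    f <- c(f, "mutation_rate_within must be in [0, 1]")
  }
  if (!is_scalar_num(cfg$seed)) f <- c(f, "seed must be a number")
  fail_all(f, "simulation config")
  cfg
}

# Toy model templates -----------------------------------------------------
#
# Producers instantiate an obligate butyrate co-production stoichiometry:
# one unit of glucose yields one biomass unit plus one unit of butyrate, so
# community butyrate capacity tracks producer abundance deterministically.
# Non-producers grow on glucose without the co-product.

#' Toy butyrate-producer species model
#'
#' Lumen metabolites `glc` and `but`; reactions: glucose exchange
#' `EX_glc` with bounds `[-uptake, 0]`, transporter `T_glc`, biomass
#' reaction `GROW` converting cytosolic glucose into one biomass unit plus
#' one cytosolic butyrate, transporter `T_but`, and butyrate exchange
#' `EX_but` with bounds `[0, 1000]`.
#'
#' @param species_id Species id (default `"S1"`).
#' @param uptake Maximal glucose uptake (default 10).
#' @return A [metabolic_model()].
#' @export
producer_model <- function(species_id = "S1", uptake = 10) {
  cyt <- paste0("c:", species_id)
  metabolic_model(
    species_id = species_id,
    metabolites = tibble(
      id = c("glc", "but", "glc_c", "but_c"),
      name = c("glucose (lumen)", "butyrate (lumen)",
               "glucose (cytosol)", "butyrate (cytosol)"),
      compartment = c("lumen", "lumen", cyt, cyt)
    ),
    reactions = tibble(
      id = c("EX_glc", "T_glc", "GROW", "T_but", "EX_but"),
      stoichiometry = list(
        c(glc = -1),
        c(glc = -1, glc_c = 1),
        c(glc_c = -1, but_c = 1),
        c(but_c = -1, but = 1),
        c(but = -1)
      ),
      lower_bound = c(-uptake, 0, 0, 0, 0),
      upper_bound = c(0, 1000, 1000, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE, FALSE, TRUE),
      is_biomass = c(FALSE, FALSE, TRUE, FALSE, FALSE)
    ),
    biomass_reaction_id = "GROW"
  )
}

#' Toy non-producer species model
#'
#' Grows on lumen glucose with no butyrate co-production: glucose exchange
#' `EX_glc` `[-uptake, 0]`, transporter `T_glc`, biomass reaction `GROW`.
#'
#' @param species_id Species id (default `"S2"`).
#' @param uptake Maximal glucose uptake (default 10).
#' @return A [metabolic_model()].
#' @export
nonproducer_model <- function(species_id = "S2", uptake = 10) {
  cyt <- paste0("c:", species_id)
  metabolic_model(
    species_id = species_id,
    metabolites = tibble(
      id = c("glc", "glc_c"),
      name = c("glucose (lumen)", "glucose (cytosol)"),
      compartment = c("lumen", cyt)
    ),
    reactions = tibble(
      id = c("EX_glc", "T_glc", "GROW"),
      stoichiometry = list(
        c(glc = -1),
        c(glc = -1, glc_c = 1),
        c(glc_c = -1)
      ),
      lower_bound = c(-uptake, 0, 0),
      upper_bound = c(0, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE),
      is_biomass = c(FALSE, FALSE, TRUE)
    ),
    biomass_reaction_id = "GROW"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) {
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  }
  paste(s, collapse = "")
}

#' Generate a registry of toy species models with reference 16S sequences
#'
#' The first `round(n_species * fraction_producers)` species instantiate the
#' butyrate-producer template, the rest the non-producer template; each
#' species draws a glucose uptake capacity uniformly from `uptake_range` and
#' a random reference 16S stand-in sequence.
#'
#' @param n_species Number of species (>= 2).
#' @param fraction_producers Fraction of producer species.
#' @param seed Integer seed (stream-derived internally).
#' @param seq_length Reference sequence length (default 250).
#' @param uptake_range Uniform range of glucose uptake capacities
#'   (default `c(5, 15)`).
#' @return A list of class `gf_registry`: `registry` (named list of models),
#'   `references` (tibble `id`, `sequence`), `species` (tibble `species_id`,
#'   `is_producer`, `uptake`).
#' @export
make_species_models <- function(n_species = 20, fraction_producers = 0.4,
                                seed = 1, seq_length = 250,
                                uptake_range = c(5, 15)) {
  if (!is_scalar_num(n_species) || n_species < 2) {
    abort("n_species must be at least 2")
  }
  n_prod <- round(n_species * fraction_producers)
  withr_seed <- derive_seed(seed, "species_models")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  ids <- sprintf("sp%03d", seq_len(n_species))
  uptake <- stats::runif(n_species, uptake_range[1], uptake_range[2])
  is_producer <- seq_len(n_species) <= n_prod
  registry <- purrr::pmap(
    list(ids, is_producer, uptake),
    function(id, prod, u) {
      if (prod) producer_model(id, uptake = u) else {
        nonproducer_model(id, uptake = u)
      }
    }
  )
  names(registry) <- ids
  refs <- tibble(
    id = ids,
    sequence = purrr::map_chr(seq_len(n_species), ~ random_dna(seq_length))
  )
  structure(
    list(registry = registry,
         references = refs,
         species = tibble(species_id = ids, is_producer = is_producer,
                          uptake = uptake)),
    class = "gf_registry"
  )
}

# Move `delta` absolute abundance mass proportionally from non-producers
# onto producers; if non-producer mass is smaller than delta, move what is
# available.
shift_to_producers <- function(w, is_producer, delta) {
  p_mass <- sum(w[is_producer])
  np_mass <- sum(w[!is_producer])
  shift <- min(delta, np_mass)
  if (shift <= 0 || p_mass <= 0) return(w)
  w[!is_producer] <- w[!is_producer] * (1 - shift / np_mass)
  w[is_producer] <- w[is_producer] * (1 + shift / p_mass)
  w / sum(w)
}

#' Generate a synthetic two-visit cohort
#'
#' Per patient, V1 abundances are drawn from a symmetric Dirichlet; V2
#' abundances are a Dirichlet drift of V1 (concentration
#' `v2_jitter_concentration`, mean V1) applied to *all* patients, after
#' which responders additionally have `producer_enrichment_delta` of
#' abundance mass moved proportionally onto producer taxa.  With
#' `producer_enrichment_delta = 0` the two groups are therefore
#' exchangeable.  Lichtiger scores are generated so that the response label
#' matches the group: responders draw V1 from 8-14 and
#' `V2 = floor(V1 * (1 - u))` with `u ~ U[0.5, 0.9]` (decrease >= 50% by
#' construction); nonresponders use `u ~ U[0, 0.4]` and a ceiling
#' (decrease <= 40%).  OTU representative sequences are the species
#' reference sequences mutated at `mutation_rate_within` per site, so they
#' remain mappable at the 97%/95% thresholds by construction.  A subset of
#' patients per group (config `v2_retained`) keeps a V2 microbiome sample;
#' every patient keeps clinical scores at both visits.
#'
#' @param config A [sim_config()].
#' @param registry_obj A `gf_registry` from [make_species_models()].
#' @return A list of class `gf_cohort`: `abundances` (tibble keyed by OTU
#'   id), `metadata`, `otus` (tibble `id`, `sequence`), `otu_truth`
#'   (tibble `taxon_id`, `species_id` ground-truth mapping), and the config.
#' @export
make_cohort <- function(config, registry_obj) {
  stopifnot(inherits(config, "gf_sim_config"),
            inherits(registry_obj, "gf_registry"))
  sp <- registry_obj$species
  if (config$producer_enrichment_delta > 0 && !any(sp$is_producer)) {
    abort("planted producer enrichment requested but registry has no producers")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "cohort"))

  n_r <- config$n_responders
  n_n <- config$n_nonresponders
  n_pat <- n_r + n_n
  patients <- sprintf("P%03d", seq_len(n_pat))
  group <- c(rep("responder", n_r), rep("nonresponder", n_n))
  keep_v2 <- c(
    patients[sample.int(n_r, config$v2_retained[["responders"]])],
    patients[n_r + sample.int(n_n, config$v2_retained[["nonresponders"]])]
  )

  k <- nrow(sp)
  otu_ids <- sprintf("OTU%03d", seq_len(k))
  otus <- tibble(
    id = otu_ids,
    sequence = purrr::map_chr(registry_obj$references$sequence,
                              mutate_dna, rate = config$mutation_rate_within)
  )
  otu_truth <- tibble(taxon_id = otu_ids, species_id = sp$species_id)

  # abundances: V1 ~ Dirichlet, V2 = Dirichlet drift of V1 (all patients),
  # plus the producer shift in responders; drawn as matrices per visit
  w1 <- matrix(stats::rgamma(n_pat * k, shape = config$abundance_concentration),
               n_pat, k)
  w1 <- w1 / rowSums(w1)
  w2 <- matrix(stats::rgamma(n_pat * k,
                             shape = config$v2_jitter_concentration *
                               pmax(w1, 1e-12)),
               n_pat, k)
  w2 <- w2 / rowSums(w2)
  if (config$producer_enrichment_delta > 0) {
    for (p in which(group == "responder")) {
      w2[p, ] <- shift_to_producers(w2[p, ], sp$is_producer,
                                    config$producer_enrichment_delta)
    }
  }

  # Lichtiger dynamics: only there to exercise the response labelling
  l1 <- sample(8:14, n_pat, replace = TRUE)
  is_resp <- group == "responder"
  u <- ifelse(is_resp, stats::runif(n_pat, 0.5, 0.9),
              stats::runif(n_pat, 0, 0.4))
  l2 <- ifelse(is_resp, floor(l1 * (1 - u)), ceiling(l1 * (1 - u)))

  metadata <- tibble(
    sample_id = c(paste0(patients, "_V1"), paste0(patients, "_V2")),
    patient_id = rep(patients, 2L),
    visit = rep(c("V1", "V2"), each = n_pat),
    lichtiger = as.integer(c(l1, l2))
  )
  has_v2 <- patients %in% keep_v2
  abundances <- tibble::new_tibble(list(
    sample_id = c(rep(paste0(patients, "_V1"), each = k),
                  rep(paste0(patients[has_v2], "_V2"), each = k)),
    taxon_id = c(rep(otu_ids, n_pat), rep(otu_ids, sum(has_v2))),
    rel_abundance = c(as.vector(t(w1)),
                      as.vector(t(w2[has_v2, , drop = FALSE])))
  ), nrow = (n_pat + sum(has_v2)) * k)
  structure(
    list(abundances = abundances,
         metadata = metadata,
         otus = otus,
         otu_truth = otu_truth,
         config = config),
    class = "gf_cohort"
  )
}

#' Check the planted producer-enrichment effect of a synthetic cohort
#'
#' Computes, per response group, the mean change from V1 to V2 in total
#' producer abundance (ground-truth producer taxa) over patients with both
#' samples.  In responders the mean shift estimates
#' `producer_enrichment_delta`; in nonresponders it is centred at 0.
#'
#' @param cohort A `gf_cohort`.
#' @param registry_obj The `gf_registry` the cohort was generated from.
#' @return Tibble `group`, `mean_shift`, `n_pairs`.
#' @export
planted_effect_check <- function(cohort, registry_obj) {
  sp <- registry_obj$species
  producers <- cohort$otu_truth$taxon_id[
    match(sp$species_id[sp$is_producer], cohort$otu_truth$species_id)]
  share <- cohort$abundances |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      producer_share = sum(.data$rel_abundance[.data$taxon_id %in% producers]),
      .groups = "drop"
    ) |>
    dplyr::inner_join(cohort$metadata, by = "sample_id")
  scores <- cohort$metadata |>
    dplyr::select("patient_id", "visit", "lichtiger") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "lichtiger")
  grp <- tibble(patient_id = scores$patient_id,
                group = label_response(scores$V1, scores$V2))
  share |>
    dplyr::select("patient_id", "visit", "producer_share") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "producer_share") |>
    dplyr::filter(!is.na(.data$V1), !is.na(.data$V2)) |>
    dplyr::inner_join(grp, by = "patient_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_shift = mean(.data$V2 - .data$V1),
                     n_pairs = dplyr::n(), .groups = "drop")
}

# Save/restore .Random.seed so generator calls do not disturb the caller's
# RNG state.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
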