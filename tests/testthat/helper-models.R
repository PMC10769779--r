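# Shared toy fixtures, built in code.

toy_producer <- function(id = "S1", uptake = 10) producer_model(id, uptake)
toy_nonproducer <- function(id = "S2", uptake = 10) nonproducer_model(id, uptake)

# Producer variant with a redundant two-step export pathway for butyrate in
# parallel to the direct transporter: pFBA must leave the longer path unused.
toy_redundant_producer <- function(id = "S3", uptake = 10) {
  cyt <- paste0("c:", id)
  metabolic_model(
    species_id = id,
    metabolites = tibble::tibble(
      id = c("glc", "but", "glc_c", "but_c", "but_x"),
      name = c("glucose (lumen)", "butyrate (lumen)", "glucose (cytosol)",
               "butyrate (cytosol)", "butyrate (carrier-bound)"),
      compartment = c("lumen", "lumen", cyt, cyt, cyt)
    ),
    reactions = tibble::tibble(
      id = c("EX_glc", "T_glc", "GROW", "T_but", "T_but_a", "T_but_b",
             "EX_but"),
      stoichiometry = list(
        c(glc = -1),
        c(glc = -1, glc_c = 1),
        c(glc_c = -1, but_c = 1),
        c(but_c = -1, but = 1),
        c(but_c = -1, but_x = 1),
        c(but_x = -1, but = 1),
        c(but = -1)
      ),
      lower_bound = c(-uptake, 0, 0, 0, 0, 0, 0),
      upper_bound = c(0, 1000, 1000, 1000, 1000, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
      is_biomass = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
    ),
    biomass_reaction_id = "GROW"
  )
}

# A small random community drawn from a synthetic registry: member subset,
# Dirichlet weights.  Returns list(models, weights).
random_community <- function(registry_obj, max_members = 20) {
  n <- length(registry_obj$registry)
  k <- sample(2:min(max_members, n), 1)
  idx <- sample(n, k)
  g <- stats::rgamma(k, shape = 1)
  list(models = registry_obj$registry[idx], weights = g / sum(g))
}

# Largest mass-balance residual of a flux solution on a community.
mass_balance_residual <- function(cm, sol) {
  S <- stoichiometric_matrix(cm)
  max(abs(as.vector(S %*% sol$fluxes[colnames(S)])))
}

coupling_residual <- function(cm, sol) {
  max(abs(sol$fluxes[cm$coupling$reaction_id] -
            cm$coupling$weight * sol$mu))
}
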