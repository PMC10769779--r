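#' Formulate the parsimonious FBA linear program for a community
#'
#' Every reaction flux is split into two non-negative variables,
#' `v = v+ - v-`, which makes the total absolute flux `sum(v+ + v-)` linear.
#' The LP maximises
#'
#'   `mu - parsimony_coef * sum_j (v+_j + v-_j)`
#'
#' subject to steady-state mass balance `S (v+ - v-) = 0` for every
#' metabolite (lumen metabolites balance species transfers against community
#' exchanges), hard proportional biomass coupling
#' `v_biomass,i - w_i * mu = 0` for every member, split-variable bounds
#' derived from the reaction bounds, and `mu >= 0`.  The default penalty
#' `1e-5` is small enough that growth is not sacrificed on desk-scale models,
#' but breaks ties among alternative optima in favour of the least total
#' flux.
#'
#' @param cm A validated `gf_community` (see [build_community()]).
#' @param parsimony_coef Non-negative scaling of the total-flux penalty
#'   (default `1e-5`; `0` gives plain community FBA).
#' @param validate Run [validate_community()] first (default `TRUE`; internal
#'   callers that assemble communities from a pre-validated registry skip
#'   it).
#' @return An object of class `gf_lp` holding the variable ids, objective,
#'   sparse constraint matrix, bounds, and the reaction/variable index maps.
#' @export
formulate_pfba <- function(cm, parsimony_coef = 1e-5, validate = TRUE) {
  if (!is_scalar_num(parsimony_coef) || parsimony_coef < 0) {
    abort("parsimony_coef must be a single non-negative number")
  }
  if (isTRUE(validate)) {
    bad <- validate_community(cm)
    if (!all(bad$ok)) {
      abort(paste0("invalid community model:\n",
                   paste0("  - ", bad$detail[!bad$ok & nzchar(bad$detail)],
                          collapse = "\n")))
    }
  }
  if (nrow(cm$coupling) == 0L) {
    abort("community has no biomass coupling; cannot define community growth")
  }
  n <- nrow(cm$reactions)
  rxn_ids <- cm$reactions$id
  # variables: v+ (1..n), v- (n+1..2n), mu (2n+1)
  nv <- 2L * n + 1L
  mets <- cm$metabolites$id
  n_m <- length(mets)
  st <- cm$reactions$stoichiometry
  ns <- lengths(st)
  met_i <- match(unlist(lapply(st, names), use.names = FALSE), mets)
  j_rxn <- rep.int(seq_len(n), ns)
  vals <- unlist(st, use.names = FALSE)
  cp_i <- match(cm$coupling$reaction_id, rxn_ids)
  m_cp <- nrow(cm$coupling)
  # rows: mass balance S(v+ - v-) = 0, then coupling v_bio,i - w_i mu = 0
  A <- Matrix::sparseMatrix(
    i = c(met_i, met_i, n_m + seq_len(m_cp), n_m + seq_len(m_cp),
          n_m + seq_len(m_cp)),
    j = c(j_rxn, n + j_rxn, cp_i, n + cp_i, rep(nv, m_cp)),
    x = c(vals, -vals, rep(1, m_cp), rep(-1, m_cp), -cm$coupling$weight),
    dims = c(n_m + m_cp, nv),
    dimnames = list(c(mets, paste0("coupling|", cm$coupling$species_id)),
                    NULL),
    repr = "T"
  )
  lb <- cm$reactions$lower_bound
  ub <- cm$reactions$upper_bound
  structure(
    list(
      var_ids = c(paste0(rxn_ids, "+"), paste0(rxn_ids, "-"),
                  cm$community_growth_id),
      objective = c(rep(-parsimony_coef, 2L * n), 1),
      A = A,
      var_lb = c(pmax(lb, 0), pmax(-ub, 0), 0),
      var_ub = c(pmax(ub, 0), pmax(-lb, 0), Inf),
      reaction_ids = rxn_ids,
      mu_index = nv,
      parsimony_coef = parsimony_coef,
      sample_id = cm$sample_id
    ),
    class = "gf_lp"
  )
}

#' @exportS3Method base::print
print.gf_lp <- function(x, ...) {
  cat("<gf_lp>", length(x$var_ids), "variables,", nrow(x$A),
      "equality constraints, parsimony", x$parsimony_coef, "\n")
  invisible(x)
}

# Serialise an LP (maximise c'x, A x = 0, lb <= x <= ub) to CPLEX LP format.
# Variables are emitted as x1..xn; glpsol's plain-text solution file is read
# back by column index.
write_lp_file <- function(lp, path) {
  nv <- length(lp$objective)
  xn <- paste0("x", seq_len(nv))
  # every variable appears in the objective (zero coefficients included):
  # glpsol numbers columns by first appearance, and the solution file is
  # read back by that index
  obj_terms <- sprintf("%+.17g %s", lp$objective, xn)
  A <- methods::as(lp$A, "TsparseMatrix")
  row_of <- A@i + 1L
  term <- sprintf("%+.17g x%d", A@x, A@j + 1L)
  terms_by_row <- split(term, row_of)
  rows <- vapply(
    seq_len(nrow(lp$A)),
    function(i) {
      tt <- terms_by_row[[as.character(i)]]
      if (is.null(tt)) "0 x1 = 0" else paste(paste(tt, collapse = " "), "= 0")
    },
    character(1)
  )
  bounds <- character(nv)
  fin_ub <- is.finite(lp$var_ub)
  lbv <- lp$var_lb + 0   # + 0 normalises IEEE negative zero, which the
  ubv <- lp$var_ub + 0   # LP-format reader does not accept as a bound
  bounds[fin_ub] <- sprintf("%.17g <= %s <= %.17g",
                            lbv[fin_ub], xn[fin_ub], ubv[fin_ub])
  bounds[!fin_ub] <- sprintf("%s >= %.17g", xn[!fin_ub], lbv[!fin_ub])
  writeLines(c(
    "Maximize",
    paste(" obj:", paste(obj_terms, collapse = " ")),
    "Subject To",
    paste0(" r", seq_along(rows), ": ", rows),
    "Bounds",
    paste0(" ", bounds),
    "End"
  ), path)
  invisible(path)
}

# Run glpsol on an LP file and parse the plain-text solution file.
run_glpsol <- function(lp_path, sol_path) {
  status <- suppressWarnings(system2(
    "glpsol", c("--lp", shQuote(lp_path), "-w", shQuote(sol_path)),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0L || !file.exists(sol_path)) {
    abort("glpsol failed to run; is GLPK installed and on the PATH?")
  }
  lines <- readLines(sol_path)
  sline <- strsplit(lines[startsWith(lines, "s ")][1], " +")[[1]]
  # s bas <m> <n> <pstat> <dstat> <obj>
  pstat <- sline[5]; dstat <- sline[6]
  obj <- as.numeric(sline[7])
  jl <- lines[startsWith(lines, "j ")]
  jt <- strsplit(jl, " +")
  x <- numeric(length(jt))
  for (rec in jt) x[as.integer(rec[2])] <- as.numeric(rec[4])
  status <- if (pstat == "f" && dstat == "f") {
    "optimal"
  } else if (pstat == "n") {
    "infeasible"
  } else if (dstat == "n") {
    "unbounded"
  } else {
    "infeasible"
  }
  list(status = status, objective = obj, x = x)
}

#' Solve a parsimonious FBA problem
#'
#' Solves the LP built by [formulate_pfba()] with the GLPK simplex solver
#' (`glpsol`), recombines the split variables into signed reaction fluxes,
#' and classifies the outcome.  An optimal solution whose community growth
#' rate is numerically zero (`mu <= 1e-10`) is reported as `zero_growth`.
#' Solver-declared infeasibility or unboundedness is returned as a status,
#' never raised as an error.
#'
#' @param lp A `gf_lp` from [formulate_pfba()].
#' @return An object of class `gf_flux` with `fluxes` (named by reaction id),
#'   `mu`, `objective`, `status` and `sample_id`.
#' @export
solve_pfba <- function(lp) {
  stopifnot(inherits(lp, "gf_lp"))
  lp_path <- tempfile(fileext = ".lp")
  sol_path <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lp_path, sol_path)))
  write_lp_file(lp, lp_path)
  res <- run_glpsol(lp_path, sol_path)
  n <- length(lp$reaction_ids)
  if (res$status != "optimal") {
    return(structure(
      list(fluxes = stats::setNames(rep(NA_real_, n), lp$reaction_ids),
           mu = NA_real_, objective = NA_real_, status = res$status,
           sample_id = lp$sample_id),
      class = "gf_flux"
    ))
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  mu <- res$x[lp$mu_index]
  structure(
    list(
      fluxes = stats::setNames(v, lp$reaction_ids),
      mu = mu,
      objective = res$objective,
      status = if (mu <= 1e-10) "zero_growth" else "optimal",
      sample_id = lp$sample_id
    ),
    class = "gf_flux"
  )
}

#' @exportS3Method base::print
print.gf_flux <- function(x, ...) {
  cat("<gf_flux>", x$status, "| mu =", format(x$mu), "| objective =",
      format(x$objective), "\n")
  invisible(x)
}

#' Butyrate production rate of a flux solution
#'
#' The butyrate production rate is the outflow of butyrate through the
#' community exchange reaction divided by the community biomass production
#' rate mu (outflow-positive sign convention).  When growth is numerically
#' zero (`mu <= 1e-10`) the ratio is undefined and `NA` is returned with a
#' message; such samples are excluded from downstream statistics rather than
#' treated as zero producers.
#'
#' @param sol A `gf_flux` solution.
#' @param butyrate_exchange_id Id of the community butyrate exchange reaction
#'   (default `"EX_but"`).
#' @return A single number, or `NA_real_` when undefined.
#' @export
butyrate_rate <- function(sol, butyrate_exchange_id = "EX_but") {
  stopifnot(inherits(sol, "gf_flux"))
  if (!butyrate_exchange_id %in% names(sol$fluxes)) {
    abort(paste0("unknown exchange reaction: ", butyrate_exchange_id))
  }
  if (sol$status == "zero_growth" || (!is.na(sol$mu) && sol$mu <= 1e-10)) {
    inform(paste0("butyrate rate undefined: community growth is zero",
                  if (!is.na(sol$sample_id)) paste0(" (sample ",
                                                    sol$sample_id, ")")))
    return(NA_real_)
  }
  if (sol$status != "optimal") {
    return(NA_real_)
  }
  unname(sol$fluxes[butyrate_exchange_id] / sol$mu)
}

#' Predict one sample's community butyrate production capacity
#'
#' End-to-end per-sample procedure: resolve taxa to species models (dropping
#' unresolved taxa with a warning and excluding their mass before
#' renormalisation), apply the strict >0.1% relative-abundance filter,
#' merge the retained members into an abundance-coupled community model,
#' solve the parsimonious FBA problem, and return the butyrate production
#' rate with diagnostics.
#'
#' @param abundances Abundance tibble (`sample_id`, `taxon_id`,
#'   `rel_abundance`).
#' @param sample_id Sample to analyse.
#' @param registry Named list of [metabolic_model()] objects keyed by
#'   species id.
#' @param mapping Optional tibble `taxon_id`, `species_id` translating
#'   abundance taxa (e.g. OTU ids) to registry species; `NULL` means taxon
#'   ids already are species ids.
#' @param threshold Strict abundance cutoff (default `0.001`).
#' @param parsimony_coef Total-flux penalty (default `1e-5`).
#' @param butyrate_exchange_id Community butyrate exchange id.
#' @return One-row tibble: `sample_id`, `butyrate_rate`, `mu`, `n_members`,
#'   `dropped_mass`, `status`.
#' @export
sample_butyrate_capacity <- function(abundances, sample_id, registry,
                                     mapping = NULL, threshold = 0.001,
                                     parsimony_coef = 1e-5,
                                     butyrate_exchange_id = "EX_but") {
  tbl <- dplyr::filter(as_tibble(abundances), .data$sample_id == !!sample_id)
  if (nrow(tbl) == 0L) {
    abort(paste0("sample not present in abundance table: ", sample_id))
  }
  if (!is.null(mapping)) {
    tbl <- dplyr::left_join(tbl, as_tibble(mapping), by = "taxon_id")
  } else {
    tbl$species_id <- tbl$taxon_id
  }
  tbl$species_id[!tbl$species_id %in% names(registry)] <- NA_character_
  dropped_mass <- sum(tbl$rel_abundance[is.na(tbl$species_id)])
  if (dropped_mass > 0) {
    warn(paste0("sample ", sample_id, ": ",
                sum(is.na(tbl$species_id)), " taxon/taxa (total abundance ",
                signif(dropped_mass, 4),
                ") resolve to no model and were dropped"))
  }
  resolved <- tbl |>
    dplyr::filter(!is.na(.data$species_id)) |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(rel_abundance = sum(.data$rel_abundance),
                     .groups = "drop")
  kept <- dplyr::filter(resolved, .data$rel_abundance > threshold)
  if (nrow(kept) == 0L) {
    return(tibble(
      sample_id = sample_id, butyrate_rate = NA_real_, mu = NA_real_,
      n_members = 0L, dropped_mass = dropped_mass, status = "empty_community"
    ))
  }
  solve_member_set(registry_parts(registry[kept$species_id]),
                   kept$rel_abundance / sum(kept$rel_abundance),
                   sample_id, dropped_mass, parsimony_coef,
                   butyrate_exchange_id)
}

# Core of the per-sample computation, shared with the fast cohort path:
# assemble the community from precomputed parts, solve the pFBA LP, report.
# A community lacking the butyrate exchange (no member produces butyrate)
# has outflow 0 by construction, hence rate 0 when it grows.
solve_member_set <- function(parts_sel, weights, sample_id, dropped_mass,
                             parsimony_coef, butyrate_exchange_id) {
  cm <- community_from_parts(parts_sel, weights, sample_id = sample_id)
  sol <- solve_pfba(formulate_pfba(cm, parsimony_coef = parsimony_coef,
                                   validate = FALSE))
  rate <- if (sol$status != "optimal") {
    NA_real_
  } else if (butyrate_exchange_id %in% names(sol$fluxes)) {
    suppressMessages(butyrate_rate(sol, butyrate_exchange_id))
  } else {
    0
  }
  tibble::new_tibble(list(
    sample_id = sample_id, butyrate_rate = unname(rate), mu = sol$mu,
    n_members = length(weights), dropped_mass = unname(dropped_mass),
    status = sol$status
  ), nrow = 1L)
}

# LP text template for a fixed member set.  Everything except the coupling
# rows (which carry the abundance weights) is weight-independent, so cohort
# runs cache one template per distinct membership and only re-emit the
# coupling lines per sample.
pfba_template <- function(parts_sel, parsimony_coef, butyrate_exchange_id) {
  k <- length(parts_sel)
  cm <- community_from_parts(parts_sel, rep(1 / k, k))
  lp <- formulate_pfba(cm, parsimony_coef = parsimony_coef,
                       validate = FALSE)
  n <- length(lp$reaction_ids)
  nv <- 2L * n + 1L
  n_m <- nrow(lp$A) - k
  A <- methods::as(lp$A, "TsparseMatrix")
  mb <- A@i < n_m
  term <- sprintf("%+.17g x%d", A@x[mb], A@j[mb] + 1L)
  terms_by_row <- split(term, A@i[mb])
  mb_rows <- vapply(terms_by_row, function(tt) {
    paste(paste(tt, collapse = " "), "= 0")
  }, character(1))
  xn <- paste0("x", seq_len(nv))
  # all variables in the objective: fixes glpsol's column numbering
  obj_terms <- sprintf("%+.17g %s", lp$objective, xn)
  fin_ub <- is.finite(lp$var_ub)
  lbv <- lp$var_lb + 0
  ubv <- lp$var_ub + 0
  bounds <- character(nv)
  bounds[fin_ub] <- sprintf("%.17g <= %s <= %.17g",
                            lbv[fin_ub], xn[fin_ub], ubv[fin_ub])
  bounds[!fin_ub] <- sprintf("%s >= %.17g", xn[!fin_ub], lbv[!fin_ub])
  cp_j <- match(vapply(parts_sel, `[[`, "", "biomass_rxn"), lp$reaction_ids)
  but_idx <- match(butyrate_exchange_id, lp$reaction_ids)
  list(
    pre = c("Maximize",
            paste(" obj:", paste(obj_terms, collapse = " ")),
            "Subject To",
            paste0(" m", seq_along(mb_rows), ": ", mb_rows)),
    cp_prefix = sprintf(" c%d: +1 x%d -1 x%d", seq_len(k), cp_j, n + cp_j),
    post = c("Bounds", paste0(" ", bounds), "End"),
    nv = nv, n = n, mu_index = nv, but_idx = but_idx
  )
}

# Solve one sample against a cached template; returns rate/mu/status only.
solve_with_template <- function(tmpl, weights, lp_path, sol_path) {
  lines <- c(tmpl$pre,
             paste0(tmpl$cp_prefix,
                    sprintf(" %+.17g x%d = 0", -weights, tmpl$nv)),
             tmpl$post)
  writeLines(lines, lp_path)
  res <- run_glpsol(lp_path, sol_path)
  if (res$status != "optimal") {
    return(list(rate = NA_real_, mu = NA_real_, status = res$status))
  }
  mu <- res$x[tmpl$mu_index]
  if (mu <= 1e-10) {
    return(list(rate = NA_real_, mu = mu, status = "zero_growth"))
  }
  outflow <- if (is.na(tmpl$but_idx)) 0 else {
    res$x[tmpl$but_idx] - res$x[tmpl$n + tmpl$but_idx]
  }
  list(rate = outflow / mu, mu = mu, status = "optimal")
}

#' Predict butyrate production capacity for every sample
#'
#' Applies [sample_butyrate_capacity()] to each sample in the abundance
#' table.
#'
#' @inheritParams sample_butyrate_capacity
#' @return Tibble with one row per sample (columns as in
#'   [sample_butyrate_capacity()]).
#' @export
predict_cohort_rates <- function(abundances, registry, mapping = NULL,
                                 threshold = 0.001, parsimony_coef = 1e-5,
                                 butyrate_exchange_id = "EX_but") {
  tbl <- as_tibble(abundances)
  samples <- unique(tbl$sample_id)
  # resolve taxa to species and aggregate once for the whole table
  if (!is.null(mapping)) {
    mp <- as_tibble(mapping)
    tbl$species_id <- mp$species_id[match(tbl$taxon_id, mp$taxon_id)]
  } else {
    tbl$species_id <- tbl$taxon_id
  }
  tbl$species_id[!tbl$species_id %in% names(registry)] <- NA_character_
  parts <- registry_parts(registry)
  resolved <- tbl |>
    dplyr::filter(!is.na(.data$species_id)) |>
    dplyr::group_by(.data$sample_id, .data$species_id) |>
    dplyr::summarise(rel_abundance = sum(.data$rel_abundance),
                     .groups = "drop")
  dropped <- tapply(tbl$rel_abundance * is.na(tbl$species_id),
                    tbl$sample_id, sum)
  n_dropped_taxa <- sum(is.na(tbl$species_id))
  if (n_dropped_taxa > 0) {
    warn(paste0(n_dropped_taxa, " abundance record(s) resolve to no model ",
                "and were dropped before renormalisation"))
  }
  kept <- resolved[resolved$rel_abundance > threshold, ]
  by_sample <- split(kept, kept$sample_id)
  # one LP template per distinct member set; one temp file pair per run
  cache <- new.env(parent = emptyenv())
  lp_path <- tempfile(fileext = ".lp")
  sol_path <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lp_path, sol_path)))
  purrr::map_dfr(samples, function(s) {
    k <- by_sample[[s]]
    dm <- unname(dropped[s])
    if (is.null(k) || nrow(k) == 0L) {
      return(tibble(
        sample_id = s, butyrate_rate = NA_real_, mu = NA_real_,
        n_members = 0L, dropped_mass = dm, status = "empty_community"
      ))
    }
    key <- paste(k$species_id, collapse = "|")
    tmpl <- cache[[key]]
    if (is.null(tmpl)) {
      tmpl <- pfba_template(parts[k$species_id], parsimony_coef,
                            butyrate_exchange_id)
      cache[[key]] <- tmpl
    }
    sol <- solve_with_template(tmpl, k$rel_abundance / sum(k$rel_abundance),
                               lp_path, sol_path)
    tibble::new_tibble(list(
      sample_id = s, butyrate_rate = sol$rate, mu = sol$mu,
      n_members = nrow(k), dropped_mass = dm, status = sol$status
    ), nrow = 1L)
  })
}
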