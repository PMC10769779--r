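#' Write a synthetic cohort and model registry to disk
#'
#' Runs the synthetic-data generator end to end and writes every input the
#' analysis pipeline reads: a directory of species model JSON files, the
#' reference 16S FASTA, the OTU representative FASTA, the long-format
#' abundance TSV and the metadata TSV, plus a `manifest.json` recording the
#' configuration and the output files.  Outputs are deterministic given the
#' config (including its seed): rerunning with the same config yields
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
pipeline_simulate <- function(config, dir) {
  stopifnot(inherits(config, "gf_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- make_species_models(
    n_species = config$n_species,
    fraction_producers = config$fraction_producers,
    seed = config$seed, seq_length = config$seq_length
  )
  cohort <- make_cohort(config, reg)

  models_dir <- file.path(dir, "models")
  dir.create(models_dir, showWarnings = FALSE)
  for (m in reg$registry) {
    write_model_json(m, file.path(models_dir, paste0(m$species_id, ".json")))
  }
  write_fasta(reg$references, file.path(dir, "reference.fasta"))
  write_fasta(cohort$otus, file.path(dir, "otus.fasta"))
  write_tsv_det(cohort$abundances, file.path(dir, "abundances.tsv"))
  write_tsv_det(cohort$metadata, file.path(dir, "metadata.tsv"))

  manifest <- list(
    config = unclass(config),
    outputs = list(
      models_dir = "models",
      reference_fasta = "reference.fasta",
      otu_fasta = "otus.fasta",
      abundance_tsv = "abundances.tsv",
      metadata_tsv = "metadata.tsv"
    )
  )
  con <- file(file.path(dir, "manifest.json"), open = "wb")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = 2), con = con, useBytes = TRUE)
  close(con)
  invisible(manifest)
}

# Deterministic TSV writing: readr uses the shortest round-trip
# representation for doubles, so identical tables give identical bytes.
write_tsv_det <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Run the full community metabolic-modelling analysis
#'
#' Orchestrates the pipeline on files written by [pipeline_simulate()] (or
#' real inputs in the same formats): maps OTU representatives to reference
#' 16S sequences, predicts each sample's community butyrate production rate
#' by parsimonious FBA, runs the four responder/nonresponder comparisons,
#' and writes `mapping.tsv`, `rates.tsv`, `tests.tsv`, a per-stage count log
#' `run_log.txt` and a `run_manifest.json` under `out_dir`.
#'
#' @param dir Input directory holding `models/`, `reference.fasta`,
#'   `otus.fasta`, `abundances.tsv`, `metadata.tsv`.
#' @param out_dir Output directory (default `file.path(dir, "results")`).
#' @param min_identity,min_coverage OTU mapping thresholds (defaults 97, 95).
#' @param abundance_min Strict community membership cutoff (default 0.001).
#' @param parsimony_coef Total-flux penalty of the pFBA objective
#'   (default 1e-5).
#' @param butyrate_exchange_id Community butyrate exchange reaction id.
#' @param exact_cap_rank_sum,exact_cap_signed_rank Exact-test enumeration
#'   caps.
#' @param dump_fluxes If `TRUE`, write each sample's full flux vector as
#'   JSON under `out_dir/fluxes/`.
#' @return A list with `mapping`, `rates`, `result` (the
#'   `gf_cohort_result`), invisibly.
#' @export
pipeline_run <- function(dir, out_dir = file.path(dir, "results"),
                         min_identity = 97, min_coverage = 95,
                         abundance_min = 0.001, parsimony_coef = 1e-5,
                         butyrate_exchange_id = "EX_but",
                         exact_cap_rank_sum = 25, exact_cap_signed_rank = 20,
                         dump_fluxes = FALSE) {
  paths <- c(
    models_dir = file.path(dir, "models"),
    reference_fasta = file.path(dir, "reference.fasta"),
    otu_fasta = file.path(dir, "otus.fasta"),
    abundance_tsv = file.path(dir, "abundances.tsv"),
    metadata_tsv = file.path(dir, "metadata.tsv")
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  model_files <- sort(list.files(paths[["models_dir"]], pattern = "\\.json$",
                                 full.names = TRUE))
  registry <- purrr::map(model_files, read_model_json)
  names(registry) <- purrr::map_chr(registry, "species_id")
  log_add("models loaded: ", length(registry))

  references <- read_fasta(paths[["reference_fasta"]])
  otus <- read_fasta(paths[["otu_fasta"]])
  mapping <- suppressWarnings(
    map_all(otus, references, min_identity = min_identity,
            min_coverage = min_coverage)
  )
  write_tsv_det(mapping, file.path(out_dir, "mapping.tsv"))
  log_add("OTUs mapped: ", sum(mapping$status == "mapped"),
          " / ", nrow(mapping),
          " (unmapped: ", sum(mapping$status == "unmapped"), ")")

  abundances <- read_abundances(paths[["abundance_tsv"]])
  metadata <- read_metadata(paths[["metadata_tsv"]])
  map_tbl <- tibble(taxon_id = mapping$otu_id,
                    species_id = mapping$assigned_reference)
  rates <- suppressWarnings(suppressMessages(predict_cohort_rates(
    abundances, registry, mapping = map_tbl, threshold = abundance_min,
    parsimony_coef = parsimony_coef,
    butyrate_exchange_id = butyrate_exchange_id
  )))
  write_tsv_det(rates, file.path(out_dir, "rates.tsv"))
  log_add("samples in: ", length(unique(abundances$sample_id)))
  log_add("samples with rate: ", sum(!is.na(rates$butyrate_rate)))
  log_add("samples excluded: ", sum(is.na(rates$butyrate_rate)))
  for (st in sort(unique(rates$status))) {
    log_add("solver status ", st, ": ", sum(rates$status == st))
  }
  log_add("mean members per community: ",
          round(mean(rates$n_members[rates$n_members > 0]), 2))

  if (isTRUE(dump_fluxes)) {
    dump_sample_fluxes(abundances, registry, map_tbl, abundance_min,
                       parsimony_coef, file.path(out_dir, "fluxes"))
  }

  result <- run_cohort_tests(rates, metadata,
                             exact_cap_rank_sum = exact_cap_rank_sum,
                             exact_cap_signed_rank = exact_cap_signed_rank)
  write_tsv_det(dplyr::rename(result$tests, test_name = "test"),
                file.path(out_dir, "tests.tsv"))
  log_add("tests computed: ",
          sum(result$tests$method != "not_computable"), " / 4")

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  manifest <- list(
    inputs = as.list(paths),
    parameters = list(min_identity = min_identity,
                      min_coverage = min_coverage,
                      abundance_min = abundance_min,
                      parsimony_coef = parsimony_coef,
                      butyrate_exchange_id = butyrate_exchange_id),
    outputs = c("mapping.tsv", "rates.tsv", "tests.tsv", "run_log.txt")
  )
  con <- file(file.path(out_dir, "run_manifest.json"), open = "wb")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = 2),
             con = con, useBytes = TRUE)
  close(con)
  invisible(list(mapping = mapping, rates = rates, result = result))
}

dump_sample_fluxes <- function(abundances, registry, map_tbl, threshold,
                               parsimony_coef, flux_dir) {
  dir.create(flux_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(abundances$sample_id)) {
    tbl <- dplyr::filter(abundances, .data$sample_id == s) |>
      dplyr::left_join(map_tbl, by = "taxon_id") |>
      dplyr::filter(!is.na(.data$species_id),
                    .data$species_id %in% names(registry)) |>
      dplyr::group_by(.data$species_id) |>
      dplyr::summarise(rel_abundance = sum(.data$rel_abundance),
                       .groups = "drop") |>
      dplyr::filter(.data$rel_abundance > threshold)
    if (nrow(tbl) == 0L) next
    w <- tbl$rel_abundance / sum(tbl$rel_abundance)
    cm <- build_community(registry[tbl$species_id], w, sample_id = s)
    sol <- solve_pfba(formulate_pfba(cm, parsimony_coef = parsimony_coef))
    con <- file(file.path(flux_dir, paste0(s, ".json")), open = "wb")
    writeLines(jsonlite::toJSON(
      list(sample_id = s, status = sol$status, mu = sol$mu,
           fluxes = as.list(sol$fluxes)),
      auto_unbox = TRUE, digits = NA, pretty = 2
    ), con = con, useBytes = TRUE)
    close(con)
  }
}

#' Summarise a finished pipeline run
#'
#' Reads `rates.tsv` and `tests.tsv` from a [pipeline_run()] output
#' directory, prints a human-readable summary of the four tests and the
#' group/visit medians, and writes a long-format `plot_data.tsv` ready for
#' plotting.
#'
#' @param out_dir A [pipeline_run()] output directory.
#' @param metadata_tsv Path to the metadata TSV (default: `metadata.tsv`
#'   next to `out_dir`).
#' @return A list with `tests`, `medians` and `plot_data`, invisibly.
#' @export
pipeline_report <- function(out_dir,
                            metadata_tsv = file.path(dirname(out_dir),
                                                     "metadata.tsv")) {
  rates_path <- file.path(out_dir, "rates.tsv")
  tests_path <- file.path(out_dir, "tests.tsv")
  if (!file.exists(rates_path) || !file.exists(tests_path)) {
    abort(paste0("no pipeline results under ", out_dir,
                 " (expected rates.tsv and tests.tsv)"))
  }
  rates <- readr::read_tsv(rates_path, show_col_types = FALSE,
                           progress = FALSE)
  tests <- readr::read_tsv(tests_path, show_col_types = FALSE,
                           progress = FALSE)
  if ("test_name" %in% names(tests)) {
    tests <- dplyr::rename(tests, test = "test_name")
  }
  metadata <- read_metadata(metadata_tsv)
  scores <- metadata |>
    dplyr::select("patient_id", "visit", "lichtiger") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "lichtiger") |>
    dplyr::filter(!is.na(.data$V1), !is.na(.data$V2))
  labels <- tibble(patient_id = scores$patient_id,
                   response_group = label_response(scores$V1, scores$V2))
  plot_data <- metadata |>
    dplyr::inner_join(rates, by = "sample_id") |>
    dplyr::left_join(labels, by = "patient_id") |>
    dplyr::select("sample_id", "patient_id", "visit", "response_group",
                  "butyrate_rate")
  write_tsv_det(plot_data, file.path(out_dir, "plot_data.tsv"))
  medians <- plot_data |>
    dplyr::filter(!is.na(.data$butyrate_rate),
                  !is.na(.data$response_group)) |>
    dplyr::group_by(.data$response_group, .data$visit) |>
    dplyr::summarise(median_rate = stats::median(.data$butyrate_rate),
                     n = dplyr::n(), .groups = "drop")

  cat("Butyrate production capacity - cohort summary\n")
  cat("=============================================\n")
  for (i in seq_len(nrow(medians))) {
    cat(sprintf("  median rate %-13s %s: %.4f (n = %d)\n",
                medians$response_group[i], medians$visit[i],
                medians$median_rate[i], medians$n[i]))
  }
  cat("Tests:\n")
  for (i in seq_len(nrow(tests))) {
    cat(sprintf("  %-17s p = %-8.4g (n = %d, %s)\n", tests$test[i],
                tests$p_value[i], tests$n[i], tests$method[i]))
  }
  invisible(list(tests = tests, medians = medians, plot_data = plot_data))
}
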