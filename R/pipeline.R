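#' Simulate the full synthetic study
#'
#' Convenience wrapper: plants the multi-species panel, emits peak tables for
#' every species from the observed PSI, and simulates the differentiation
#' time-course panel, all from one seeded configuration.
#'
#' @param config A [sim_config()].
#' @return A list: everything from [simulate_panel()] plus `peaks` (named
#'   list per species of [simulate_peak_tables()] results) and `timecourse`
#'   ([simulate_timecourse()] result).
#' @export
simulate_study <- function(config = sim_config()) {
  panel <- simulate_panel(config)
  peaks <- lapply(seq_along(config$species), function(j) {
    sp <- config$species[j]
    simulate_peak_tables(panel$psi[[sp]],
                         panel$assays[panel$assays$species == sp, ],
                         config, species = sp, seed = config$seed + j)
  })
  names(peaks) <- config$species
  tc <- simulate_timecourse(config)
  c(panel, list(peaks = peaks, timecourse = tc))
}

#' Run the full screen pipeline on a simulated or loaded study
#'
#' Executes quantification (peak tables to PSI through the purity gate), the
#' per-species switch screen, event-type enrichment in the discovery species,
#' the cross-species conservation funnel, and the time-course dynamics stage;
#' writes every stage table plus a JSON run manifest recording the seed,
#' thresholds and stage counts.  Idempotent for a fixed seed and
#' configuration.
#'
#' @param config A [sim_config()] describing the synthetic study.
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @param purity_threshold,switch_threshold Quality gate and switch threshold.
#' @param reference Reference tissue name.
#' @return A list: `quant` and `psi` (per species), `calls` (per species),
#'   `enrichment`, `funnel`, `dynamics`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         purity_threshold = 0.75, switch_threshold = 50,
                         reference = "brain") {
  study <- simulate_study(config)
  species <- config$species
  quant <- list(); psi <- list(); calls <- list()
  for (sp in species) {
    assays_sp <- study$assays[study$assays$species == sp, ]
    quant[[sp]] <- quantify_table(study$peaks[[sp]]$peaks, assays_sp,
                                  purity_threshold = purity_threshold)
    psi[[sp]] <- quant_to_psi(quant[[sp]],
                              samples = config$tissues_per_species[[sp]])
    calls[[sp]] <- screen_psi(psi[[sp]], reference = reference,
                              threshold = switch_threshold)
  }
  sp1 <- species[1L]
  enr <- enrichment_test(calls[[sp1]], study$assays)
  funnel <- staged_screen(calls[[species[1L]]],
                          if (length(species) >= 2) calls[[species[2L]]] else NULL,
                          if (length(species) >= 3) calls[[species[3L]]] else NULL,
                          study$ortholog_map, species_names = species)
  dyn <- dynamics_screen(study$timecourse$tc, threshold = switch_threshold,
                         quiet = TRUE)
  manifest <- list(
    package = "switchscreen",
    version = as.character(utils::packageVersion("switchscreen")),
    seed = config$seed,
    thresholds = list(purity = purity_threshold, switch = switch_threshold,
                      match_abs_nt = 2, match_rel = 0.03),
    reference = reference,
    stage_counts = c(
      as.list(vapply(species, function(sp) nrow(psi[[sp]]), integer(1))),
      list(discovery_complete = sum(calls[[sp1]]$complete)),
      as.list(funnel$counts),
      list(timecourse_total = attr(dyn, "n_total"),
           timecourse_complete = attr(dyn, "n_complete"),
           timecourse_switch = sum(dyn$is_switch))),
    enrichment = list(counts = as.vector(enr$counts),
                      odds_ratio = enr$odds_ratio, p_value = enr$p_value))
  res <- list(quant = quant, psi = psi, calls = calls, enrichment = enr,
              funnel = funnel, dynamics = dyn, manifest = manifest,
              study = study)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_assays(res$study$assays, p("assays.tsv"))
  write_orthologs(res$study$ortholog_map, p("orthologs.tsv"))
  for (sp in names(res$psi)) {
    readr::write_tsv(res$quant[[sp]], p(paste0("quant_", sp, ".tsv")), na = "NA")
    write_psi(res$psi[[sp]], p(paste0("psi_", sp, ".tsv")))
    readr::write_tsv(res$calls[[sp]], p(paste0("screen_", sp, ".tsv")), na = "NA")
  }
  readr::write_tsv(res$dynamics, p("dynamics.tsv"), na = "NA")
  jsonlite::write_json(
    list(counts = as.vector(res$enrichment$counts),
         odds_ratio = res$enrichment$odds_ratio,
         p_value = res$enrichment$p_value),
    p("enrich.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(res$funnel$counts), p("funnel.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Switch-recovery F1 against planted truth
#'
#' Precision/recall/F1 of a set of switch calls against the generator's
#' planted flags, over QC-complete events only (an event the screen could not
#' evaluate is excluded from both margins).
#'
#' @param calls [screen_psi()] output.
#' @param truth Tibble with `ase_id`-compatible ids and `is_switch` flags
#'   (`group_id` is matched against the `ase_id` prefix if needed).
#' @param id_map Optional named vector mapping `calls$ase_id` to truth ids.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
recovery_f1 <- function(calls, truth, id_map = NULL) {
  ids <- if (is.null(id_map)) calls$ase_id else unname(id_map[calls$ase_id])
  truth_flag <- truth$is_switch[match(ids, truth[[1L]])]
  keep <- calls$complete & !is.na(truth_flag)
  pred <- calls$is_switch[keep]; tr <- truth_flag[keep]
  tp <- sum(pred & tr); fp <- sum(pred & !tr); fn <- sum(!pred & tr)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
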