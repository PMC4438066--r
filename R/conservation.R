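#' Validate an ortholog map against per-species screen tables
#'
#' @param map Tibble `group_id`, `species`, `ase_id` (at most one member per
#'   species per group).
#' @param calls_by_species Named list of [screen_psi()] outputs, one per
#'   species.
#' @keywords internal
validate_ortholog_map <- function(map, calls_by_species) {
  stopifnot(all(c("group_id", "species", "ase_id") %in% names(map)))
  if (anyDuplicated(map[, c("group_id", "species")])) {
    stop("ortholog group lists more than one event for a species", call. = FALSE)
  }
  for (sp in names(calls_by_species)) {
    ids <- calls_by_species[[sp]]$ase_id
    if (anyDuplicated(ids)) {
      stop("duplicate ase_id within species '", sp, "'", call. = FALSE)
    }
    hit <- map$ase_id %in% ids
    if (any(hit & map$species != sp)) {
      bad <- map$ase_id[hit & map$species != sp][1L]
      stop("ase_id '", bad, "' is listed under species '",
           map$species[map$ase_id == bad][1L],
           "' but appears in the call table of '", sp, "'", call. = FALSE)
    }
  }
  invisible(map)
}

#' Call conserved switch-like splicing across species
#'
#' A group is evaluable only if every required species contributes a complete
#' switch call for its member event.  Conservation requires the event to be
#' switch-like in every required species *with the same direction sign* — the
#' same isoform must be the brain-specific one in all species.
#'
#' @param calls_by_species Named list of [screen_psi()] outputs.
#' @param map Ortholog map (`group_id`, `species`, `ase_id`).
#' @param required_species Species that must all be evaluable; defaults to
#'   `names(calls_by_species)`.
#' @return A tibble: `group_id`, `n_species_evaluated`, `evaluable`,
#'   `all_switch` (`NA` when not evaluable), `direction_consistent`,
#'   `is_conserved`.
#' @export
join_orthologs <- function(calls_by_species, map,
                           required_species = names(calls_by_species)) {
  validate_ortholog_map(map, calls_by_species)
  missing_sp <- setdiff(required_species, names(calls_by_species))
  if (length(missing_sp)) {
    stop("no call table for required species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  calls <- dplyr::bind_rows(lapply(names(calls_by_species), function(sp) {
    cbind(species = sp, calls_by_species[[sp]])
  }))
  joined <- merge(map, calls, by = c("species", "ase_id"), all.x = TRUE)
  per_group <- split(joined, joined$group_id)
  res <- lapply(per_group, function(g) {
    req <- g[g$species %in% required_species, , drop = FALSE]
    have <- req[!is.na(req$complete) & req$complete, , drop = FALSE]
    evaluable <- all(required_species %in% have$species)
    if (!evaluable) {
      return(tibble::tibble(group_id = g$group_id[1L],
                            n_species_evaluated = nrow(have),
                            evaluable = FALSE, all_switch = NA,
                            direction_consistent = NA, is_conserved = FALSE))
    }
    all_sw <- all(have$is_switch)
    dir_ok <- all_sw && length(unique(sign(have$direction))) == 1L
    tibble::tibble(group_id = g$group_id[1L],
                   n_species_evaluated = nrow(have),
                   evaluable = TRUE, all_switch = all_sw,
                   direction_consistent = if (all_sw) dir_ok else NA,
                   is_conserved = all_sw && dir_ok)
  })
  out <- dplyr::bind_rows(res)
  out[order(out$group_id), ]
}

#' Staged cross-species screening funnel
#'
#' Reproduces the discovery funnel: switch-like events found in the discovery
#' species (mouse), restricted to those with an ortholog assayed in the second
#' species (human), to those complete across all second-species tissues, to
#' those switch-like versus every comparator tissue, and finally to those
#' whose conservation is confirmed in the third species (zebrafish) with a
#' consistent direction.  Each stage count is at most the previous one.
#'
#' @param mouse_calls,human_calls,fish_calls [screen_psi()] outputs (pass
#'   `NULL` for a stage that was not run; downstream counts are then `NA`).
#' @param map Ortholog map covering all three species (`group_id`, `species`,
#'   `ase_id`); species names must match the argument roles via
#'   `species_names`.
#' @param species_names Length-3 character vector naming the discovery,
#'   second and third species as they appear in `map`.
#' @return List with `counts` (named integer vector of the five stage counts),
#'   `conserved` (tibble of confirmed groups) and `stages_run`.
#' @export
staged_screen <- function(mouse_calls, human_calls, fish_calls, map,
                          species_names = c("mouse", "human", "zebrafish")) {
  stopifnot(length(species_names) == 3L)
  sp1 <- species_names[1L]; sp2 <- species_names[2L]; sp3 <- species_names[3L]
  counts <- c(discovery_switch = NA_integer_, orthologs_found = NA_integer_,
              second_species_complete = NA_integer_,
              second_species_switch = NA_integer_, conserved = NA_integer_)
  stages_run <- character(0)
  conserved_tbl <- NULL

  if (is.null(mouse_calls)) {
    return(list(counts = counts, conserved = conserved_tbl,
                stages_run = stages_run))
  }
  stages_run <- sp1
  hits1 <- mouse_calls$ase_id[mouse_calls$is_switch]
  counts["discovery_switch"] <- length(hits1)

  hit_groups <- unique(map$group_id[map$species == sp1 & map$ase_id %in% hits1])
  map2 <- map[map$group_id %in% hit_groups, , drop = FALSE]
  counts["orthologs_found"] <-
    length(unique(map2$group_id[map2$species == sp2]))

  if (is.null(human_calls)) {
    return(list(counts = counts, conserved = conserved_tbl,
                stages_run = stages_run))
  }
  stages_run <- c(stages_run, sp2)
  ids2 <- map2$ase_id[map2$species == sp2]
  calls2 <- human_calls[human_calls$ase_id %in% ids2, , drop = FALSE]
  counts["second_species_complete"] <- sum(calls2$complete)
  hits2 <- calls2$ase_id[calls2$is_switch]
  counts["second_species_switch"] <- length(hits2)

  if (is.null(fish_calls)) {
    return(list(counts = counts, conserved = conserved_tbl,
                stages_run = stages_run))
  }
  stages_run <- c(stages_run, sp3)
  groups2 <- unique(map2$group_id[map2$species == sp2 & map2$ase_id %in% hits2])
  map3 <- map[map$group_id %in% groups2, , drop = FALSE]
  cons <- join_orthologs(
    stats::setNames(list(mouse_calls, human_calls, fish_calls),
                    c(sp1, sp2, sp3)),
    map3, required_species = c(sp1, sp2, sp3))
  conserved_tbl <- cons[cons$is_conserved, , drop = FALSE]
  counts["conserved"] <- nrow(conserved_tbl)

  list(counts = counts, conserved = conserved_tbl, stages_run = stages_run)
}
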