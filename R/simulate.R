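clamp_pct <- function(x) {
  y <- pmin(100, pmax(0, x))
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Configuration of the synthetic splicing study
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults emulate the design of a three-species brain-specificity screen:
#' a 1329-event discovery panel profiled in mouse brain/kidney/liver, a
#' six-tissue human validation stage, a zebrafish confirmation stage, and a
#' five-point neural stem-cell differentiation time course pivoting between
#' days 6 and 10.  Switch events are planted as near-complete isoform
#' reversals (the reference tissue at one PSI extreme, every comparator at
#' the other); non-switch events keep all tissues within 40 percentage points
#' of brain, a guard band below the 50-point switch threshold so zero-noise
#' recovery is unambiguous.
#'
#' @param n_ases Number of alternative splicing events on the discovery panel.
#' @param species Species names; the first is the discovery species.
#' @param tissues_per_species Named list of ordered tissue names per species;
#'   the first tissue of each is the reference ("brain").
#' @param fraction_switch Fraction of events planted switch-like in the
#'   discovery species.
#' @param fraction_conserved Fraction *of switch events* planted switch-like
#'   in all species (same direction).
#' @param fraction_switch_second Fraction of switch events planted switch-like
#'   in the second species as well, but not in the third.
#' @param ortholog_rate Probability that a non-conserved event has an ortholog
#'   assayed in each later species (conserved and second-species-switch events
#'   always do, so their planted truth is evaluable).
#' @param psi_noise_sd Gaussian measurement noise on observed PSI
#'   (percentage points).
#' @param spurious_peak_rate Per-lane probability of an off-target
#'   contaminating peak; a scalar or a named per-species vector.
#' @param spurious_mass_fraction Fraction of the lane's total mass carried by
#'   the contaminating peak (in `[0, 1)`).
#' @param event_type_probs Event-type distribution for non-switch events
#'   (must sum to 1).
#' @param switch_type_probs Event-type distribution for switch events; the
#'   default is cassette-enriched, reproducing the cassette-exon excess among
#'   brain-specific events.
#' @param size_range_nt Range the short-product amplicon size is drawn from.
#' @param timepoints Ordered times of the differentiation time course (days).
#' @param pivot_interval Interval (within the time span) in which planted
#'   logistic midpoints fall.
#' @param tc_n_series,tc_n_switch Time-course panel size and planted switch
#'   count.
#' @param tc_missing_rate Per-point dropout probability for non-switch time
#'   courses (planted switch series stay complete so the planted count is
#'   well-defined).
#' @param seed Integer seed; one seeded stream drives the whole run.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_ases = 1329,
    species = c("mouse", "human", "zebrafish"),
    tissues_per_species = list(
      mouse = c("brain", "kidney", "liver"),
      human = c("brain", "kidney", "liver", "lung", "muscle", "heart"),
      zebrafish = c("brain", "kidney", "liver")),
    fraction_switch = 93 / 809,
    fraction_conserved = 0.145,
    fraction_switch_second = 0.097,
    ortholog_rate = 89 / 93,
    psi_noise_sd = 5,
    spurious_peak_rate = c(mouse = 0.257, human = 0.099, zebrafish = 0),
    spurious_mass_fraction = 0.30,
    event_type_probs = c(cassette = 0.673, alt5 = 0.131, alt3 = 0.134,
                         complex = 0.062),
    switch_type_probs = c(cassette = 0.8387, alt5 = 0.0648, alt3 = 0.0661,
                          complex = 0.0304),
    size_range_nt = c(120, 700),
    timepoints = c(0, 2, 6, 10, 14),
    pivot_interval = c(6, 10),
    tc_n_series = 89,
    tc_n_switch = 13,
    tc_missing_rate = 0.108,
    seed = 1L) {
  cfg <- list(n_ases = n_ases, species = species,
              tissues_per_species = tissues_per_species,
              fraction_switch = fraction_switch,
              fraction_conserved = fraction_conserved,
              fraction_switch_second = fraction_switch_second,
              ortholog_rate = ortholog_rate,
              psi_noise_sd = psi_noise_sd,
              spurious_peak_rate = spurious_peak_rate,
              spurious_mass_fraction = spurious_mass_fraction,
              event_type_probs = event_type_probs,
              switch_type_probs = switch_type_probs,
              size_range_nt = size_range_nt,
              timepoints = timepoints, pivot_interval = pivot_interval,
              tc_n_series = tc_n_series, tc_n_switch = tc_n_switch,
              tc_missing_rate = tc_missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac_ok <- function(x) is.numeric(x) && all(x >= 0) && all(x <= 1)
  if (cfg$n_ases < 1) stop("n_ases must be >= 1", call. = FALSE)
  if (!length(cfg$species)) stop("species list is empty", call. = FALSE)
  if (!all(cfg$species %in% names(cfg$tissues_per_species))) {
    stop("every species needs an ordered tissue list", call. = FALSE)
  }
  if (any(lengths(cfg$tissues_per_species[cfg$species]) < 2)) {
    stop("each species needs a reference tissue and at least one comparator",
         call. = FALSE)
  }
  for (f in c("fraction_switch", "fraction_conserved",
              "fraction_switch_second", "ortholog_rate", "spurious_peak_rate",
              "tc_missing_rate")) {
    if (!frac_ok(cfg[[f]])) stop(f, " must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$fraction_conserved + cfg$fraction_switch_second > 1) {
    stop("conserved and second-species switch fractions exceed 1", call. = FALSE)
  }
  if (!frac_ok(cfg$spurious_mass_fraction) || cfg$spurious_mass_fraction >= 1) {
    stop("spurious_mass_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$psi_noise_sd < 0) stop("psi_noise_sd must be >= 0", call. = FALSE)
  for (p in c("event_type_probs", "switch_type_probs")) {
    if (abs(sum(cfg[[p]]) - 1) > 1e-9) {
      stop(p, " must sum to 1", call. = FALSE)
    }
    if (!all(c("cassette", "alt5", "alt3", "complex") %in% names(cfg[[p]]))) {
      stop(p, " must name cassette, alt5, alt3 and complex", call. = FALSE)
    }
  }
  if (cfg$size_range_nt[1] >= cfg$size_range_nt[2]) {
    stop("size_range_nt must be (min, max) with min < max", call. = FALSE)
  }
  if (length(cfg$timepoints) < 2 || any(diff(cfg$timepoints) <= 0)) {
    stop("timepoints must be >= 2 strictly increasing values", call. = FALSE)
  }
  if (cfg$pivot_interval[1] < min(cfg$timepoints) ||
      cfg$pivot_interval[2] > max(cfg$timepoints) ||
      cfg$pivot_interval[1] >= cfg$pivot_interval[2]) {
    stop("pivot_interval must be an increasing interval inside the time span",
         call. = FALSE)
  }
  invisible(cfg)
}

spurious_rate_for <- function(cfg, species) {
  r <- cfg$spurious_peak_rate
  if (is.null(names(r))) return(r[1L])
  if (!species %in% names(r)) return(0)
  unname(r[species])
}

# Switch pattern: reference at one PSI extreme, every comparator at the other
# (planted gap >= 70 points).  Non-switch: comparators within 40 points of the
# reference (guard band below the 50-point threshold).
draw_true_psi <- function(n_tissues, is_switch, direction) {
  if (is_switch) {
    if (direction > 0) {
      c(stats::runif(1, 85, 100), stats::runif(n_tissues - 1, 0, 15))
    } else {
      c(stats::runif(1, 0, 15), stats::runif(n_tissues - 1, 85, 100))
    }
  } else {
    ref <- stats::runif(1, 0, 100)
    clamp_pct(c(ref, ref + stats::runif(n_tissues - 1, -40, 40)))
  }
}

#' Simulate a multi-species PSI panel with planted switch events
#'
#' Plants exactly `round(n_ases * fraction_switch)` switch-like events in the
#' discovery species; of these, a planted subset is switch-like (same
#' direction) in all species ("conserved") and another subset in the second
#' species only.  Observed PSI is the true PSI plus Gaussian noise, clamped to
#' `[0, 100]`.  Deterministic for a given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list:
#'   \describe{
#'     \item{assays}{assay table over all species (`ase_id`, `gene`,
#'       `species`, `event_type`, `size_short_nt`, `size_long_nt`).}
#'     \item{psi}{named list of observed wide PSI tibbles, one per species.}
#'     \item{psi_true}{the noise-free counterparts.}
#'     \item{ortholog_map}{`group_id`, `species`, `ase_id`.}
#'     \item{truth}{per-event ground truth (`group_id`, `event_type`,
#'       `is_switch`, `switch_class`, `is_conserved`, `direction`).}
#'   }
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_ases
  sp1 <- config$species[1L]
  group_id <- sprintf("ASE%05d", seq_len(n))

  n_switch <- round(n * config$fraction_switch)
  switch_idx <- sample.int(n, n_switch)
  is_switch <- seq_len(n) %in% switch_idx
  n_cons <- round(n_switch * config$fraction_conserved)
  n_second <- round(n_switch * config$fraction_switch_second)
  shuffled <- sample(switch_idx)
  switch_class <- rep("none", n)
  switch_class[switch_idx] <- "discovery_only"
  if (n_cons > 0) switch_class[shuffled[seq_len(n_cons)]] <- "conserved"
  if (n_second > 0) {
    switch_class[shuffled[n_cons + seq_len(n_second)]] <- "second_species"
  }
  direction <- sample(c(-1, 1), n, replace = TRUE)
  event_type <- character(n)
  types <- names(config$event_type_probs)
  event_type[!is_switch] <- sample(types, sum(!is_switch), replace = TRUE,
                                   prob = config$event_type_probs)
  event_type[is_switch] <- sample(types, sum(is_switch), replace = TRUE,
                                  prob = config$switch_type_probs[types])

  # ortholog presence: later species carry the event at ortholog_rate, but
  # events planted as switch there always carry it (evaluable truth)
  present <- matrix(TRUE, n, length(config$species),
                    dimnames = list(NULL, config$species))
  for (j in seq_along(config$species)[-1]) {
    sp <- config$species[j]
    pres <- stats::runif(n) < config$ortholog_rate
    forced <- switch_class == "conserved" |
      (switch_class == "second_species" & j == 2L)
    present[, sp] <- pres | forced
  }

  switch_in_species <- function(sp_index) {
    if (sp_index == 1L) return(is_switch)
    if (sp_index == 2L) return(switch_class %in% c("conserved", "second_species"))
    switch_class == "conserved"
  }

  assays <- list(); psi <- list(); psi_true <- list(); map <- list()
  for (j in seq_along(config$species)) {
    sp <- config$species[j]
    tissues <- config$tissues_per_species[[sp]]
    idx <- which(present[, sp])
    ase_id <- paste0(group_id[idx], "_", sp)
    size_short <- sample(seq(config$size_range_nt[1],
                             config$size_range_nt[2] - 60), length(idx),
                         replace = TRUE)
    ase_len <- 3 * sample(10:50, length(idx), replace = TRUE)  # in-frame
    assays[[sp]] <- tibble::tibble(
      ase_id = ase_id, gene = paste0("GENE", sprintf("%05d", idx)),
      species = sp, event_type = event_type[idx],
      size_short_nt = size_short, size_long_nt = size_short + ase_len)
    sw <- switch_in_species(j)[idx]
    truth_mat <- t(vapply(seq_along(idx), function(k) {
      draw_true_psi(length(tissues), sw[k], direction[idx[k]])
    }, numeric(length(tissues))))
    obs_mat <- if (config$psi_noise_sd > 0) {
      clamp_pct(truth_mat + stats::rnorm(length(truth_mat),
                                         sd = config$psi_noise_sd))
    } else truth_mat
    colnames(truth_mat) <- colnames(obs_mat) <- tissues
    psi_true[[sp]] <- tibble::as_tibble(cbind(
      tibble::tibble(ase_id = ase_id), tibble::as_tibble(truth_mat)))
    psi[[sp]] <- tibble::as_tibble(cbind(
      tibble::tibble(ase_id = ase_id), tibble::as_tibble(obs_mat)))
    map[[sp]] <- tibble::tibble(group_id = group_id[idx], species = sp,
                                ase_id = ase_id)
  }

  truth <- tibble::tibble(
    group_id = group_id, event_type = event_type, is_switch = is_switch,
    switch_class = switch_class,
    is_conserved = switch_class == "conserved", direction = direction)
  list(assays = dplyr::bind_rows(assays), psi = psi, psi_true = psi_true,
       ortholog_map = dplyr::bind_rows(map), truth = truth,
       config = config)
}

draw_spurious_size <- function(size_short, size_long, size_range) {
  guard <- function(x, expected) {
    abs(x - expected) >= max(2, 0.05 * expected)
  }
  lo <- max(50, size_range[1] - 50); hi <- size_range[2] + 100
  for (i in 1:100) {
    x <- stats::runif(1, lo, hi)
    if (guard(x, size_short) && guard(x, size_long)) return(x)
  }
  stop("could not place a spurious peak away from both expected sizes",
       call. = FALSE)
}

#' Simulate capillary-electrophoresis peak tables from a PSI matrix
#'
#' For an event with PSI `p` (percent), the long and short products carry
#' molar amounts proportional to `p` and `100 - p`; each peak's emitted mass
#' is molarity times fragment length, times an arbitrary per-lane scale.  With
#' per-lane probability `spurious_peak_rate` an off-target peak is added at a
#' size at least `max(2 nt, 5%)` away from both expected sizes, carrying
#' `spurious_mass_fraction` of the lane's total mass.  Deterministic given
#' `seed`.
#'
#' @param psi Wide PSI tibble for one species (`ase_id` + tissue columns,
#'   percent; `NA` cells yield no lane).
#' @param assays Assay table covering every `ase_id` in `psi`.
#' @param config A [sim_config()] (supplies the contamination parameters).
#' @param species Species whose `spurious_peak_rate` applies; defaults to the
#'   species of the first assay.
#' @param seed Seed for this step; defaults to `config$seed + 1`.
#' @return A list: `peaks` (long tibble `ase_id`, `sample_id`, `size_nt`,
#'   `conc`) and `lane_truth` (`ase_id`, `sample_id`, `psi_true`,
#'   `has_spurious`, `spurious_molar_fraction` — the planted contamination as
#'   a fraction of total lane molarity).
#' @export
simulate_peak_tables <- function(psi, assays, config,
                                 species = assays$species[1L],
                                 seed = config$seed + 1L) {
  validate_sim_config(config)
  stopifnot(names(psi)[1] == "ase_id")
  vals <- as.matrix(psi[, -1, drop = FALSE])
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    stop("PSI values must lie in [0, 100]", call. = FALSE)
  }
  assays <- as.data.frame(assays)
  if (!all(psi$ase_id %in% assays$ase_id)) {
    stop("every event in the PSI matrix needs expected product sizes",
         call. = FALSE)
  }
  rownames(assays) <- assays$ase_id
  rate <- spurious_rate_for(config, species)
  smf <- config$spurious_mass_fraction
  set.seed(seed)
  samples <- colnames(vals)
  peaks <- vector("list", nrow(psi) * length(samples))
  lanes <- vector("list", length(peaks))
  k <- 0L
  for (i in seq_len(nrow(psi))) {
    a <- assays[psi$ase_id[i], ]
    for (s in samples) {
      p <- unname(vals[i, s])
      if (is.na(p)) next
      k <- k + 1L
      scale <- stats::runif(1, 0.5, 2)      # arbitrary molar units per lane
      mol_long <- scale * p / 100
      mol_short <- scale * (1 - p / 100)
      size <- c(a$size_short_nt, a$size_long_nt)
      mass <- c(mol_short, mol_long) * size
      keep <- mass > 0
      size <- size[keep]; mass <- mass[keep]
      spurious <- stats::runif(1) < rate
      sp_frac <- 0
      if (spurious && smf > 0) {
        sp_size <- draw_spurious_size(a$size_short_nt, a$size_long_nt,
                                      config$size_range_nt)
        sp_mass <- smf / (1 - smf) * sum(mass)
        sp_frac <- (sp_mass / sp_size) /
          (sp_mass / sp_size + sum(mass / size))
        size <- c(size, sp_size); mass <- c(mass, sp_mass)
      }
      peaks[[k]] <- tibble::tibble(ase_id = a$ase_id, sample_id = s,
                                   size_nt = size, conc = mass)
      lanes[[k]] <- tibble::tibble(ase_id = a$ase_id, sample_id = s,
                                   psi_true = p, has_spurious = spurious,
                                   spurious_molar_fraction = sp_frac)
    }
  }
  list(peaks = dplyr::bind_rows(peaks[seq_len(k)]),
       lane_truth = dplyr::bind_rows(lanes[seq_len(k)]))
}

#' Simulate PSI time courses with planted logistic switches
#'
#' Switch series follow a logistic curve `base + amp / (1 + exp(-k (t - t0)))`
#' with midpoint `t0` drawn inside the configured pivot interval (shrunk by a
#' 12.5% margin at each end so the pivot is identifiable at the sampling
#' resolution), steepness `k = 2` per time unit and amplitude drawn from
#' `amplitude_range` with a random sign; non-switch series are flat.  Observed
#' values add Gaussian noise and are clamped to `[0, 100]`; non-switch series
#' lose individual points at `tc_missing_rate` (switch series stay complete so
#' the planted switch count is exact ground truth).  Deterministic given
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param n_series,n_switch Panel size and planted switch count; default from
#'   `config`.
#' @param amplitude_range Magnitude range of the planted net shift
#'   (percentage points).
#' @param seed Seed for this step; defaults to `config$seed + 2`.
#' @return A list: `tc` (wide tibble `ase_id` + one column per time point)
#'   and `truth` (`ase_id`, `is_switch`, `direction`, `amplitude`,
#'   `midpoint`, `base`).
#' @export
simulate_timecourse <- function(config, n_series = config$tc_n_series,
                                n_switch = config$tc_n_switch,
                                amplitude_range = c(60, 90),
                                seed = config$seed + 2L) {
  validate_sim_config(config)
  if (n_switch > n_series) stop("n_switch exceeds n_series", call. = FALSE)
  tp <- config$timepoints
  w <- diff(config$pivot_interval)
  lo <- config$pivot_interval[1] + 0.125 * w
  hi <- config$pivot_interval[2] - 0.125 * w
  set.seed(seed)
  is_switch <- seq_len(n_series) %in% sample.int(n_series, n_switch)
  ase_id <- sprintf("TC%04d", seq_len(n_series))
  steep <- 2
  rows <- vector("list", n_series)
  truth <- vector("list", n_series)
  for (i in seq_len(n_series)) {
    if (is_switch[i]) {
      amp <- stats::runif(1, amplitude_range[1], amplitude_range[2])
      dir <- sample(c(-1, 1), 1)
      base <- stats::runif(1, 2, 98 - amp)
      t0 <- stats::runif(1, lo, hi)
      f <- 1 / (1 + exp(-steep * (tp - t0)))
      true_psi <- if (dir > 0) base + amp * f else base + amp * (1 - f)
    } else {
      amp <- 0; dir <- 0; t0 <- NA_real_
      base <- stats::runif(1, 5, 95)
      true_psi <- rep(base, length(tp))
    }
    obs <- if (config$psi_noise_sd > 0) {
      clamp_pct(true_psi + stats::rnorm(length(tp), sd = config$psi_noise_sd))
    } else true_psi
    if (!is_switch[i] && config$tc_missing_rate > 0) {
      obs[stats::runif(length(tp)) < config$tc_missing_rate] <- NA_real_
    }
    rows[[i]] <- obs
    truth[[i]] <- tibble::tibble(ase_id = ase_id[i], is_switch = is_switch[i],
                                 direction = dir, amplitude = amp,
                                 midpoint = t0, base = base)
  }
  tc <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(tc) <- as.character(tp)
  tc <- tibble::as_tibble(cbind(tibble::tibble(ase_id = ase_id), tc))
  list(tc = tc, truth = dplyr::bind_rows(truth))
}
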