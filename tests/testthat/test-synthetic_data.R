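test_that("the planted switch count is exactly round(n_ases * fraction_switch)", {
  p <- simulate_panel(quick_config(seed = 3, fraction_switch = 0))
  expect_equal(sum(p$truth$is_switch), 0)
  p <- simulate_panel(quick_config(seed = 9, n_ases = 100, fraction_switch = 0.1))
  expect_equal(sum(p$truth$is_switch), 10)
  p <- simulate_panel(quick_config(seed = 2, n_ases = 101, fraction_switch = 0.25))
  expect_equal(sum(p$truth$is_switch), round(101 * 0.25))
})

test_that("zero noise leaves observed PSI equal to the truth; a seed fixes everything", {
  cfg <- quick_config(seed = 5, psi_noise_sd = 0)
  p <- simulate_panel(cfg)
  for (sp in cfg$species) expect_identical(p$psi[[sp]], p$psi_true[[sp]])
  p2 <- simulate_panel(cfg)
  expect_identical(p, p2)
  noisy <- simulate_panel(quick_config(seed = 5, psi_noise_sd = 5))
  expect_false(identical(noisy$psi$mouse, noisy$psi_true$mouse))
  vals <- as.matrix(noisy$psi$mouse[, -1])
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("planted truth respects the switch gap and the non-switch guard band", {
  p <- simulate_panel(quick_config(seed = 13, n_ases = 200))
  tr <- as.matrix(p$psi_true$mouse[, -1])
  sw <- p$truth$is_switch[match(group_of(p$psi_true$mouse$ase_id),
                                p$truth$group_id)]
  gaps <- abs(tr[, 1] - tr[, -1, drop = FALSE])
  expect_true(all(gaps[sw, ] > 50))       # every comparator far from brain
  expect_true(all(gaps[!sw, ] < 40))      # guard band below the threshold
  # conserved events are switch-like wherever they occur
  cons <- p$truth$group_id[p$truth$is_conserved]
  for (sp in c("human", "zebrafish")) {
    m <- p$psi_true[[sp]]
    rows <- group_of(m$ase_id) %in% cons
    g <- abs(as.matrix(m[rows, -1])[, 1] - as.matrix(m[rows, -1])[, -1])
    expect_true(all(g > 50))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(quick_config(fraction_switch = 1.2), "\\[0, 1\\]")
  expect_error(quick_config(psi_noise_sd = -1), ">= 0")
  expect_error(quick_config(size_range_nt = c(500, 100)), "min < max")
  expect_error(quick_config(event_type_probs = c(cassette = 0.9, alt5 = 0.2,
                                                 alt3 = 0, complex = 0)),
               "sum to 1")
  expect_error(sim_config(tissues_per_species = list(mouse = "brain"),
                          species = "mouse"), "comparator")
  expect_error(quick_config(pivot_interval = c(6, 99)), "inside the time span")
})

test_that("peak tables carry the molar ratios the PSI dictates", {
  cfg <- quick_config(seed = 1)
  assay <- one_assay(200, 400)
  # PSI 100: no short-product peak is emitted
  psi <- tibble::tibble(ase_id = "A1", brain = 100)
  pk <- simulate_peak_tables(psi, assay, cfg)$peaks
  expect_false(any(abs(pk$size_nt - 200) < 6))
  expect_true(any(abs(pk$size_nt - 400) < 6))
  # PSI 50 at sizes 200/400: equal molarity, so mass ratio long:short = 2:1
  psi$brain <- 50
  pk <- simulate_peak_tables(psi, assay, cfg)$peaks
  expect_equal(pk$conc[pk$size_nt == 400] / pk$conc[pk$size_nt == 200], 2)
  expect_error(simulate_peak_tables(tibble::tibble(ase_id = "A1", brain = 104),
                                    assay, cfg), "\\[0, 100\\]")
})

test_that("uncontaminated simulated lanes quantify to purity 1 and exact PSI", {
  cfg <- quick_config(seed = 21, n_ases = 30, psi_noise_sd = 0,
                      spurious_peak_rate = 0)
  p <- simulate_panel(cfg)
  assays <- p$assays[p$assays$species == "mouse", ]
  pk <- simulate_peak_tables(p$psi$mouse, assays, cfg, species = "mouse")
  q <- quantify_table(pk$peaks, assays)
  expect_true(all(q$purity == 1))
  expect_true(all(q$qc_pass))
  wide <- quant_to_psi(q, samples = cfg$tissues_per_species$mouse)
  wide <- wide[match(p$psi$mouse$ase_id, wide$ase_id), ]
  expect_equal(as.matrix(wide[, -1]), as.matrix(p$psi$mouse[, -1]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("contaminated lanes record their planted molar fraction", {
  cfg <- quick_config(seed = 8, n_ases = 40, spurious_peak_rate = 0.5)
  p <- simulate_panel(cfg)
  assays <- p$assays[p$assays$species == "mouse", ]
  sim <- simulate_peak_tables(p$psi$mouse, assays, cfg, species = "mouse")
  lt <- sim$lane_truth
  expect_gt(sum(lt$has_spurious), 0)
  expect_true(all(lt$spurious_molar_fraction[!lt$has_spurious] == 0))
  # spurious sizes never fall inside a matching window
  spur_lanes <- lt[lt$has_spurious, ]
  for (i in seq_len(nrow(spur_lanes))) {
    a <- assays[assays$ase_id == spur_lanes$ase_id[i], ]
    lane <- sim$peaks[sim$peaks$ase_id == spur_lanes$ase_id[i] &
                        sim$peaks$sample_id == spur_lanes$sample_id[i], ]
    third <- lane[!(lane$size_nt %in% c(a$size_short_nt, a$size_long_nt)), ]
    expect_equal(nrow(third), 1)
    expect_gte(abs(third$size_nt - a$size_short_nt), max(2, 0.05 * a$size_short_nt))
    expect_gte(abs(third$size_nt - a$size_long_nt), max(2, 0.05 * a$size_long_nt))
  }
})

test_that("time courses are deterministic, planted, and flat when unswitched", {
  cfg <- quick_config(seed = 4, psi_noise_sd = 0)
  tc <- simulate_timecourse(cfg)
  tc2 <- simulate_timecourse(cfg)
  expect_identical(tc, tc2)
  dyn <- dynamics_screen(tc$tc, quiet = TRUE)
  m <- merge(dyn, tc$truth, by = "ase_id")
  expect_true(all(abs(m$net_shift[!m$is_switch.y]) < 1e-9))   # flat series
  expect_true(all(abs(m$net_shift[m$is_switch.y]) > 50))
  # the realised net shift is the planted amplitude up to logistic tails
  expect_equal(abs(m$net_shift[m$is_switch.y]), m$amplitude[m$is_switch.y],
               tolerance = 0.01)
  none <- simulate_timecourse(cfg, n_switch = 0)
  expect_true(all(dynamics_screen(none$tc, quiet = TRUE)$net_shift == 0))
})

test_that("switch recovery degrades monotonically with PSI noise", {
  mean_f1 <- vapply(c(0, 5, 15), function(sd) {
    f1 <- vapply(1:20, function(s) {
      p <- simulate_panel(quick_config(seed = 100 + s, psi_noise_sd = sd))
      calls <- screen_psi(p$psi$mouse)
      ids <- stats::setNames(group_of(calls$ase_id), calls$ase_id)
      recovery_f1(calls, p$truth, id_map = ids)$f1
    }, numeric(1))
    mean(f1)
  }, numeric(1))
  expect_equal(mean_f1[1], 1)                 # zero noise: perfect recovery
  expect_true(all(diff(mean_f1) <= 1e-12))    # non-increasing in noise
})
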