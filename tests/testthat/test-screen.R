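psi_fixture <- function() {
  tibble::tibble(ase_id = c("a", "b", "c", "d"),
                 brain = c(90, 50, 90, 10),
                 kidney = c(20, 50, 20, NA),
                 liver = c(30, 50, 50, 80))
}

test_that("completeness filtering keeps only rows with data in every sample", {
  psi <- psi_fixture()
  kept <- suppressMessages(qc_filter(psi))
  expect_equal(kept$ase_id, c("a", "b", "c"))
  expect_identical(suppressMessages(qc_filter(kept)), kept)  # identity when complete
  # brute-force row scan on a synthetic matrix with ~10% failing cells
  set.seed(31)
  m <- matrix(runif(300, 0, 100), 100, 3)
  m[sample(length(m), 30)] <- NA
  big <- tibble::as_tibble(cbind(tibble::tibble(ase_id = sprintf("e%03d", 1:100)),
                                 tibble::as_tibble(m, .name_repair = ~c("t1", "t2", "t3"))))
  expect_equal(nrow(suppressMessages(qc_filter(big))),
               sum(apply(m, 1, function(r) all(!is.na(r)))))
})

test_that("the shift statistic is governed by the nearest comparator tissue", {
  expect_equal(compute_shift(90, c(20, 30)), 60)
  expect_equal(compute_shift(50, c(50, 50)), 0)
  expect_equal(compute_shift(90, c(20, 50)), 40)
  expect_true(is.na(compute_shift(90, c(20, NA))))
  expect_error(compute_shift(90, numeric(0)), "comparator")
})

test_that("switch classification is strict at the threshold", {
  expect_true(classify_switch(60))
  expect_false(classify_switch(50))        # exactly 50 is not a switch
  expect_true(classify_switch(1e-9, threshold = 0))
  expect_true(is.na(classify_switch(NA)))
})

test_that("screen calls carry shift, direction and completeness", {
  calls <- screen_psi(psi_fixture(), reference = "brain")
  expect_equal(calls$shift, c(60, 0, 40, NA))
  expect_equal(calls$is_switch, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$complete, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(calls$direction, c(1, 0, 1, NA))
  expect_error(screen_psi(psi_fixture(), reference = "cortex"), "not in")

  # permutation invariance: shuffling rows changes no call
  psi <- psi_fixture()[c(3, 1, 4, 2), ]
  shuffled <- screen_psi(psi)
  expect_equal(shuffled[order(shuffled$ase_id), ],
               calls[order(calls$ase_id), ], ignore_attr = TRUE)
})

test_that("raising the threshold can only shrink the switch set", {
  p <- simulate_panel(quick_config(seed = 17, psi_noise_sd = 5))
  psi <- p$psi$mouse
  sets <- lapply(c(30, 50, 70), function(thr) {
    calls <- screen_psi(psi, threshold = thr)
    calls$ase_id[calls$is_switch]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("at zero noise the switch calls equal the planted truth exactly", {
  p <- simulate_panel(quick_config(seed = 23, psi_noise_sd = 0))
  calls <- screen_psi(p$psi$mouse)
  truth <- p$truth$is_switch[match(group_of(calls$ase_id), p$truth$group_id)]
  expect_identical(calls$is_switch, truth)
})

test_that("the exact test matches its arithmetic example and fisher.test", {
  ft <- fisher_exact_2x2(c(78, 15, 482, 234))
  expect_equal(ft$odds_ratio, (78 * 234) / (15 * 482))
  expect_equal(ft$odds_ratio, 2.52, tolerance = 0.01)
  ref <- stats::fisher.test(matrix(c(78, 15, 482, 234), 2, byrow = TRUE))
  expect_equal(ft$p_value, ref$p.value, tolerance = 1e-12)

  expect_equal(fisher_exact_2x2(c(10, 10, 10, 10))$p_value, 1)
  expect_equal(fisher_exact_2x2(c(0, 0, 5, 5))$p_value, 1)   # degenerate margin
  expect_true(is.na(fisher_exact_2x2(c(5, 0, 3, 2))$odds_ratio))
  g <- fisher_exact_2x2(c(8, 2, 3, 7), alternative = "greater")
  expect_equal(g$p_value,
               stats::fisher.test(matrix(c(8, 2, 3, 7), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("enrichment counts only complete events and builds the 2x2 table", {
  calls <- tibble::tibble(
    ase_id = sprintf("a%02d", 1:12),
    shift = c(rep(80, 4), rep(10, 7), NA),
    direction = 1,
    is_switch = c(rep(TRUE, 4), rep(FALSE, 8)),
    complete = c(rep(TRUE, 11), FALSE))
  assays <- tibble::tibble(ase_id = calls$ase_id,
                           event_type = c(rep("cassette", 3), "alt5",
                                          rep("cassette", 2), rep("alt3", 5),
                                          "cassette"))
  e <- enrichment_test(calls, assays)
  expect_equal(as.vector(e$counts), c(3, 2, 1, 5))  # column-major
  expect_equal(sum(e$counts), 11)                   # incomplete row excluded
  expect_equal(e$odds_ratio, (3 * 5) / (1 * 2))
  expect_error(enrichment_test(dplyr::mutate(calls, is_switch = FALSE), assays),
               "at least one switch")
})

test_that("dendrogram leaf order reproduces brute-force average linkage", {
  # identical columns are adjacent in the column ordering
  psi <- tibble::tibble(ase_id = c("a", "b", "c"),
                        t1 = c(90, 10, 50), t2 = c(0, 95, 40),
                        t3 = c(90, 10, 50), t4 = c(30, 60, 45))
  ord <- cluster_order(psi, axis = "cols")
  pos <- match(c(1, 3), ord)
  expect_equal(abs(diff(pos)), 1)

  expect_equal(cluster_order(psi[1, ]), 1L)
  expect_error(cluster_order(tibble::tibble(ase_id = "a", t1 = NA_real_)),
               "missing")

  set.seed(19)
  for (i in 1:10) {
    m <- matrix(runif(15, 0, 100), 5, 3)
    psi <- tibble::as_tibble(cbind(tibble::tibble(ase_id = letters[1:5]),
                                   tibble::as_tibble(m, .name_repair = ~paste0("t", 1:3))))
    got <- cluster_order(psi, axis = "rows")
    want <- oracle_cluster_order(m)
    expect_true(identical(as.integer(got), as.integer(want)) ||
                  identical(as.integer(got), rev(as.integer(want))))
  }
})
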