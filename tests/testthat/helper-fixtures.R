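# Small study configurations and independent oracles shared across tests.

quick_config <- function(seed = 1, ...) {
  defaults <- list(
    n_ases = 60, fraction_switch = 0.2, fraction_conserved = 0.25,
    fraction_switch_second = 0.25, ortholog_rate = 0.9,
    psi_noise_sd = 0, spurious_peak_rate = 0, spurious_mass_fraction = 0.3,
    tc_n_series = 20, tc_n_switch = 6, tc_missing_rate = 0, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

one_assay <- function(short = 200, long = 400) {
  tibble::tibble(ase_id = "A1", gene = "G1", species = "mouse",
                 event_type = "cassette",
                 size_short_nt = short, size_long_nt = long)
}

peak_tbl <- function(size_nt, conc) tibble::tibble(size_nt = size_nt, conc = conc)

# map per-species simulated ase ids ("ASE00001_mouse") back to group ids
group_of <- function(ase_id) sub("_[a-z]+$", "", ase_id)

# Independent quantification oracle: for each expected size take the nearest
# in-tolerance peak (ties toward the smaller observed size), then apply the
# purity and PSI definitions directly.  Valid when the two tolerance windows
# claim disjoint peaks (always true for simulated tables).
oracle_quant <- function(peaks, assay, purity_threshold = 0.75) {
  mol <- peaks$conc / peaks$size_nt
  pick <- function(expected) {
    tol <- max(2, 0.03 * expected)
    d <- abs(peaks$size_nt - expected)
    cand <- which(d <= tol)
    if (!length(cand)) return(NA_integer_)
    cand[order(d[cand], peaks$size_nt[cand])][1L]
  }
  i_s <- pick(assay$size_short_nt); i_l <- pick(assay$size_long_nt)
  stopifnot(is.na(i_s) || is.na(i_l) || i_s != i_l)
  m_s <- if (is.na(i_s)) 0 else mol[i_s]
  m_l <- if (is.na(i_l)) 0 else mol[i_l]
  purity <- (m_s + m_l) / sum(mol)
  psi <- if (m_s + m_l > 0) 100 * m_l / (m_s + m_l) else NA_real_
  list(purity = purity, psi = psi,
       qc_pass = purity > purity_threshold && !is.na(psi))
}

# Independent exact-test oracle: enumerate every 2x2 table with the observed
# margins; probabilities from binomial coefficients.
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent average-linkage agglomeration: merge the closest pair of
# clusters (mean pairwise Euclidean distance), concatenating leaf orders.
oracle_cluster_order <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  while (length(clusters) > 1L) {
    k <- length(clusters); best <- NULL; bd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dd < bd - 1e-12) { bd <- dd; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  clusters[[1L]]
}

# Synthetic supplementary-style table in the fixed a-am column layout, with a
# planted mouse/human/stem-cell funnel.  Returns the path and the truth.
write_synthetic_s1 <- function(path, seed = 1) {
  set.seed(seed)
  n <- 40
  is_switch <- seq_len(n) <= 8          # mouse switch rows
  human_sw <- seq_len(n) <= 5           # of which switch in human too
  human_complete <- rep(TRUE, n); human_complete[9:12] <- FALSE
  tc_switch <- seq_len(n) <= 6
  tc_complete <- rep(TRUE, n); tc_complete[13:15] <- FALSE
  blank <- function(k) rep("", k)
  m <- matrix("", n, 39)
  m[, 1] <- sprintf("HS_%02d", seq_len(n))      # a: human ASE name
  m[, 2] <- sprintf("Mm%02d", seq_len(n))       # b: mouse gene
  m[, 4] <- ifelse(is_switch, "cassette", "alt5")  # d: event type
  m[, 11] <- 200; m[, 12] <- 260                # k,l: mouse product sizes
  mouse_brain <- ifelse(is_switch, 90, 50)
  m[, 14] <- mouse_brain                        # n
  m[, 15] <- ifelse(is_switch, 10, 45)          # o kidney
  m[, 16] <- ifelse(is_switch, 15, 60)          # p liver
  m[, 17] <- round(pmin(abs(mouse_brain - as.numeric(m[, 15])),
                        abs(mouse_brain - as.numeric(m[, 16]))), 1)  # q: nearest tissue
  hb <- ifelse(human_sw, 85, 40)
  hv <- cbind(hb, ifelse(human_sw, 10, 35), ifelse(human_sw, 12, 45),
              ifelse(human_sw, 20, 50), ifelse(human_sw, 25, 55),
              ifelse(human_sw, 30, 42))
  for (i in 1:6) m[, 24 + i] <- hv[, i]         # y-ad
  m[!human_complete, 26] <- ""                  # drop a tissue
  tcv <- cbind(ifelse(tc_switch, 5, 50), ifelse(tc_switch, 8, 52),
               ifelse(tc_switch, 40, 49), ifelse(tc_switch, 80, 51),
               ifelse(tc_switch, 90, 50))
  for (i in 1:5) m[, 30 + i] <- tcv[, i]        # ae-ai
  m[!tc_complete, 33] <- ""
  header <- c(letters, paste0("a", letters[1:13]))
  utils::write.table(rbind(header, m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(path = path,
       truth = list(n = n, mouse_switch = sum(is_switch),
                    human_complete = sum(human_complete),
                    human_switch = sum(human_sw & human_complete),
                    tc_complete = sum(tc_complete),
                    tc_switch = sum(tc_switch & tc_complete)))
}
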