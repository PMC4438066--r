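#' Restrict a PSI matrix to events complete in every sample
#'
#' Mirrors the screen's quality rule: an event contributes to any count only
#' if it produced a QC-passing PSI in all samples; missing cells encode failed
#' lanes.
#'
#' @param psi Wide PSI tibble (`ase_id` + one percent column per sample).
#' @param quiet Suppress the surviving-row message.
#' @return The rows of `psi` with no missing values.
#' @export
qc_filter <- function(psi, quiet = FALSE) {
  stopifnot(nrow(psi) > 0, names(psi)[1] == "ase_id")
  vals <- as.matrix(psi[, -1, drop = FALSE])
  keep <- rowSums(is.na(vals)) == 0L
  if (!quiet) {
    message(sum(keep), " of ", nrow(psi), " events complete in all ",
            ncol(vals), " samples")
  }
  psi[keep, , drop = FALSE]
}

#' Shift statistic: distance from the reference tissue to its nearest comparator
#'
#' The shift of an event is the minimum over comparator tissues of the
#' absolute PSI difference from the reference tissue (brain), in percentage
#' points — the nearest comparator governs, so a large shift means the
#' reference differs from *every* other tissue.
#'
#' @param psi_ref Reference-tissue PSI (percent).
#' @param psi_others Numeric vector of comparator PSI values.
#' @return Shift in percentage points, or `NA` if any value is missing.
#' @examples
#' compute_shift(90, c(20, 50)) # 40: the nearest tissue governs
#' @export
compute_shift <- function(psi_ref, psi_others) {
  if (length(psi_others) == 0L) stop("no comparator tissues", call. = FALSE)
  if (is.na(psi_ref) || anyNA(psi_others)) return(NA_real_)
  min(abs(psi_ref - psi_others))
}

#' Switch-like classification of a shift
#'
#' @param shift Shift in percentage points (see [compute_shift()]).
#' @param threshold Strict threshold in percentage points; an event is
#'   switch-like iff `shift > threshold`.  A shift of exactly the threshold is
#'   not a switch.
#' @return Logical; `NA` shifts propagate (not evaluable, never `FALSE`).
#' @export
classify_switch <- function(shift, threshold = 50) {
  ifelse(is.na(shift), NA, shift > threshold)
}

#' Screen a PSI matrix for switch-like reference-specific events
#'
#' Computes, per event, the shift from the reference sample to its nearest
#' comparator, the direction of the reference relative to the comparator mean,
#' and the switch flag (strict `> threshold`).  Events with any missing sample
#' are marked incomplete; they are never switch calls and are excluded from
#' enrichment counts.
#'
#' @param psi Wide PSI tibble (`ase_id` + sample columns, percent).
#' @param reference Reference sample column name (default `"brain"`).
#' @param threshold Switch threshold in percentage points.
#' @return A tibble: `ase_id`, `shift`, `direction` (sign of reference minus
#'   comparator mean), `is_switch`, `complete`.
#' @export
screen_psi <- function(psi, reference = "brain", threshold = 50) {
  stopifnot(names(psi)[1] == "ase_id")
  if (!reference %in% names(psi)) {
    stop("reference sample '", reference, "' not in PSI matrix", call. = FALSE)
  }
  others <- setdiff(names(psi)[-1], reference)
  if (!length(others)) stop("no comparator samples", call. = FALSE)
  ref <- psi[[reference]]
  oth <- as.matrix(psi[, others, drop = FALSE])
  complete <- !is.na(ref) & rowSums(is.na(oth)) == 0L
  shift <- vapply(seq_len(nrow(psi)), function(i) {
    if (!complete[i]) NA_real_ else compute_shift(ref[i], oth[i, ])
  }, numeric(1))
  direction <- ifelse(complete, sign(ref - rowMeans(oth)), NA_real_)
  is_switch <- ifelse(complete, classify_switch(shift, threshold), FALSE)
  # incomplete events are excluded, never counted as switches
  is_switch[!complete] <- FALSE
  tibble::tibble(ase_id = psi$ase_id, shift = shift, direction = direction,
                 is_switch = as.logical(is_switch), complete = complete)
}

#' Two-sided Fisher's exact test for a 2x2 table by hypergeometric enumeration
#'
#' Enumerates all tables with the observed margins; the two-sided p-value is
#' the sum of point probabilities not exceeding the observed table's
#' (point-probability rule).  Used by [enrichment_test()]; exposed for direct
#' use on printed counts.
#'
#' @param tab A 2x2 integer matrix or a length-4 vector `c(a, b, c, d)` read
#'   row-wise.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (one-sided on the top-left cell).
#' @return List with `p_value` and `odds_ratio` (sample odds ratio
#'   `(a*d)/(b*c)`; `NA` when `b*c == 0`).
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- matrix(as.numeric(tab), 2, 2, byrow = is.null(dim(tab)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c_ > 0) (a * d) / (b * c_) else NA_real_
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    return(list(p_value = 1, odds_ratio = or))  # degenerate margin
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- switch(alternative,
    two.sided = sum(dens[dens <= p_obs * (1 + 1e-7)]),
    greater   = sum(dens[support >= a]),
    less      = sum(dens[support <= a]))
  list(p_value = min(1, p), odds_ratio = or)
}

#' Event-type enrichment among switch-like events
#'
#' Builds the 2x2 table (switch / non-switch) x (cassette exon / other event
#' type) over QC-complete events and tests association with the exact test.
#' Only complete events enter either margin.
#'
#' @param calls Output of [screen_psi()].
#' @param assays Assay table with `ase_id` and `event_type`
#'   (`"cassette"`, `"alt5"`, `"alt3"`, `"complex"`).
#' @param alternative Sidedness, see [fisher_exact_2x2()].
#' @return List with `counts` (2x2 matrix), `odds_ratio` and `p_value`.
#' @export
enrichment_test <- function(calls, assays, alternative = "two.sided") {
  m <- merge(calls[calls$complete, c("ase_id", "is_switch")],
             assays[, c("ase_id", "event_type")], by = "ase_id")
  if (!any(m$is_switch) || all(m$is_switch)) {
    stop("need at least one switch and one non-switch event", call. = FALSE)
  }
  cass <- m$event_type == "cassette"
  counts <- matrix(c(sum(m$is_switch & cass), sum(m$is_switch & !cass),
                     sum(!m$is_switch & cass), sum(!m$is_switch & !cass)),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("switch", "non_switch"),
                                   c("cassette", "other")))
  ft <- fisher_exact_2x2(counts, alternative = alternative)
  list(counts = counts, odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Dendrogram leaf order for heat-map display
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the rows
#' or columns of a complete PSI matrix; only the leaf ordering is part of the
#' contract — rendering is left to the caller.  Deterministic for a given
#' input order (stats::hclust breaks ties by original index).
#'
#' @param psi Complete wide PSI tibble (`ase_id` + sample columns).
#' @param axis `"rows"` (events) or `"cols"` (samples).
#' @return Integer permutation of row (or column) indices.
#' @export
cluster_order <- function(psi, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  m <- as.matrix(psi[, -1, drop = FALSE])
  if (anyNA(m)) stop("PSI matrix has missing values; run qc_filter() first",
                     call. = FALSE)
  if (axis == "cols") m <- t(m)
  if (nrow(m) == 1L) return(1L)
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")$order
}
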