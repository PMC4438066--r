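#' Molar amount of a capillary-electrophoresis peak
#'
#' Converts the mass signal of a dsDNA peak to a molar amount by dividing the
#' mass concentration by the fragment length in nucleotides.  Fluorescent mass
#' signal is proportional to base pairs of double-stranded product, so mass
#' divided by length compares products per molecule rather than per mass; any
#' instrument-specific proportionality constant cancels in all downstream
#' ratios (PSI and purity), so the result is in arbitrary molar units.
#'
#' @param conc Mass concentration of the peak (arbitrary mass units, >= 0).
#' @param size_nt Fragment size in nucleotides (> 0).
#' @return Molar amount, `conc / size_nt`, in arbitrary molar units.
#' @examples
#' peak_molarity(100, 200) # 0.5
#' @export
peak_molarity <- function(conc, size_nt) {
  if (any(!is.finite(size_nt)) || any(size_nt <= 0)) {
    stop("peak size must be a positive number of nucleotides", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("peak concentration must be >= 0", call. = FALSE)
  }
  conc / size_nt
}

#' Size-matching tolerance for capillary electrophoresis
#'
#' A peak matches an expected product size if it lies within
#' `max(abs_nt, rel * expected)` of it; the defaults (2 nt or 3%, whichever is
#' larger) reflect typical capillary sizing accuracy.
#'
#' @param expected Expected fragment size in nt.
#' @param abs_nt Absolute tolerance floor in nt.
#' @param rel Relative tolerance as a fraction of the expected size.
#' @return Tolerance window half-width in nt.
#' @export
match_tolerance <- function(expected, abs_nt = 2, rel = 0.03) {
  pmax(abs_nt, rel * expected)
}

#' Assign observed peaks to the expected short/long products
#'
#' Each expected size takes at most one peak: the nearest observed peak within
#' tolerance, ties broken toward the smaller observed size.  Expected sizes are
#' processed short first, so in the (rare, and never simulated) case where one
#' peak is nearest to both windows the short product claims it.  All remaining
#' peaks are unmatched and count against lane purity.
#'
#' @param peaks A data frame with columns `size_nt` and `conc` (one row per
#'   peak), as read by [read_peaks()].
#' @param assay A one-row assay definition with `size_short_nt` and
#'   `size_long_nt` (see [read_assays()]).
#' @param abs_nt,rel Tolerance parameters, see [match_tolerance()].
#' @return `peaks` with an added factor column `match` taking values
#'   `"short"`, `"long"` or `"unmatched"`.
#' @export
match_peaks <- function(peaks, assay, abs_nt = 2, rel = 0.03) {
  stopifnot(is.data.frame(peaks), all(c("size_nt", "conc") %in% names(peaks)))
  if (assay$size_long_nt <= assay$size_short_nt) {
    stop("assay long product must be larger than short product", call. = FALSE)
  }
  match <- rep("unmatched", nrow(peaks))
  taken <- rep(FALSE, nrow(peaks))
  for (which_prod in c("short", "long")) {
    expected <- if (which_prod == "short") assay$size_short_nt else assay$size_long_nt
    tol <- match_tolerance(expected, abs_nt, rel)
    d <- abs(peaks$size_nt - expected)
    cand <- which(!taken & d <= tol)
    if (length(cand) == 0L) next
    # nearest peak wins; exact distance ties go to the smaller observed size
    best <- cand[order(d[cand], peaks$size_nt[cand])][1L]
    match[best] <- which_prod
    taken[best] <- TRUE
  }
  peaks$match <- match
  peaks
}

#' Lane purity: fraction of total molarity at the expected product sizes
#'
#' @param matched_peaks Output of [match_peaks()].
#' @return Purity in `[0, 1]`, or `NA` if the lane's total molarity is zero
#'   (a QC failure).
#' @export
compute_purity <- function(matched_peaks) {
  mol <- peak_molarity(matched_peaks$conc, matched_peaks$size_nt)
  total <- sum(mol)
  if (!nrow(matched_peaks) || total <= 0) return(NA_real_)
  sum(mol[matched_peaks$match != "unmatched"]) / total
}

#' Percent spliced in from product molarities
#'
#' PSI is the molarity of the long (alternative-region-containing) product
#' divided by the combined molarity of the long and short products, on the
#' percent scale.  A lane where exactly one expected product is found yields 0
#' or 100 (a fully switched lane), not a missing value; PSI is undefined only
#' when neither product is present.
#'
#' @param molarity_long,molarity_short Molar amounts, both >= 0.
#' @return PSI in percent, or `NA` if both molarities are zero.
#' @examples
#' compute_psi(3, 1) # 75
#' @export
compute_psi <- function(molarity_long, molarity_short) {
  if (any(c(molarity_long, molarity_short) < 0)) {
    stop("molarities must be >= 0", call. = FALSE)
  }
  total <- molarity_long + molarity_short
  ifelse(total > 0, 100 * molarity_long / total, NA_real_)
}

#' Quantify one assay-sample lane
#'
#' Composes peak matching, mass-to-molarity conversion, purity and PSI, and
#' applies the quality gate: a lane passes QC iff its purity is strictly
#' greater than `purity_threshold` (default 0.75, i.e. the ">75% purity" rule)
#' and PSI is defined.
#'
#' @param peaks Peak table for one lane (columns `size_nt`, `conc`).
#' @param assay One-row assay definition.
#' @param purity_threshold Strict lower purity bound for QC (fraction).
#' @param abs_nt,rel Size-matching tolerance, see [match_tolerance()].
#' @return A one-row tibble with `molarity_long`, `molarity_short`, `purity`,
#'   `psi` (percent) and `qc_pass`.
#' @export
quantify_assay <- function(peaks, assay, purity_threshold = 0.75,
                           abs_nt = 2, rel = 0.03) {
  if (!nrow(peaks)) {
    return(tibble::tibble(molarity_long = 0, molarity_short = 0,
                          purity = NA_real_, psi = NA_real_, qc_pass = FALSE))
  }
  m <- match_peaks(peaks, assay, abs_nt = abs_nt, rel = rel)
  mol <- peak_molarity(m$conc, m$size_nt)
  mol_long <- sum(mol[m$match == "long"])
  mol_short <- sum(mol[m$match == "short"])
  purity <- compute_purity(m)
  psi <- compute_psi(mol_long, mol_short)
  qc <- !is.na(purity) && purity > purity_threshold && !is.na(psi)
  tibble::tibble(molarity_long = mol_long, molarity_short = mol_short,
                 purity = purity, psi = psi, qc_pass = qc)
}

#' Quantify a full peak table
#'
#' Runs [quantify_assay()] on every (ase_id, sample_id) lane of a long-format
#' peak table and returns one row per lane.  Lanes present in `assays` but
#' absent from `peaks` are reported with undefined PSI and `qc_pass = FALSE`.
#'
#' @param peaks Long peak table: `ase_id`, `sample_id`, `size_nt`, `conc`.
#' @param assays Assay table: one row per `ase_id` with `size_short_nt` and
#'   `size_long_nt`.
#' @param purity_threshold,abs_nt,rel See [quantify_assay()].
#' @return A tibble with columns `ase_id`, `sample_id`, `molarity_long`,
#'   `molarity_short`, `purity`, `psi`, `qc_pass`.
#' @export
quantify_table <- function(peaks, assays, purity_threshold = 0.75,
                           abs_nt = 2, rel = 0.03) {
  stopifnot(all(c("ase_id", "sample_id", "size_nt", "conc") %in% names(peaks)))
  assays <- as.data.frame(assays)
  rownames(assays) <- assays$ase_id
  unknown <- setdiff(unique(peaks$ase_id), assays$ase_id)
  if (length(unknown)) {
    stop("peak table refers to assays not in the assay table: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  key <- paste(peaks$ase_id, peaks$sample_id, sep = "\r")
  lanes <- split(seq_len(nrow(peaks)), key)
  out <- lapply(lanes, function(idx) {
    lane <- peaks[idx, , drop = FALSE]
    res <- quantify_assay(lane[, c("size_nt", "conc")],
                          assays[lane$ase_id[1L], , drop = FALSE],
                          purity_threshold = purity_threshold,
                          abs_nt = abs_nt, rel = rel)
    cbind(ase_id = lane$ase_id[1L], sample_id = lane$sample_id[1L], res)
  })
  res <- dplyr::bind_rows(out)
  tibble::as_tibble(res[order(match(res$ase_id, assays$ase_id), res$sample_id), ])
}

#' Reshape lane-level quantification into a PSI matrix
#'
#' QC-failing lanes become missing (`NA`) cells, so downstream completeness
#' filters see exactly the lanes that passed the purity gate.
#'
#' @param quant Output of [quantify_table()].
#' @param samples Optional sample ordering for the columns.
#' @return A wide tibble: `ase_id` plus one PSI column (percent) per sample.
#' @export
quant_to_psi <- function(quant, samples = NULL) {
  quant$psi[!quant$qc_pass] <- NA_real_
  wide <- tidyr::pivot_wider(quant[, c("ase_id", "sample_id", "psi")],
                             names_from = "sample_id", values_from = "psi")
  if (!is.null(samples)) wide <- wide[, c("ase_id", samples)]
  wide
}
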