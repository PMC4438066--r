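#' Summary statistics of a PSI time course
#'
#' The switch statistic is the *net* first-to-last PSI shift (switch-like
#' dynamics move in one direction), with the range reported alongside for
#' diagnostics; a transient excursion that returns to baseline is not a
#' switch.  The pivot interval is the pair of consecutive time points with the
#' largest absolute PSI change (earliest such pair on ties).
#'
#' @param times Strictly increasing numeric time points (days of
#'   differentiation or hours post fertilisation).
#' @param psi PSI in percent at each time point; must be complete.
#' @param threshold Strict switch threshold in percentage points on
#'   `|net_shift|`.
#' @return A one-row tibble: `net_shift`, `range`, `direction`, `is_switch`,
#'   `pivot_lo`, `pivot_hi`.
#' @examples
#' timecourse_stats(c(0, 2, 6, 10, 14), c(10, 12, 70, 85, 88))
#' @export
timecourse_stats <- function(times, psi, threshold = 50) {
  if (length(times) < 2L || length(psi) != length(times)) {
    stop("need >= 2 time points with one PSI value each", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (anyNA(psi)) stop("time course is incomplete; exclude it upstream", call. = FALSE)
  net <- psi[length(psi)] - psi[1L]
  rng <- max(psi) - min(psi)
  step <- diff(psi)
  piv <- which.max(abs(step))  # earliest maximal jump on ties
  tibble::tibble(net_shift = net, range = rng, direction = sign(net),
                 is_switch = abs(net) > threshold,
                 pivot_lo = times[piv], pivot_hi = times[piv + 1L])
}

#' Summarise a set of time courses
#'
#' Applies [timecourse_stats()] to every complete series of a wide time-course
#' table; incomplete series are excluded and reported in a message, mirroring
#' the good-data-at-all-time-points rule.
#'
#' @param tc Wide tibble: `ase_id` plus one PSI column per time point; column
#'   names must parse to numeric times.
#' @param threshold Switch threshold, see [timecourse_stats()].
#' @param quiet Suppress the exclusion message.
#' @return A tibble with one row per complete series plus a `complete` count
#'   attribute; columns `ase_id`, `net_shift`, `range`, `direction`,
#'   `is_switch`, `pivot_lo`, `pivot_hi`.
#' @export
dynamics_screen <- function(tc, threshold = 50, quiet = FALSE) {
  stopifnot(names(tc)[1] == "ase_id")
  times <- suppressWarnings(as.numeric(names(tc)[-1]))
  if (anyNA(times)) {
    stop("time-course column names must parse to numbers: ",
         paste(names(tc)[-1][is.na(times)], collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(tc[, -1, drop = FALSE])
  complete <- rowSums(is.na(vals)) == 0L
  if (!quiet && any(!complete)) {
    message(sum(!complete), " series excluded (missing time points); ",
            sum(complete), " complete")
  }
  rows <- lapply(which(complete), function(i) {
    cbind(ase_id = tc$ase_id[i],
          timecourse_stats(times, vals[i, ], threshold = threshold))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_complete") <- sum(complete)
  attr(out, "n_total") <- nrow(tc)
  out
}

#' Onset time of the brain-specific isoform
#'
#' First time point at which the brain-specific isoform's PSI strictly
#' exceeds the detection threshold.  The series must be oriented: if the
#' brain-specific isoform is the short product, PSI is flipped to `100 - psi`
#' before scanning.
#'
#' @param times Strictly increasing time points.
#' @param psi Complete PSI series (percent).
#' @param detect Detection threshold in percentage points (strict).
#' @param brain_isoform `"long"` or `"short"`: which product is the
#'   brain-specific isoform.  There is no default — the orientation must be
#'   stated by the caller.
#' @return The onset time, or `NA` if the threshold is never exceeded.
#' @examples
#' onset_time(c(2, 12, 24, 48), c(0, 0, 15, 60), detect = 10,
#'            brain_isoform = "long") # 24
#' @export
onset_time <- function(times, psi, detect = 10, brain_isoform) {
  if (missing(brain_isoform)) {
    stop("orientation unknown: set brain_isoform = \"long\" or \"short\" ",
         "so the brain-specific product's PSI is scanned", call. = FALSE)
  }
  brain_isoform <- match.arg(brain_isoform, c("long", "short"))
  if (anyNA(psi)) stop("time course is incomplete", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  p <- if (brain_isoform == "short") 100 - psi else psi
  hit <- which(p > detect)
  if (!length(hit)) NA_real_ else times[hit[1L]]
}
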