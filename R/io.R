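# Text-table conventions: header row, tab (or comma for peak tables)
# separated, "NA" for missing, "." decimal separator, PSI written with one
# decimal on the percent scale.

fmt_psi <- function(x) ifelse(is.na(x), NA_real_, round(x, 1))

#' Read / write the assay annotation table
#'
#' Columns: `ase_id`, `gene`, `species`, `event_type`, `size_short_nt`,
#' `size_long_nt` (tab-separated).
#' @param path File path.
#' @return A tibble.
#' @export
read_assays <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  need <- c("ase_id", "gene", "species", "event_type",
            "size_short_nt", "size_long_nt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("assay table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- x$size_long_nt <= x$size_short_nt
  if (any(bad)) stop("long product must exceed short product (first bad: ",
                     x$ase_id[bad][1L], ")", call. = FALSE)
  x
}

#' @rdname read_assays
#' @param assays Assay tibble.
#' @export
write_assays <- function(assays, path) {
  readr::write_tsv(assays, path, na = "NA")
  invisible(path)
}

#' Read / write peak tables
#'
#' Comma-separated with columns `ase_id`, `sample_id`, `size_nt`, `conc`, as
#' produced by capillary-electrophoresis instrument export.
#' @param path File path.
#' @return A tibble.
#' @export
read_peaks <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  need <- c("ase_id", "sample_id", "size_nt", "conc")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("peak table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(x$size_nt <= 0) || any(x$conc < 0)) {
    stop("peaks need size_nt > 0 and conc >= 0", call. = FALSE)
  }
  x
}

#' @rdname read_peaks
#' @param peaks Peak tibble.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_csv(peaks, path, na = "NA")
  invisible(path)
}

#' Read / write a wide PSI matrix
#'
#' First column `ase_id`, one column per sample, percent scale, `NA` for
#' missing/QC-failed cells; written with one decimal.
#' @param path File path.
#' @return A tibble.
#' @export
read_psi <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  if (names(x)[1] != "ase_id") stop("first column must be ase_id", call. = FALSE)
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    stop("PSI values must lie in [0, 100]", call. = FALSE)
  }
  x
}

#' @rdname read_psi
#' @param psi Wide PSI tibble.
#' @export
write_psi <- function(psi, path) {
  out <- psi
  out[, -1] <- lapply(out[, -1, drop = FALSE], fmt_psi)
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read / write an ortholog map
#'
#' Tab-separated `group_id`, `species`, `ase_id`.
#' @param path File path.
#' @return A tibble.
#' @export
read_orthologs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  miss <- setdiff(c("group_id", "species", "ase_id"), names(x))
  if (length(miss)) stop("ortholog map lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x
}

#' @rdname read_orthologs
#' @param map Ortholog tibble.
#' @export
write_orthologs <- function(map, path) {
  readr::write_tsv(map, path, na = "NA")
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [sim_config()] plus
#' `purity_threshold`, `switch_threshold`, `reference`, `out_dir`; unknown
#' keys are an error.  Thresholds are validated (`purity_threshold` in
#' `[0, 1]`, `switch_threshold` in `[0, 100]`).
#' @param path YAML file.
#' @return A named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- list(purity_threshold = 0.75, switch_threshold = 50,
                   match_abs_nt = 2, match_rel = 0.03,
                   reference = "brain", out_dir = ".", seed = 1L)
  sim_keys <- names(formals(sim_config))
  unknown <- setdiff(names(user), c(names(defaults), sim_keys))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  if (cfg$purity_threshold < 0 || cfg$purity_threshold > 1) {
    stop("purity_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$switch_threshold < 0 || cfg$switch_threshold > 100) {
    stop("switch_threshold must lie in [0, 100]", call. = FALSE)
  }
  cfg
}

excel_col_index <- function(label) {
  chars <- strsplit(tolower(label), "")[[1]]
  Reduce(function(acc, ch) acc * 26L + match(ch, letters), chars, 0L)
}

#' Read a supplementary splicing table in the cross-evolutionary S1 layout
#'
#' Maps the fixed column layout (spreadsheet columns a–am) of the deposited
#' splicing table to the package's containers: mouse assay sizes (k, l),
#' mouse brain/kidney/liver PSI (n–p), human product sizes (v, w), human
#' six-tissue PSI (y–ad), neural stem-cell PSI at days 0/2/6/10/14 (ae–ai)
#' and zebrafish product sizes (al, am).  Columns are taken by position, so
#' the header text may vary; blank cells become missing values; PSI is on the
#' percent scale.  Accepts a `.xls`/`.xlsx` sheet (via readxl, if installed)
#' or a tab-separated export with the same 39-column layout.
#'
#' @param path Spreadsheet or TSV file.
#' @param sheet Sheet index for spreadsheet input.
#' @return A list: `assays_mouse`, `psi_mouse`, `psi_human`, `stemcell_tc`
#'   (wide, columns `0,2,6,10,14`), `shift_reported` (column q), `n_rows`.
#' @export
read_supplementary_table <- function(path, sheet = 1) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheet input needs the readxl package; ",
           "export the sheet as TSV instead", call. = FALSE)
    }
    raw <- readxl::read_excel(path, sheet = sheet, col_types = "text")
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                           col_types = readr::cols(.default = "c"))
  }
  n_need <- excel_col_index("am")
  if (ncol(raw) < n_need) {
    first_missing <- ncol(raw) + 1L
    lab <- c(letters, paste0("a", letters))[first_missing]
    stop("unrecognised layout: expected ", n_need, " columns (a-am), found ",
         ncol(raw), "; first unmapped column: ", lab, call. = FALSE)
  }
  col <- function(label) raw[[excel_col_index(label)]]
  num <- function(label) suppressWarnings(as.numeric(col(label)))
  ase_id <- as.character(col("a"))
  assays_mouse <- tibble::tibble(
    ase_id = ase_id, gene = as.character(col("b")), species = "mouse",
    event_type = tolower(as.character(col("d"))),
    size_short_nt = num("k"), size_long_nt = num("l"))
  psi_mouse <- tibble::tibble(ase_id = ase_id, brain = num("n"),
                              kidney = num("o"), liver = num("p"))
  human_cols <- c("y", "z", "aa", "ab", "ac", "ad")
  psi_human <- tibble::tibble(ase_id = ase_id)
  for (i in seq_along(human_cols)) {
    psi_human[[c("brain", "kidney", "liver", "lung", "muscle",
                 "heart")[i]]] <- num(human_cols[i])
  }
  sc_cols <- c("ae", "af", "ag", "ah", "ai")
  stemcell <- tibble::tibble(ase_id = ase_id)
  for (i in seq_along(sc_cols)) {
    stemcell[[as.character(c(0, 2, 6, 10, 14)[i])]] <- num(sc_cols[i])
  }
  list(assays_mouse = assays_mouse, psi_mouse = psi_mouse,
       psi_human = psi_human, stemcell_tc = stemcell,
       shift_reported = num("q"), n_rows = nrow(raw))
}
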