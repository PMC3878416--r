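# CSV (RFC 4180, UTF-8, header row) readers/writers with schema checks.

FIELD_COLS <- c("trial", "block", "field_row", "field_column", "cultivar")
LAB_COLS <- c("trial", "block", "day", "plate", "plate_plot", "plate_row",
              "plate_column", "cultivar", "copy", "is_standard")
PHENO_COLS <- c(LAB_COLS[1:2], "field_row", "field_column", LAB_COLS[3:10], "sugar")

check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop2(what, " file is missing required column(s): ",
          paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Read a cultivar list (plain text, one id per line)
#' @param path file path.
#' @return character vector of unique cultivar ids.
#' @export
read_cultivar_list <- function(path) {
  ids <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    stop2("duplicate cultivar ids in ", path, ": ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ids
}

#' Write a cultivar list
#' @param ids character vector of cultivar ids.
#' @param path file path.
#' @export
write_cultivar_list <- function(ids, path) {
  writeLines(as.character(ids), path, useBytes = TRUE)
  invisible(path)
}

#' Write a design or phenotype table as CSV
#' @param x a `field_design`, `lab_design` or `phenotype_table`.
#' @param path file path.
#' @export
write_design <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_design
#' @export
write_phenotypes <- write_design

#' Read a field design CSV
#' @param path file path.
#' @return a `field_design` data.frame.
#' @export
read_field_design <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  check_schema(df, FIELD_COLS, "field design")
  df$trial <- as.character(df$trial); df$cultivar <- as.character(df$cultivar)
  class(df) <- c("field_design", "data.frame")
  df
}

#' Read a lab design CSV
#' @param path file path.
#' @return a `lab_design` data.frame.
#' @export
read_lab_design <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  check_schema(df, LAB_COLS, "lab design")
  df$trial <- as.character(df$trial); df$cultivar <- as.character(df$cultivar)
  df$is_standard <- as.logical(df$is_standard)
  class(df) <- c("lab_design", "data.frame")
  df
}

#' Read a phenotype table CSV
#'
#' Validates the schema: all required columns present, `sugar` numeric and
#' finite, and no duplicated well keys
#' (`trial`, `block`, `plate`, `plate_row`, `plate_column`); violations are
#' reported with their row numbers.
#'
#' @param path file path.
#' @return a `phenotype_table` data.frame (unknown columns preserved).
#' @export
read_phenotypes <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  check_schema(df, PHENO_COLS, "phenotype")
  if (!is.numeric(df$sugar)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$sugar))))
    stop2("non-numeric sugar values at row(s): ",
          paste(head(bad, 10), collapse = ", "))
  }
  if (anyNA(df$sugar) || any(!is.finite(df$sugar))) {
    bad <- which(!is.finite(df$sugar))
    stop2("missing or non-finite sugar values at row(s): ",
          paste(head(bad, 10), collapse = ", "))
  }
  key <- paste(df$trial, df$block, df$plate, df$plate_row, df$plate_column)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop2("duplicated well keys (trial, block, plate, plate_row, ",
          "plate_column) at row(s): ", paste(head(bad, 10), collapse = ", "))
  }
  df$trial <- as.character(df$trial); df$cultivar <- as.character(df$cultivar)
  df$is_standard <- as.logical(df$is_standard)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write or read a fit result
#'
#' The fit is stored as JSON (estimates, log likelihood, convergence,
#' per-trial heritability and fixed means, dropped terms) together with a
#' companion EBLUP CSV (`trial`, `cultivar`, `eblup`, `pev_diag`). The
#' full PEV blocks are not serialised; recompute them by refitting if
#' needed.
#'
#' @param fit a [fit_reml()] result.
#' @param path JSON output path; the EBLUP CSV lands next to it with
#'   suffix `_eblups.csv`.
#' @return `write_fit`: the path, invisibly. `read_fit`: a list mirroring
#'   the serialised fields plus the `eblups` data.frame.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "met_fit"))
  herit <- tryCatch(
    setNames(lapply(fit$trials, function(tr) heritability(fit, tr)), fit$trials),
    error = function(e) NULL)
  obj <- list(
    kind = fit$kind, trials = fit$trials,
    theta = as.list(fit$theta), loglik = fit$loglik,
    n_params = fit$n_params,
    fixed_estimates = as.list(fit$fixed_estimates),
    converged = fit$converged, iterations = fit$iterations,
    dropped_terms = fit$dropped_terms,
    heritability = herit,
    avg_pev = if (length(fit$pev_blocks)) avg_pev(fit) else NULL,
    n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(fit$eblups))
    data.table::fwrite(fit$eblups, sub("\\.json$", "_eblups.csv", path))
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- sub("\\.json$", "_eblups.csv", path)
  if (file.exists(ep)) obj$eblups <- as.data.frame(data.table::fread(ep))
  obj$theta <- unlist(obj$theta)
  obj$fixed_estimates <- unlist(obj$fixed_estimates)
  obj
}
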