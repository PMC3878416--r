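#' Field-vs-laboratory confounding diagnostics
#'
#' The laboratory re-randomisation exists so that a sample's field position
#' is not confounded with its order of laboratory processing. For each
#' replicate block this returns the Spearman rank correlation between a
#' sample's field column and the processing order of its plate, and the
#' largest number of samples from any single field column that share a
#' plate. Designs exceeding the configured thresholds are flagged.
#'
#' @param field a `field_design`.
#' @param lab the matching `lab_design` (same trial).
#' @param rho_threshold flag a block when `|rank correlation|` exceeds this.
#' @param max_share_threshold flag a block when more than this many samples
#'   of one field column share a plate.
#' @param allow_missing_field_samples if `TRUE` (default) the field design
#'   may contain cultivars absent from the laboratory design (an
#'   availability mask); the reverse is always an error.
#' @return data.frame with one row per block: `block`, `n_samples`,
#'   `rank_cor`, `max_column_share`, `flagged`.
#' @export
check_confounding <- function(field, lab, rho_threshold = 0.2,
                              max_share_threshold = 4,
                              allow_missing_field_samples = TRUE) {
  stopifnot(is.data.frame(field), is.data.frame(lab))
  key <- paste(lab$plate, lab$plate_plot)
  smp <- lab[!lab$is_standard & !duplicated(key), ]
  fld <- field[field$cultivar != "EMPTY", ]

  res <- lapply(sort(unique(smp$block)), function(b) {
    sb <- smp[smp$block == b, ]
    fb <- fld[fld$block == b, ]
    extra_lab <- setdiff(sb$cultivar, fb$cultivar)
    extra_fld <- setdiff(fb$cultivar, sb$cultivar)
    if (length(extra_lab) ||
        (!allow_missing_field_samples && length(extra_fld)))
      stop2("block ", b, ": sample sets differ between field and lab; ",
            "symmetric difference: ",
            paste(head(c(extra_lab, extra_fld), 10), collapse = ", "))
    fc <- fb$field_column[match(sb$cultivar, fb$cultivar)]
    rho <- suppressWarnings(cor(fc, sb$plate, method = "spearman"))
    share <- max(table(paste(sb$plate, fc)))
    data.frame(block = b, n_samples = nrow(sb), rank_cor = rho,
               max_column_share = as.integer(share),
               flagged = abs(rho) > rho_threshold | share > max_share_threshold)
  })
  do.call(rbind, res)
}
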