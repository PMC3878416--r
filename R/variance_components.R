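#' Field and laboratory random-term vocabulary
#'
#' The twelve random model terms indexing the two randomisation phases:
#' field terms (`F_*`) describe the pot grid, laboratory terms (`L_*`)
#' describe 96-well plate processing. Each term is scoped per trial and
#' carries its own variance.
#'
#' @return named list mapping term name to the phenotype-table factor
#'   columns whose interaction defines the term's levels.
#' @export
met_terms <- function() {
  list(
    F_block       = "block",
    F_row         = "field_row",
    F_column      = "field_column",
    F_rowxcol     = c("field_row", "field_column"),
    L_day         = "day",
    L_dayxplate   = c("day", "plate"),
    L_platexplot  = c("plate", "plate_plot"),
    L_column      = "plate_column",
    L_row         = "plate_row",
    L_platexcolumn = c("plate", "plate_column"),
    L_platexrow   = c("plate", "plate_row"),
    L_rowxcol     = c("plate_row", "plate_column")
  )
}

#' Declare the variance-component structure of a two-phase MET
#'
#' Collects, per trial: the variances of the field/laboratory random terms
#' (squared response units; absent terms carry 0), the genetic variance,
#' and the residual (technical-replicate) variance; plus one cross-trial
#' genetic correlation. These are both the generative parameters of
#' [simulate_met()] and the estimands of [fit_reml()].
#'
#' @param terms named list, one named numeric vector per trial
#'   (term name -> variance; names from [met_terms()]).
#' @param genetic_var named numeric, genetic variance per trial.
#' @param genetic_correlation cross-trial genetic correlation in \[-1, 1\].
#' @param residual_var named numeric, residual variance per trial.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(terms, genetic_var, genetic_correlation = 0,
                                residual_var) {
  trials <- names(genetic_var)
  if (is.null(trials) || anyDuplicated(trials))
    stop2("genetic_var must be named by unique trial labels")
  stopifnot(setequal(names(terms), trials), setequal(names(residual_var), trials))
  vocab <- names(met_terms())
  for (tr in trials) {
    tt <- terms[[tr]]
    bad <- setdiff(names(tt), vocab)
    if (length(bad)) stop2("unknown random terms: ", paste(bad, collapse = ", "))
    if (any(tt < 0)) stop2("negative variance in trial ", tr)
  }
  if (any(genetic_var < 0) || any(residual_var < 0))
    stop2("variances must be non-negative")
  if (abs(genetic_correlation) > 1) stop2("|genetic correlation| must be <= 1")
  structure(list(trials = trials,
                 terms = terms[trials],
                 genetic_var = genetic_var,
                 genetic_correlation = genetic_correlation,
                 residual_var = residual_var[trials]),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components for trials:", paste(x$trials, collapse = ", "), "\n")
  for (tr in x$trials) {
    cat(sprintf("  %s: genetic %.3g, residual %.3g, %d F/L terms (total %.3g)\n",
                tr, x$genetic_var[[tr]], x$residual_var[[tr]],
                sum(x$terms[[tr]] > 0), sum(x$terms[[tr]])))
  }
  cat(sprintf("  cross-trial genetic correlation: %.3g\n", x$genetic_correlation))
  invisible(x)
}

#' Restrict a variance-component declaration to a subset of trials
#'
#' @param vc a [variance_components()] object.
#' @param trials trial labels to keep.
#' @return a [variance_components()] object for those trials (the genetic
#'   correlation is kept only when two trials remain).
#' @export
vc_subset <- function(vc, trials) {
  stopifnot(all(trials %in% vc$trials))
  variance_components(
    terms = vc$terms[trials],
    genetic_var = vc$genetic_var[trials],
    genetic_correlation = if (length(trials) >= 2) vc$genetic_correlation else 0,
    residual_var = vc$residual_var[trials])
}

#' Realized random-term lists of a variance-component declaration
#'
#' Term names with positive variance, per trial: the term sets a model
#' fit to data generated from `vc` should carry.
#'
#' @param vc a [variance_components()] object.
#' @return named list of character vectors, one per trial.
#' @export
realized_term_lists <- function(vc) {
  lapply(setNames(vc$trials, vc$trials),
         function(tr) names(vc$terms[[tr]])[vc$terms[[tr]] > 0])
}

#' Preset variance components of the barley saccharification screen
#'
#' REML variance-component magnitudes of the published two-trial barley
#' straw sugar-release screen (nmol glucose/mg dry matter, squared units),
#' used as the package's default simulation world: trial `"2010"` is
#' dominated by field-block and laboratory day/plate effects, trial
#' `"2011"` has smaller overall variance; the cross-trial genetic
#' correlation is 0.66. One term per trial is absent (variance 0):
#' plate-by-column in 2010 and field row in 2011.
#'
#' @return a [variance_components()] object for trials `"2010"`, `"2011"`.
#' @export
vc_preset_trials <- function() {
  t2010 <- c(F_block = 54.0, F_column = 2.1, F_row = 0.4, F_rowxcol = 16.8,
             L_day = 32.2, L_dayxplate = 28.3, L_platexplot = 37.5,
             L_column = 4.1, L_row = 12.8, L_platexcolumn = 0,
             L_platexrow = 32.5, L_rowxcol = 1.6)
  t2011 <- c(F_block = 0.7, F_column = 0.8, F_row = 0, F_rowxcol = 19.1,
             L_day = 1.6, L_dayxplate = 10.0, L_platexplot = 18.3,
             L_column = 4.8, L_row = 8.5, L_platexcolumn = 2.7,
             L_platexrow = 7.4, L_rowxcol = 0.7)
  variance_components(
    terms = list("2010" = t2010, "2011" = t2011),
    genetic_var = c("2010" = 13.5, "2011" = 6.9),
    genetic_correlation = 0.66,
    residual_var = c("2010" = 27.4, "2011" = 11.5))
}

#' Preset trial means of the barley saccharification screen
#'
#' Overall mean sugar release per trial, nmol glucose/mg dry matter.
#' @return named numeric vector.
#' @export
trial_means_preset <- function() c("2010" = 93.3, "2011" = 54.0)
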