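#' Generalized heritability of a trial
#'
#' Computes `1 - a / (2 * vg)` where `vg` is the trial's genetic variance
#' and `a` is the average pairwise prediction error variance of cultivar
#' effects, `mean over pairs (i, j) of (pev_ii + pev_jj - 2 pev_ij)`,
#' evaluated through the identity
#' `a = 2 (m * trace(PEV) - sum(PEV)) / (m (m - 1))` on the within-trial
#' PEV block. In a balanced one-way design this reduces to the classical
#' line-mean heritability `vg / (vg + ve / r)`.
#'
#' @param fit a converged [fit_reml()] result.
#' @param trial trial label.
#' @return heritability (scalar in `(-Inf, 1]`, typically `[0, 1]`).
#' @export
heritability <- function(fit, trial) {
  stopifnot(inherits(fit, "met_fit"))
  if (!trial %in% fit$trials) stop2("unknown trial: ", trial)
  vg <- fit$theta[[paste0("g_var.", trial)]]
  if (!is.finite(vg) || vg <= 0) stop2("genetic variance of trial ", trial,
                                       " is at the boundary")
  P <- fit$pev_blocks[[trial]]
  a <- avg_pairwise_pev(P)
  1 - a / (2 * vg)
}

#' Average pairwise prediction error variance of a PEV block
#'
#' @param P square PEV matrix (m >= 2).
#' @return `mean_{i != j} (P_ii + P_jj - 2 P_ij)`.
#' @export
avg_pairwise_pev <- function(P) {
  m <- nrow(P)
  stopifnot(m >= 2L, ncol(P) == m)
  2 * (m * sum(diag(P)) - sum(P)) / (m * (m - 1))
}

#' Average prediction error variance of cultivar effects
#'
#' Mean of the diagonal of the cultivar-effect PEV block across all
#' cultivar-by-trial effects: a summary of how far predicted cultivar
#' effects sit from the true ones (smaller is better).
#'
#' @param fit a converged [fit_reml()] result.
#' @return scalar.
#' @export
avg_pev <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  mean(unlist(lapply(fit$pev_blocks, diag), use.names = FALSE))
}

#' Log likelihood ratio test between nested REML fits
#'
#' `statistic = 2 (l_full - l_nested)`, degrees of freedom the difference
#' in variance-parameter count, p-value from the chi-square upper tail.
#' When the restriction pins variances to the boundary of the parameter
#' space (e.g. all field/laboratory variances zero in model B vs A) the
#' naive chi-square reference is conservative; a caveat attribute is set.
#'
#' @param nested,full [fit_reml()] results (or lists with `loglik` and
#'   `n_params`) on the same data, `nested` a restriction of `full`.
#' @param tol numerical tolerance for a negative statistic before it is
#'   treated as an optimiser failure.
#' @return data.frame with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(nested, full, tol = 1e-4) {
  ln <- nested$loglik; lf <- full$loglik
  dn <- nested$n_params; df_ <- full$n_params - dn
  if (is.null(ln) || is.null(lf)) stop2("fits must carry loglik and n_params")
  if (df_ < 0) stop2("'full' has fewer variance parameters than 'nested'")
  stat <- 2 * (lf - ln)
  if (stat < -tol)
    stop2("full-model log likelihood below nested model (", signif(stat, 4),
          "): optimizer failure")
  stat <- max(stat, 0)
  p <- if (df_ > 0) pchisq(stat, df_, lower.tail = FALSE) else NA_real_
  out <- data.frame(statistic = stat, df = df_, p_value = p)
  attr(out, "boundary_caveat") <-
    "variance restrictions lie on the parameter-space boundary; the naive chi-square p-value is conservative"
  out
}

#' Cross-trial genetic correlation of a MET fit
#'
#' `rho = cov_g / sqrt(vg_1 * vg_2)` from the fitted 2x2 genetic
#' covariance; defined for model kind C only.
#'
#' @param fit a converged model-C [fit_reml()] result.
#' @param boundary_tol relative threshold below which a genetic variance
#'   counts as on the boundary (correlation undefined).
#' @return correlation in `[-1, 1]`.
#' @export
genetic_correlation <- function(fit, boundary_tol = 1e-8) {
  stopifnot(inherits(fit, "met_fit"))
  if (!"g_cor" %in% names(fit$theta))
    stop2("fit has no cross-trial genetic covariance (model C required)")
  v <- fit$theta[paste0("g_var.", fit$trials)]
  tot <- sum(fit$theta[setdiff(names(fit$theta), "g_cor")])
  if (any(v <= boundary_tol * tot))
    stop2("a genetic variance is at the boundary; correlation undefined")
  unname(fit$theta[["g_cor"]])
}

#' Cross-trial genetic covariance of a MET fit
#'
#' The off-diagonal element of the fitted 2x2 genetic covariance matrix,
#' `cov_g = rho * sqrt(vg_1 * vg_2)` (the model parameterises the
#' covariance through the correlation, which keeps the matrix positive
#' definite at every iterate).
#'
#' @param fit a converged model-C [fit_reml()] result.
#' @return covariance in squared response units.
#' @export
genetic_covariance <- function(fit) {
  rho <- genetic_correlation(fit)
  v <- fit$theta[paste0("g_var.", fit$trials)]
  unname(rho * sqrt(v[1] * v[2]))
}

#' Variance-component table with percent of total
#'
#' Reproduces the standard MET reporting layout: each component's variance
#' and its percent of the trial's total variation (all field, laboratory,
#' genetic and residual components), rounded to one decimal place, with
#' Field and Laboratory subtotal rows whose variances are sums of the
#' component variances and whose percentages are sums of the *rounded*
#' component percentages (the conventional table arithmetic).
#'
#' @param components named numeric: field/laboratory term variances (names
#'   from [met_terms()]), plus `Cultivar` and `Residual`.
#' @return data.frame `term`, `variance`, `percent`, `group`.
#' @export
variance_percent_table <- function(components) {
  stopifnot(is.numeric(components), !is.null(names(components)))
  vocab <- names(met_terms())
  extra <- setdiff(names(components), c(vocab, "Cultivar", "Residual"))
  if (length(extra)) stop2("unknown components: ", paste(extra, collapse = ", "))
  total <- sum(components)
  pct <- function(v) round(100 * v / total, 1)
  f_terms <- intersect(vocab[startsWith(vocab, "F_")], names(components))
  l_terms <- intersect(vocab[startsWith(vocab, "L_")], names(components))
  rows <- list()
  add <- function(term, v, group) {
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, variance = v, percent = pct(v), group = group,
      stringsAsFactors = FALSE)
  }
  for (t in f_terms) add(t, components[[t]], "Field")
  if (length(f_terms)) {
    fsum <- sum(components[f_terms])
    rows[[length(rows) + 1L]] <- data.frame(
      term = "Field Total", variance = fsum,
      percent = sum(pct(components[f_terms])), group = "Field",
      stringsAsFactors = FALSE)
  }
  for (t in l_terms) add(t, components[[t]], "Laboratory")
  if (length(l_terms)) {
    lsum <- sum(components[l_terms])
    rows[[length(rows) + 1L]] <- data.frame(
      term = "Laboratory Total", variance = lsum,
      percent = sum(pct(components[l_terms])), group = "Laboratory",
      stringsAsFactors = FALSE)
  }
  if ("Cultivar" %in% names(components))
    add("Cultivar", components[["Cultivar"]], "Genetic")
  if ("Residual" %in% names(components))
    add("Residual", components[["Residual"]], "Residual")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Variance table of a fitted trial
#'
#' @param fit a converged [fit_reml()] result.
#' @param trial trial label.
#' @return [variance_percent_table()] of the trial's estimated components.
#' @export
variance_table <- function(fit, trial) {
  stopifnot(inherits(fit, "met_fit"))
  if (!trial %in% fit$trials) stop2("unknown trial: ", trial)
  th <- fit$theta
  keys <- grep(paste0("^v\\.", trial, "\\."), names(th), value = TRUE)
  comp <- setNames(unname(th[keys]), sub(paste0("^v\\.", trial, "\\."), "", keys))
  gk <- paste0("g_var.", trial)
  if (gk %in% names(th)) comp["Cultivar"] <- th[[gk]]
  comp["Residual"] <- th[[paste0("resid.", trial)]]
  variance_percent_table(comp)
}
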