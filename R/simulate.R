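#' Simulate a multi-environment, two-phase phenotype table
#'
#' Draws well-level sugar-release observations from the linear mixed model
#' the analysis assumes: response = trial mean + genetic effect + sum of
#' field/laboratory random-term effects + residual. Genetic effects of
#' cultivars present in both trials are drawn once per cultivar from a
#' bivariate normal with the per-trial genetic variances and the
#' cross-trial correlation; cultivars in a single trial draw from the
#' marginal. Every random term draws independent normal effects per level.
#' The four technical replicates of a sample share all effects except the
#' residual. Standard wells (plate columns 11-12) receive fixed known true
#' means plus laboratory effects and residual; they carry no genetic or
#' field terms and are excluded from model fitting.
#'
#' @param field_designs named list (by trial) of field designs.
#' @param lab_designs named list (by trial) of matching lab designs.
#' @param vc a [variance_components()] object covering the same trials.
#' @param means named numeric of per-trial overall means
#'   (nmol glucose/mg DM).
#' @param seed integer seed; identical seeds reproduce the table exactly.
#' @param standard_means named numeric of true means for the four standard
#'   samples. The published screen does not state them; the defaults are
#'   arbitrary labelled constants spanning the response range.
#' @param genetic_shift optional named numeric (cultivar -> shift) added to
#'   that cultivar's genetic effect in every trial (spike-in experiments).
#' @return a `phenotype_table` data.frame, one row per well: all design
#'   factors plus `sugar`. Attribute `true_genetic` holds the drawn
#'   genetic effects (cultivar x trial).
#' @export
simulate_met <- function(field_designs, lab_designs, vc, means, seed = 1,
                         standard_means = c(STD1 = 25, STD2 = 50,
                                            STD3 = 100, STD4 = 150),
                         genetic_shift = NULL) {
  trials <- vc$trials
  if (is.null(names(field_designs))) names(field_designs) <- trials
  if (is.null(names(lab_designs))) names(lab_designs) <- trials
  miss <- setdiff(trials, intersect(names(field_designs), names(lab_designs)))
  if (length(miss)) stop2("designs missing for trials: ", paste(miss, collapse = ", "))
  if (!all(trials %in% names(means)))
    stop2("means must be named for every trial")
  factors <- met_terms()

  with_seed(seed, {
    ## genetic effects: joint draw for shared cultivars, marginal otherwise
    cult_by_trial <- lapply(setNames(trials, trials), function(tr) {
      fd <- field_designs[[tr]]
      sort(unique(fd$cultivar[fd$cultivar != "EMPTY"]))
    })
    g <- draw_genetic_effects(cult_by_trial, vc, genetic_shift)

    tabs <- lapply(trials, function(tr) {
      ld <- lab_designs[[tr]]
      fd <- field_designs[[tr]]
      tab <- as.data.frame(ld)
      fkey <- paste(fd$block, fd$cultivar)
      idx <- match(paste(tab$block, tab$cultivar), fkey)
      idx[tab$is_standard] <- NA_integer_
      if (anyNA(idx[!tab$is_standard]))
        stop2("trial ", tr, ": lab sample without a field pot")
      tab$field_row <- fd$field_row[idx]
      tab$field_column <- fd$field_column[idx]

      std <- tab$is_standard
      mu <- ifelse(std, standard_means[tab$cultivar], means[[tr]])
      eff <- numeric(nrow(tab))
      for (term in names(factors)) {
        v <- vc$terms[[tr]][term]
        v <- if (is.na(v)) 0 else unname(v)
        if (v <= 0) next
        cols <- factors[[term]]
        lev <- interaction(tab[cols], drop = FALSE, lex.order = TRUE)
        draw <- rnorm(nlevels(lev), 0, sqrt(v))
        e <- draw[as.integer(lev)]
        if (startsWith(term, "F_")) e[std] <- 0  # no field factors for standards
        eff <- eff + e
      }
      gv <- g[[tr]][tab$cultivar]
      gv[std] <- 0
      resid <- rnorm(nrow(tab), 0, sqrt(vc$residual_var[[tr]]))
      tab$sugar <- mu + gv + eff + resid
      tab
    })
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    tg <- do.call(rbind, lapply(trials, function(tr)
      data.frame(trial = tr, cultivar = names(g[[tr]]),
                 effect = unname(g[[tr]]), stringsAsFactors = FALSE)))
    attr(out, "true_genetic") <- tg
    attr(out, "seed") <- seed
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}

# One draw per cultivar: bivariate normal across the two trials for the
# overlap set (marginal variances from vc, correlation rho), marginal
# normal for single-trial cultivars.
draw_genetic_effects <- function(cult_by_trial, vc, genetic_shift = NULL) {
  trials <- vc$trials
  rho <- vc$genetic_correlation
  g <- lapply(setNames(trials, trials), function(tr)
    setNames(numeric(length(cult_by_trial[[tr]])), cult_by_trial[[tr]]))
  if (length(trials) == 2L) {
    sh <- intersect(cult_by_trial[[1]], cult_by_trial[[2]])
    v1 <- vc$genetic_var[[trials[1]]]; v2 <- vc$genetic_var[[trials[2]]]
    if (length(sh)) {
      z1 <- rnorm(length(sh)); z2 <- rnorm(length(sh))
      g1 <- sqrt(v1) * z1
      g2 <- sqrt(v2) * (rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)
      g[[1]][sh] <- g1; g[[2]][sh] <- g2
    }
    for (k in 1:2) {
      only <- setdiff(cult_by_trial[[k]], sh)
      if (length(only))
        g[[k]][only] <- rnorm(length(only), 0, sqrt(vc$genetic_var[[trials[k]]]))
    }
  } else {
    for (tr in trials) {
      cv <- cult_by_trial[[tr]]
      g[[tr]][cv] <- rnorm(length(cv), 0, sqrt(vc$genetic_var[[tr]]))
    }
  }
  if (!is.null(genetic_shift)) {
    for (tr in trials) {
      hit <- intersect(names(genetic_shift), names(g[[tr]]))
      g[[tr]][hit] <- g[[tr]][hit] + genetic_shift[hit]
    }
  }
  g
}

#' Remove whole samples from a phenotype table at random
#'
#' Drops `round(rate * n_samples)` whole test samples (all four technical
#' replicates) uniformly at random; standard wells are never removed.
#' Emulates cultivars lost between field and laboratory.
#'
#' @param table a `phenotype_table`.
#' @param rate fraction of samples to remove, in `[0, 1)`.
#' @param seed integer seed.
#' @return the reduced `phenotype_table`.
#' @export
inject_missingness <- function(table, rate, seed = 1) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop2("rate must be in [0, 1)")
  if (rate == 0) return(table)
  key <- paste(table$trial, table$plate, table$plate_plot)
  test_keys <- unique(key[!table$is_standard])
  n_remove <- round(rate * length(test_keys))
  if (n_remove == 0) return(table)
  drop <- with_seed(seed, sample_safe(test_keys, n_remove))
  out <- table[!(key %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo standard deviation of a simulated trial mean
#'
#' The raw mean of a simulated trial is itself random: each random term
#' contributes `v * sum_l (n_l / N)^2` over its realized levels (a term
#' with few levels, like the replicate block, barely averages out), the
#' genetic term contributes analogously over cultivars, and the residual
#' contributes `v / N`. This closed form gives the sampling sd of the
#' simulated trial mean around the declared trial mean, used to set
#' honest tolerances when checking simulated means.
#'
#' @param table a `phenotype_table` restricted to test wells.
#' @param vc the generating [variance_components()].
#' @param trial trial label.
#' @return standard deviation of the simulated trial mean.
#' @export
simulated_mean_sd <- function(table, vc, trial) {
  tab <- table[table$trial == trial & !table$is_standard, , drop = FALSE]
  N <- nrow(tab)
  factors <- met_terms()
  vtot <- 0
  for (term in names(factors)) {
    v <- vc$terms[[trial]][term]
    v <- if (is.na(v)) 0 else unname(v)
    if (v <= 0) next
    lev <- interaction(tab[factors[[term]]], drop = TRUE)
    vtot <- vtot + v * sum((tabulate(as.integer(lev)) / N)^2)
  }
  ncult <- table(tab$cultivar)
  vtot <- vtot + vc$genetic_var[[trial]] * sum((ncult / N)^2)
  vtot <- vtot + vc$residual_var[[trial]] / N
  sqrt(vtot)
}

#' Drop standard wells from a phenotype table
#'
#' Standards carry no cultivar term and are excluded before model fitting.
#' @param table a `phenotype_table`.
#' @return the table without standard wells.
#' @export
drop_standards <- function(table) {
  out <- table[!table$is_standard, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf(
    "Phenotype table: %d wells (%d standard), trials %s, mean sugar %.1f\n",
    nrow(x), sum(x$is_standard),
    paste(sort(unique(x$trial)), collapse = "/"),
    mean(x$sugar[!x$is_standard])))
  invisible(x)
}
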