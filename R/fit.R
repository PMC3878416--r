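#' Fit a model by REML
#'
#' Maximises the residual log likelihood over the unconstrained transform
#' of the variance parameters (log variances; inverse hyperbolic tangent
#' of the cross-trial genetic correlation) with a quasi-Newton optimiser
#' (`L-BFGS-B` with finite-difference gradients), warm-started from
#' moment-based heuristics. Design-factor terms whose estimated variance
#' tends to zero (below `boundary_tol` times the phenotypic variance) are
#' dropped and the model refitted, mirroring standard MET practice. On
#' convergence, empirical BLUPs of the cultivar-by-trial effects and their
#' prediction-error-variance (PEV) blocks are extracted from the inverse
#' coefficient matrix of the mixed-model equations.
#'
#' @param spec a [spec_model()] result.
#' @param data a `phenotype_table`; standard wells are removed internally.
#' @param opts list of options: `max_iter` (default 400), `factr`
#'   (optimiser tolerance, default 1e7), `boundary_tol` (default 1e-8),
#'   `start` (named natural-scale vector), `drop_boundary_terms`
#'   (default `TRUE`), `verbose`.
#' @return a `met_fit` with elements `theta` (natural-scale estimates),
#'   `loglik`, `n_params`, `fixed_estimates` (trial means), `eblups`
#'   (data.frame `trial`, `cultivar`, `eblup`, `pev_diag`), `pev_blocks`
#'   (within-trial PEV matrices), `converged`, `iterations`,
#'   `dropped_terms`, `cultivar_means` (raw per-trial means) and the spec.
#' @export
fit_reml <- function(spec, data, opts = list()) {
  stopifnot(inherits(spec, "met_model_spec"))
  o <- modifyList(list(max_iter = 400L, factr = 1e7, boundary_tol = 1e-8,
                       start = NULL, drop_boundary_terms = TRUE,
                       verbose = FALSE), opts)
  tab <- if (any(data$is_standard)) drop_standards(data) else data
  dropped <- character(0)
  spec_cur <- spec
  start <- o$start
  fit <- NULL
  var_y <- var(tab$sugar)

  for (round in 1:6) {
    fit <- fit_reml_once(spec_cur, tab, start, o)
    if (!o$drop_boundary_terms) break
    thr <- o$boundary_tol * var_y
    vkeys <- grep("^v\\.", names(fit$theta), value = TRUE)
    low <- vkeys[fit$theta[vkeys] < thr]
    if (!length(low)) break
    dropped <- c(dropped, sub("^v\\.", "", low))
    for (key in low) {
      tk <- strsplit(sub("^v\\.", "", key), ".", fixed = TRUE)[[1]]
      tr <- tk[1]; term <- paste(tk[-1], collapse = ".")
      spec_cur$term_lists[[tr]] <- setdiff(spec_cur$term_lists[[tr]], term)
    }
    spec_cur$n_params <- spec_cur$n_params - length(low)
    start <- fit$theta[setdiff(names(fit$theta), low)]
    if (o$verbose) message("dropping boundary terms: ", paste(low, collapse = ", "))
  }
  fit$dropped_terms <- dropped
  fit$spec_requested <- spec
  fit
}

fit_reml_once <- function(spec, tab, start, o) {
  mats <- build_matrices(tab, spec)
  prep <- reml_prepare(mats)
  lay <- prep$lay
  theta0 <- reml_start(mats, prep, lay)
  if (!is.null(start)) {
    keep <- intersect(names(theta0), names(start))
    theta0[keep] <- start[keep]
  }
  u0 <- to_unconstrained(theta0)[lay$names]

  nfev <- 0L
  last_u <- NULL; last_f <- NULL
  negll <- function(u) {
    nfev <<- nfev + 1L
    th <- to_natural(setNames(u, lay$names))
    ll <- reml_eval(th, prep)$ll
    f <- if (!is.finite(ll)) 1e10 else -ll
    last_u <<- u; last_f <<- f
    f
  }
  # forward-difference gradient on the unconstrained scale, reusing the
  # base evaluation the optimiser has just made at the same point
  h <- 1e-5
  grad <- function(u) {
    f0 <- if (!is.null(last_u) && identical(as.numeric(u), as.numeric(last_u)))
      last_f else negll(u)
    vapply(seq_along(u), function(i) {
      ui <- u; ui[i] <- ui[i] + h
      (negll(ui) - f0) / h
    }, numeric(1))
  }
  opt <- nlminb(u0, negll, grad,
                control = list(iter.max = o$max_iter, eval.max = 4L * o$max_iter,
                               rel.tol = 1e-9))
  if (opt$convergence != 0) {
    # polish with a quasi-Newton restart from the current best point
    opt2 <- optim(opt$par, negll, grad, method = "L-BFGS-B",
                  control = list(maxit = o$max_iter, factr = o$factr))
    if (opt2$value <= opt$objective)
      opt <- list(par = opt2$par, objective = opt2$value,
                  convergence = opt2$convergence, iterations = opt2$counts[1])
  }
  theta <- to_natural(setNames(opt$par, lay$names))
  final <- reml_eval(theta, prep, want_solution = TRUE)
  if (!is.finite(final$ll))
    stop2("REML evaluation failed at the optimum; best loglik ", -opt$objective)

  sol <- final$solution
  tau <- setNames(sol[seq_len(mats$p)], mats$trials)

  ## PEV of the genetic effects: corresponding block of C^-1
  gen_all <- unlist(mats$gen_cols, use.names = FALSE)
  pev_blocks <- list(); eblups <- NULL
  if (length(gen_all)) {
    E <- Matrix::sparseMatrix(i = gen_all, j = seq_along(gen_all), x = 1,
                              dims = c(prep$N, length(gen_all)))
    Cinv_cols <- as.matrix(Matrix::solve(final$chol, E, system = "A"))
    pev_full <- Cinv_cols[gen_all, , drop = FALSE]
    offs <- 0L
    for (tr in mats$trials) {
      m <- length(mats$gen_levels[[tr]])
      ix <- offs + seq_len(m)
      blk <- pev_full[ix, ix, drop = FALSE]
      dimnames(blk) <- list(mats$gen_levels[[tr]], mats$gen_levels[[tr]])
      pev_blocks[[tr]] <- blk
      offs <- offs + m
    }
    eblups <- do.call(rbind, lapply(mats$trials, function(tr) {
      cols <- mats$gen_cols[[tr]]
      data.frame(trial = tr, cultivar = mats$gen_levels[[tr]],
                 eblup = sol[cols],
                 pev_diag = diag(pev_blocks[[tr]]),
                 stringsAsFactors = FALSE)
    }))
  }

  raw_means <- lapply(setNames(mats$trials, mats$trials), function(tr) {
    rows <- mats$trial_obs[[tr]]
    tapply(mats$y[rows], tab$cultivar[rows], mean)
  })

  structure(list(
    kind = spec$kind, spec = spec, trials = mats$trials,
    theta = theta, loglik = final$ll, n_params = spec$n_params,
    fixed_estimates = tau, eblups = eblups, pev_blocks = pev_blocks,
    converged = opt$convergence == 0, iterations = nfev,
    dropped_terms = character(0),
    cultivar_means = raw_means, n_obs = mats$n,
    gen_levels = mats$gen_levels, shared_cultivars = mats$shared_cultivars
  ), class = "met_fit")
}

# Moment-based warm start: residual from the pooled within-sample variance
# of technical replicates, genetic from the spread of cultivar means, the
# rest of the phenotypic variance split evenly over the F/L terms.
reml_start <- function(mats, prep, lay) {
  theta <- setNames(numeric(length(lay$names)), lay$names)
  for (k in seq_along(mats$trials)) {
    tr <- mats$trials[k]
    rows <- mats$trial_obs[[tr]]
    yp <- mats$y[rows]
    vy <- max(var(yp), 1e-6)
    theta[paste0("resid.", tr)] <- max(0.4 * vy, 1e-4 * vy)
    if (lay$has_gen) theta[paste0("g_var.", tr)] <- 0.2 * vy
    keys <- grep(paste0("^v\\.", tr, "\\."), lay$names, value = TRUE)
    if (length(keys)) theta[keys] <- max(0.4 * vy, 1e-4) / length(keys)
  }
  if (lay$free_cov) theta["g_cor"] <- 0.3
  theta
}

#' @export
print.met_fit <- function(x, ...) {
  cat(sprintf("REML fit, model %s: loglik %.2f, %d variance parameters, %s\n",
              x$kind, x$loglik, x$n_params,
              if (x$converged) "converged" else "NOT converged"))
  cat("  trials:", paste(sprintf("%s (tau=%.2f)", x$trials,
                                 x$fixed_estimates[x$trials]),
                         collapse = ", "), "\n")
  if (length(x$dropped_terms))
    cat("  dropped at boundary:", paste(x$dropped_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Extract EBLUPs and their prediction error variances
#'
#' @param fit a converged [fit_reml()] result.
#' @return list with `eblups` (data.frame `trial`, `cultivar`, `eblup`,
#'   `pev_diag`) and `pev` (named list of within-trial PEV matrices).
#' @export
eblups_and_pev <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  if (!fit$converged) stop2("fit did not converge")
  list(eblups = fit$eblups, pev = fit$pev_blocks)
}
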