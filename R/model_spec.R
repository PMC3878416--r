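#' Specify one of the three analysis models
#'
#' Declares the mixed model fitted to a phenotype table. All three kinds
#' share a fixed overall mean per trial, random cultivar-by-trial effects
#' and per-trial residual variances; they differ in the non-genetic terms
#' and the cross-trial genetic covariance:
#' * `A` — baseline: no field/laboratory terms, genetic covariance fixed
#'   at zero (equivalent to analysing each trial separately and averaging
#'   a cultivar's observations);
#' * `B` — field and laboratory random terms included, covariance zero;
#' * `C` — the MET model: field and laboratory terms plus a free
#'   cross-trial genetic covariance (parameterised through the
#'   correlation).
#'
#' @param kind `"A"`, `"B"` or `"C"`.
#' @param data a `phenotype_table` (used for the trial set and to check
#'   term feasibility).
#' @param term_lists named list (by trial) of random-term names from
#'   [met_terms()]; ignored for kind `A`. Default: all twelve terms per
#'   trial.
#' @param genetic include the cultivar-by-trial term (default `TRUE`;
#'   `FALSE` gives the degenerate fixed-means-plus-residual model, mainly
#'   useful for closed-form checks of the likelihood engine).
#' @return a `met_model_spec` with the variance-parameter count in
#'   `$n_params` (genetic variances + covariances + term variances +
#'   residual variances).
#' @export
spec_model <- function(kind = c("A", "B", "C"), data, term_lists = NULL,
                       genetic = TRUE) {
  kind <- match.arg(kind)
  trials <- sort(unique(as.character(data$trial)))
  if (length(trials) < 1L) stop2("data contains no trials")
  if (kind == "C" && length(trials) < 2L)
    stop2("model C needs at least two trials for a genetic covariance")
  vocab <- names(met_terms())
  if (kind == "A") {
    term_lists <- setNames(rep(list(character(0)), length(trials)), trials)
  } else {
    if (is.null(term_lists))
      term_lists <- setNames(rep(list(vocab), length(trials)), trials)
    if (!all(trials %in% names(term_lists)))
      stop2("term_lists must be named for every trial")
    term_lists <- term_lists[trials]
    for (tr in trials) {
      bad <- setdiff(term_lists[[tr]], vocab)
      if (length(bad)) stop2("unknown terms: ", paste(bad, collapse = ", "))
      if (anyDuplicated(term_lists[[tr]]))
        stop2("duplicated term names in trial ", tr)
    }
  }
  free_cov <- kind == "C" && genetic
  n_params <- (if (genetic) length(trials) else 0L) +  # genetic variances
    (if (free_cov) choose(length(trials), 2L) else 0L) +
    sum(lengths(term_lists)) +                      # F/L term variances
    length(trials)                                  # residual variances
  structure(list(kind = kind, trials = trials, term_lists = term_lists,
                 free_cov = free_cov, genetic = genetic,
                 n_params = as.integer(n_params)),
            class = "met_model_spec")
}

#' @export
print.met_model_spec <- function(x, ...) {
  cat(sprintf("Model %s: trials %s; %d variance parameters (%s covariance)\n",
              x$kind, paste(x$trials, collapse = "/"), x$n_params,
              if (x$free_cov) "free genetic" else "no"))
  invisible(x)
}

#' Build sparse incidence matrices for a model specification
#'
#' Constructs the fixed-effect incidence `X` (one trial-mean column per
#' trial), the cultivar-by-trial incidence `Zg` (columns ordered
#' trial-major, cultivars lexicographic within trial) and one incidence
#' matrix per random term, all as one column-partitioned sparse matrix.
#' Rows of a term scoped to one trial are all-zero for the other trial's
#' observations. Standard wells must be removed beforehand
#' (see [drop_standards()]).
#'
#' @param data a `phenotype_table` without standards.
#' @param spec a [spec_model()] result.
#' @return a `met_matrices` list: `y`, `W` (sparse `[X | Zg | Zu]`),
#'   `col_info` (data.frame describing every column), index bookkeeping
#'   used by the REML engine, and per-trial observation indices.
#' @export
build_matrices <- function(data, spec) {
  stopifnot(inherits(spec, "met_model_spec"))
  if (any(data$is_standard))
    stop2("standards must be excluded before matrix construction")
  need <- unique(c("trial", "cultivar", "sugar",
                   unlist(met_terms()[unlist(spec$term_lists)], use.names = FALSE)))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop2("phenotype table lacks columns: ",
                          paste(miss, collapse = ", "))
  trials <- spec$trials
  n <- nrow(data)
  obs_trial <- as.character(data$trial)
  trial_obs <- lapply(setNames(trials, trials), function(tr) which(obs_trial == tr))

  factors <- met_terms()
  blocks <- list()   # list of sparse matrices, cbind at the end
  info <- list()

  ## fixed: one mean per trial
  Xj <- match(obs_trial, trials)
  blocks$X <- Matrix::sparseMatrix(i = seq_len(n), j = Xj, x = 1,
                                   dims = c(n, length(trials)))
  info$X <- data.frame(part = "fixed", term = "trial_mean", trial = trials,
                       level = trials, stringsAsFactors = FALSE)

  ## genetic: trial-major, cultivar lexicographic
  use_genetic <- isTRUE(spec$genetic %||% TRUE)
  gen_levels <- if (use_genetic)
    lapply(setNames(trials, trials), function(tr)
      sort(unique(data$cultivar[trial_obs[[tr]]])))
  else setNames(rep(list(character(0)), length(trials)), trials)
  gcols <- 0L
  gen_col_range <- list()
  gi <- integer(0); gj <- integer(0)
  for (tr in trials) {
    lev <- gen_levels[[tr]]
    if (!length(lev)) next
    rows <- trial_obs[[tr]]
    j <- match(data$cultivar[rows], lev)
    gi <- c(gi, rows); gj <- c(gj, gcols + j)
    gen_col_range[[tr]] <- gcols + seq_along(lev)
    gcols <- gcols + length(lev)
    info[[paste0("g_", tr)]] <- data.frame(part = "genetic", term = "cultivar",
                                           trial = tr, level = lev,
                                           stringsAsFactors = FALSE)
  }
  blocks$Zg <- Matrix::sparseMatrix(i = gi, j = gj, x = 1, dims = c(n, gcols))

  ## field/laboratory terms, scoped per trial
  zu <- list()
  term_levels <- list()
  for (tr in trials) {
    for (term in spec$term_lists[[tr]]) {
      cols <- factors[[term]]
      rows <- trial_obs[[tr]]
      lev <- interaction(data[rows, cols, drop = FALSE], drop = TRUE,
                         lex.order = TRUE)
      key <- paste(tr, term, sep = ".")
      zu[[key]] <- Matrix::sparseMatrix(i = rows, j = as.integer(lev), x = 1,
                                        dims = c(n, nlevels(lev)))
      term_levels[[key]] <- levels(lev)
      info[[paste0("u_", key)]] <- data.frame(part = "random", term = term,
                                              trial = tr, level = levels(lev),
                                              stringsAsFactors = FALSE)
    }
  }

  W <- do.call(cbind, c(list(blocks$X, blocks$Zg), unname(zu)))
  col_info <- do.call(rbind, unname(info))
  rownames(col_info) <- NULL

  p <- length(trials)
  offset <- p + gcols
  term_cols <- list()
  for (key in names(zu)) {
    q <- ncol(zu[[key]])
    term_cols[[key]] <- offset + seq_len(q)
    offset <- offset + q
  }
  shared <- if (length(trials) == 2L)
    intersect(gen_levels[[1]], gen_levels[[2]]) else character(0)

  structure(list(
    y = data$sugar, W = W, col_info = col_info,
    n = n, p = p, trials = trials, trial_obs = trial_obs,
    gen_levels = gen_levels,
    gen_cols = lapply(gen_col_range, function(ix) p + ix),
    term_cols = term_cols, shared_cultivars = shared,
    spec = spec
  ), class = "met_matrices")
}
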