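#' Predicted cultivar values of a fit for one trial
#'
#' Model A values are the raw mean of all a cultivar's observations (the
#' practice the baseline model represents); models B and C use
#' `tau_trial + EBLUP`.
#'
#' @param fit a [fit_reml()] result.
#' @param trial trial label.
#' @return named numeric vector of predicted values per cultivar.
#' @export
cultivar_values <- function(fit, trial) {
  stopifnot(inherits(fit, "met_fit"))
  if (!trial %in% fit$trials) stop2("unknown trial: ", trial)
  if (fit$kind == "A") {
    v <- fit$cultivar_means[[trial]]
    setNames(as.numeric(v), names(v))
  } else {
    eb <- fit$eblups[fit$eblups$trial == trial, ]
    setNames(fit$fixed_estimates[[trial]] + eb$eblup, eb$cultivar)
  }
}

#' Top-k cultivars of a trial
#'
#' Ranks cultivars by predicted value, descending; ties are broken
#' lexicographically by cultivar id and flagged in the `ties` attribute.
#'
#' @param fit a [fit_reml()] result.
#' @param trial trial label.
#' @param k cutoff (default 40, a practical shortlist size for follow-up).
#' @return a `ranked_list` data.frame (`rank`, `cultivar`, `value`) with
#'   attributes `trial`, `model`, `k`, `ties`.
#' @export
top_k <- function(fit, trial, k = 40) {
  vals <- cultivar_values(fit, trial)
  if (k > length(vals)) stop2("k exceeds cultivar count in trial ", trial)
  ord <- order(-vals, names(vals), method = "radix")
  sel <- ord[seq_len(k)]
  tied <- k < length(vals) && vals[ord[k]] == vals[ord[k + 1L]]
  out <- data.frame(rank = seq_len(k), cultivar = names(vals)[sel],
                    value = unname(vals[sel]), stringsAsFactors = FALSE)
  structure(out, trial = trial, model = fit$kind, k = k,
            ties = tied, class = c("ranked_list", "data.frame"))
}

#' Overlap between two top-k lists
#'
#' @param a,b `ranked_list`s with the same `k`.
#' @return list with `count` and `shared` (cultivar ids in both lists).
#' @export
overlap <- function(a, b) {
  stopifnot(inherits(a, "ranked_list"), inherits(b, "ranked_list"))
  if (attr(a, "k") != attr(b, "k")) stop2("ranked lists have differing k")
  sh <- intersect(a$cultivar, b$cultivar)
  list(count = length(sh), shared = sort(sh))
}

#' Cross-trial selection index
#'
#' Weighted sum of a cultivar's predicted values over the trials where it
#' is present, with the weights renormalised over those trials. An
#' equal-weight index over a MET fit summarises consistent performance.
#'
#' @param fit a [fit_reml()] result.
#' @param weights named non-negative per-trial weights summing to 1
#'   (default: equal weights).
#' @return data.frame `cultivar`, `index`, sorted by index descending.
#' @export
selection_index <- function(fit, weights = NULL) {
  stopifnot(inherits(fit, "met_fit"))
  trials <- fit$trials
  if (is.null(weights))
    weights <- setNames(rep(1 / length(trials), length(trials)), trials)
  if (any(weights < 0)) stop2("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop2("weights must sum to 1")
  if (!all(trials %in% names(weights))) stop2("weights must be named per trial")
  vals <- lapply(setNames(trials, trials), function(tr) cultivar_values(fit, tr))
  cultivars <- sort(unique(unlist(lapply(vals, names), use.names = FALSE)))
  idx <- vapply(cultivars, function(cv) {
    pres <- trials[vapply(trials, function(tr) cv %in% names(vals[[tr]]), logical(1))]
    w <- weights[pres] / sum(weights[pres])
    sum(w * vapply(pres, function(tr) vals[[tr]][[cv]], numeric(1)))
  }, numeric(1))
  out <- data.frame(cultivar = cultivars, index = unname(idx),
                    stringsAsFactors = FALSE)
  out[order(-out$index, out$cultivar), , drop = FALSE]
}

#' Concordance report across models and trials
#'
#' For each fitted model: the cross-trial top-k overlap (the cultivars
#' consistently in the top k in every trial); for each trial: pairwise
#' top-k overlaps between models.
#'
#' @param fits named list of [fit_reml()] results on the same data
#'   (e.g. `list(A = ..., B = ..., C = ...)`).
#' @param k top-list cutoff.
#' @return a `concordance_report` list with `cross_trial` (data.frame
#'   `model`, `count`), `consistent` (named list of cultivar id vectors),
#'   and `model_pairs` (data.frame `trial`, `model_a`, `model_b`, `count`).
#' @export
concordance_report <- function(fits, k = 40) {
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)))
  trials <- fits[[1]]$trials
  tops <- lapply(fits, function(f)
    lapply(setNames(trials, trials), function(tr) top_k(f, tr, k)))

  cross <- do.call(rbind, lapply(names(fits), function(mn) {
    sets <- lapply(tops[[mn]], function(t) t$cultivar)
    common <- Reduce(intersect, sets)
    data.frame(model = mn, count = length(common), stringsAsFactors = FALSE)
  }))
  consistent <- lapply(tops, function(tt)
    sort(Reduce(intersect, lapply(tt, function(t) t$cultivar))))

  pairs <- NULL
  mns <- names(fits)
  if (length(mns) >= 2L) {
    cmb <- utils::combn(mns, 2L)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      do.call(rbind, lapply(trials, function(tr) {
        ov <- overlap(tops[[cmb[1, i]]][[tr]], tops[[cmb[2, i]]][[tr]])
        data.frame(trial = tr, model_a = cmb[1, i], model_b = cmb[2, i],
                   count = ov$count, stringsAsFactors = FALSE)
      }))
    }))
  }
  structure(list(k = k, cross_trial = cross, consistent = consistent,
                 model_pairs = pairs),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Top-", x$k, " concordance\n", sep = "")
  cat("Cross-trial consistent cultivars per model:\n")
  print(x$cross_trial, row.names = FALSE)
  if (!is.null(x$model_pairs)) {
    cat("Pairwise model overlaps within trial:\n")
    print(x$model_pairs, row.names = FALSE)
  }
  invisible(x)
}
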