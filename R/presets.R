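#' Construct cultivar sets for a two-trial screen with partial overlap
#'
#' Builds two cultivar id lists sharing `n_shared` ids, emulating a
#' germplasm panel re-assembled across years.
#'
#' @param n1,n2 cultivar counts per trial.
#' @param n_shared cultivars common to both trials.
#' @param prefix id prefix.
#' @return named list of two character vectors.
#' @export
make_cultivar_sets <- function(n1 = 648, n2 = 856, n_shared = 639,
                               prefix = "CV") {
  stopifnot(n_shared <= min(n1, n2))
  total <- n1 + n2 - n_shared
  ids <- sprintf("%s%05d", prefix, seq_len(total))
  shared <- ids[seq_len(n_shared)]
  only1 <- ids[n_shared + seq_len(n1 - n_shared)]
  only2 <- ids[n_shared + (n1 - n_shared) + seq_len(n2 - n_shared)]
  list(trial1 = sort(c(shared, only1)), trial2 = sort(c(shared, only2)))
}

#' Pipeline configuration presets
#'
#' * `"paper"` — the published screen's configuration: trials `"2010"`
#'   (648 cultivars, 8 samples missing per block) and `"2011"` (856
#'   cultivars, 20 missing in block 1), 639 shared cultivars, 5 replicate
#'   blocks of 8 field rows, 4 plates per day, duplicate counts chosen in
#'   the 3-5% window that fills plates exactly; variance components and
#'   trial means from the package presets.
#' * `"reduced"` — a desk-scale world for testing and simulation studies:
#'   100 cultivars fully shared across both trials, 3 blocks, ~4%
#'   laboratory duplicates (short final plate allowed), same variance
#'   structure.
#'
#' @param preset `"paper"` or `"reduced"`.
#' @param ... fields overriding the preset (see the returned list).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("paper", "reduced"), ...) {
  preset <- match.arg(preset)
  vc <- vc_preset_trials()
  means <- trial_means_preset()
  base <- if (preset == "paper") {
    sets <- make_cultivar_sets(648, 856, 639)
    list(
      trials = list(
        "2010" = list(cultivars = sets$trial1, n_blocks = 5, n_rows = 8,
                      missing_per_block = c(8, 8, 8, 8, 8),
                      plates_per_day = 4, pad_to_full_plates = TRUE),
        "2011" = list(cultivars = sets$trial2, n_blocks = 5, n_rows = 8,
                      missing_per_block = c(20, 0, 0, 0, 0),
                      plates_per_day = 4, pad_to_full_plates = TRUE)),
      vc = vc, means = means)
  } else {
    sets <- make_cultivar_sets(100, 100, 100)
    list(
      trials = list(
        "2010" = list(cultivars = sets$trial1, n_blocks = 3, n_rows = 8,
                      missing_per_block = c(0, 0, 0),
                      plates_per_day = 4, pad_to_full_plates = FALSE,
                      dup_frac = 0.04),
        "2011" = list(cultivars = sets$trial2, n_blocks = 3, n_rows = 8,
                      missing_per_block = c(0, 0, 0),
                      plates_per_day = 4, pad_to_full_plates = FALSE,
                      dup_frac = 0.04)),
      vc = vc, means = means)
  }
  cfg <- modifyList(c(base, list(models = c("A", "B", "C"), k = 40,
                                 seed = 1, preset = preset)),
                    list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Generate field and laboratory designs for every trial of a config
#'
#' The availability mask removes `missing_per_block` cultivars per block
#' at random (samples lost between field and laboratory) before the lab
#' design is built.
#'
#' @param cfg a [pipeline_config()].
#' @param seed integer seed (per-trial design seeds are derived from it).
#' @return list with named lists `field` and `lab`, one design per trial.
#' @export
generate_trial_designs <- function(cfg, seed) {
  trials <- names(cfg$trials)
  out <- list(field = list(), lab = list())
  for (i in seq_along(trials)) {
    tr <- trials[i]
    tc <- cfg$trials[[tr]]
    fseed <- (seed * 131L + i * 7L) %% .Machine$integer.max
    fd <- generate_field_design(tc$cultivars, n_blocks = tc$n_blocks,
                                n_rows = tc$n_rows, trial = tr, seed = fseed)
    avail <- NULL
    mpb <- tc$missing_per_block %||% rep(0, tc$n_blocks)
    if (any(mpb > 0)) {
      avail <- with_seed(fseed + 1L, lapply(seq_len(tc$n_blocks), function(b)
        sample_safe(tc$cultivars, length(tc$cultivars) - mpb[b])))
    }
    ld <- generate_lab_design(
      fd, dup_count = tc$dup_count %||% NULL,
      dup_frac = tc$dup_frac %||% 0.04,
      plates_per_day = tc$plates_per_day %||% 4,
      available = avail,
      pad_to_full_plates = tc$pad_to_full_plates %||% TRUE,
      seed = fseed + 2L)
    out$field[[tr]] <- fd
    out$lab[[tr]] <- ld
  }
  out
}
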