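#' Generate the partially replicated (p-rep) laboratory plate design
#'
#' Re-randomises the milled field samples of each replicate block to
#' 96-well plates. Each plate holds 24 samples of four technical replicates
#' each (one sample per *plate plot*, four vertically consecutive wells of
#' one column): 20 test samples in columns 1-10 and four standard samples
#' confined to columns 11-12. Within each block, a random subset of
#' cultivars (by default 3-5%) is duplicated; their two copies are forced
#' onto different plates and every plate receives between one and two
#' duplicated-cultivar samples, so that plate-to-plate laboratory variation
#' is estimable. Plates are processed in index order, grouped into days of
#' `plates_per_day` consecutive plates (days and plates are numbered
#' globally within the trial).
#'
#' @param field a [generate_field_design()] result for one trial.
#' @param dup_count duplicates per block, a single count or one per block.
#'   Default `NULL`: chosen automatically (see `dup_frac`).
#' @param dup_frac target duplicate fraction of the trial's cultivar count
#'   used when `dup_count` is `NULL`; with `pad_to_full_plates = TRUE` the
#'   feasible count closest to the target that makes the block's sample
#'   count a multiple of 20 is used.
#' @param plates_per_day plates processed per day (3-4 in practice).
#' @param available optional availability mask: a list, indexed by block,
#'   of cultivar ids with harvested samples (e.g. excluding pots that
#'   failed in the field). Default: all cultivars in every block.
#' @param pad_to_full_plates if `TRUE`, adjust the duplicate count so every
#'   plate carries exactly 20 test samples; if `FALSE` the last plate of a
#'   block may hold fewer.
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @return A `lab_design`: a data.frame with one row per well (four rows
#'   per sample): `trial`, `block`, `day`, `plate`, `plate_plot`,
#'   `plate_row`, `plate_column`, `cultivar`, `copy`, `is_standard`.
#'   Attribute `duplicates` lists the duplicated cultivars per block.
#' @export
generate_lab_design <- function(field, dup_count = NULL, dup_frac = 0.04,
                                plates_per_day = 4, available = NULL,
                                pad_to_full_plates = TRUE, seed = 1) {
  stopifnot(inherits(field, "field_design") || is.data.frame(field))
  stopifnot(plates_per_day >= 1)
  trial <- field$trial[1]
  blocks <- sort(unique(field$block))
  cultivars <- sort(unique(field$cultivar[field$cultivar != "EMPTY"]))
  n_cult <- length(cultivars)

  if (!is.null(dup_count)) {
    dup_count <- rep_len(as.integer(dup_count), length(blocks))
  }

  with_seed(seed, {
    plate_counter <- 0L
    out <- vector("list", length(blocks))
    dup_sets <- vector("list", length(blocks))
    names(dup_sets) <- as.character(blocks)

    for (bi in seq_along(blocks)) {
      b <- blocks[bi]
      avail <- if (is.null(available)) cultivars else {
        av <- available[[bi]] %||% available[[as.character(b)]]
        if (is.null(av)) cultivars else intersect(cultivars, as.character(av))
      }
      n_avail <- length(avail)
      if (n_avail < 1L) stop2("block ", b, ": no available samples")

      d <- if (!is.null(dup_count)) dup_count[bi] else
        choose_dup_count(n_avail, n_cult, dup_frac, pad_to_full_plates)
      total <- n_avail + d
      n_plates <- ceiling(total / 20)
      check_dup_feasible(d, n_plates, n_avail)

      dups <- if (d > 0L) sort(sample_safe(avail, d)) else character(0)
      dup_sets[[bi]] <- dups

      plates <- assemble_block_plates(avail, dups, n_plates, total)
      out[[bi]] <- block_wells(plates, trial, b, plate_counter)
      plate_counter <- plate_counter + n_plates
    }
    ld <- do.call(rbind, out)
    ld$day <- (ld$plate - 1L) %/% as.integer(plates_per_day) + 1L
    ld <- ld[, c("trial", "block", "day", "plate", "plate_plot", "plate_row",
                 "plate_column", "cultivar", "copy", "is_standard")]
    attr(ld, "duplicates") <- dup_sets
    attr(ld, "plates_per_day") <- plates_per_day
    attr(ld, "seed") <- seed
    class(ld) <- c("lab_design", "data.frame")
    ld
  })
}

# Choose the per-block duplicate count: among counts that make
# (n_avail + d) a multiple of 20 (or any count if padding is off), prefer
# the 3-5% window of the trial's cultivar total and take the candidate
# closest to 4%.
choose_dup_count <- function(n_avail, n_cult, dup_frac, pad_to_full_plates) {
  target <- dup_frac * n_cult
  if (!pad_to_full_plates) {
    d <- max(1L, as.integer(round(target)))
    if (ceiling((n_avail + d) / 20) < 2L) return(0L)  # single plate: no cross-plate copies
    return(d)
  }
  r <- n_avail %% 20L
  cand <- seq.int(if (r == 0L) 20L else 20L - r, by = 20L,
                  length.out = max(2L, ceiling(0.10 * n_cult / 20) + 1L))
  cand <- cand[cand <= n_avail]
  # keep only counts the 1-2-duplicates-per-plate rule can accommodate
  feas <- vapply(cand, function(d) {
    P <- (n_avail + d) %/% 20L
    P >= 2L && d >= ceiling(P / 2) && d <= P
  }, logical(1))
  cand <- cand[feas]
  if (length(cand)) {
    in_win <- cand[cand >= 0.03 * n_cult & cand <= 0.05 * n_cult]
    pool <- if (length(in_win)) in_win else cand
    return(pool[which.min(abs(pool - target))])
  }
  # no padded count is feasible (small blocks): allow a short last plate
  d <- max(1L, as.integer(round(target)))
  P <- ceiling((n_avail + d) / 20)
  if (P < 2L) return(0L)
  min(max(d, ceiling(P / 2)), P, n_avail)
}

check_dup_feasible <- function(d, n_plates, n_avail) {
  if (d == 0L) return(invisible(TRUE))
  if (n_plates < 2L)
    stop2("duplicate count ", d, " infeasible: both copies of a duplicated ",
          "cultivar must sit on different plates, but the block has a ",
          "single plate (feasible dup_count: 0)")
  lo <- ceiling(n_plates / 2); hi <- min(n_plates, n_avail)
  if (d < lo || d > hi)
    stop2("duplicate count ", d, " infeasible for ", n_plates,
          " plates: every plate needs 1-2 duplicated samples ",
          "(feasible range ", lo, "-", hi, ")")
  invisible(TRUE)
}

# Allocate one block's samples (available cultivars once, duplicated
# cultivars twice) to plates: each plate gets a quota of 1-2 duplicate
# samples, the two copies of a cultivar land on different plates (repaired
# by swaps if the initial random deal violates this), and the remaining
# capacity is filled with the shuffled non-duplicate samples.
assemble_block_plates <- function(avail, dups, n_plates, total) {
  capacity <- rep(20L, n_plates)
  if (total < 20L * n_plates) capacity[n_plates] <- total - 20L * (n_plates - 1L)
  d <- length(dups)

  plate_of_dup <- integer(0)
  if (d > 0L) {
    quota <- rep(1L, n_plates)
    extra <- 2L * d - n_plates
    if (extra > 0L) {
      eligible <- which(capacity >= 2L)
      quota[sample_safe(eligible, extra)] <- 2L
    }
    # slots: plate index repeated by quota; dup samples: cultivar x copy
    # slot p repeated quota[p] times; dup sample i is copy 1 or 2 of
    # cultivar ceiling(i/2)
    slots <- rep(seq_len(n_plates), quota)
    plate_of_dup <- slots[sample.int(2L * d)]
    other_copy <- function(i) if (i %% 2L == 1L) i + 1L else i - 1L
    # repair: both copies of a cultivar on one plate P -> swap the second
    # copy with another slot whose move to P creates no new violation
    for (tries in 1:1000) {
      pd <- matrix(plate_of_dup, nrow = 2L)
      bad <- which(pd[1L, ] == pd[2L, ])
      if (!length(bad)) break
      j <- bad[1L]
      i1 <- 2L * j
      P <- plate_of_dup[i1]
      other <- setdiff(seq_len(2L * d), c(2L * j - 1L, 2L * j))
      ok <- other[vapply(other, function(i)
        plate_of_dup[i] != P && plate_of_dup[other_copy(i)] != P,
        logical(1))]
      if (!length(ok)) stop2("cannot repair duplicate allocation")
      i2 <- sample_safe(ok, 1L)
      tmp <- plate_of_dup[i1]
      plate_of_dup[i1] <- plate_of_dup[i2]
      plate_of_dup[i2] <- tmp
    }
    pd <- matrix(plate_of_dup, nrow = 2L)
    if (any(pd[1L, ] == pd[2L, ]))
      stop2("cannot place both copies of a duplicated cultivar on different plates")
  }

  nondup <- sample_safe(setdiff(avail, dups))
  used <- tabulate(plate_of_dup, n_plates)
  fill <- capacity - used
  if (any(fill < 0L)) stop2("plate over capacity during allocation")
  if (sum(fill) != length(nondup)) stop2("internal capacity accounting error")
  plate_of_nondup <- rep(seq_len(n_plates), fill)

  plates <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    cult <- character(0); cop <- integer(0)
    if (d > 0L) {
      idx <- which(plate_of_dup == p)
      if (length(idx)) {
        cult <- rep(dups, each = 2L)[idx]
        cop <- rep(1:2, d)[idx]
      }
    }
    nd <- nondup[plate_of_nondup == p]
    cult <- c(cult, nd); cop <- c(cop, rep(1L, length(nd)))
    # random assignment of samples to the 20 test plate plots
    plots <- sample_safe(1:20, length(cult))
    plates[[p]] <- data.frame(plate_plot = plots, cultivar = cult, copy = cop,
                              stringsAsFactors = FALSE)
  }
  plates
}

# Expand per-plate sample lists to well rows. Plate plots 1..20 are the
# test plots (column ceil(plot/2), upper rows A-D for odd plots, lower
# rows E-H for even); plots 21..24 hold the four standards in columns
# 11-12, identical on every plate.
block_wells <- function(plates, trial, block, plate_offset) {
  rows_upper <- PLATE_ROW_LABELS[1:4]; rows_lower <- PLATE_ROW_LABELS[5:8]
  one_plate <- function(p) {
    smp <- plates[[p]]
    std <- data.frame(plate_plot = 21:24,
                      cultivar = paste0("STD", 1:4),
                      copy = 0L, stringsAsFactors = FALSE)
    all_s <- rbind(smp, std)
    col <- ceiling(all_s$plate_plot / 2)
    upper <- all_s$plate_plot %% 2L == 1L
    data.frame(
      trial = trial, block = block, plate = plate_offset + p,
      plate_plot = rep(all_s$plate_plot, each = 4L),
      plate_row = as.vector(vapply(upper, function(u)
        if (u) rows_upper else rows_lower, character(4))),
      plate_column = rep(col, each = 4L),
      cultivar = rep(all_s$cultivar, each = 4L),
      copy = rep(all_s$copy, each = 4L),
      is_standard = rep(all_s$plate_plot > 20L, each = 4L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(plates), one_plate))
}

#' Validate laboratory-design invariants
#'
#' Checks plate-plot geometry (four wells per sample, two samples per
#' column, standards confined to columns 11-12), per-plate test-sample
#' counts, the 1-2 duplicated samples per plate rule, cross-plate placement
#' of duplicate copies, and that each block's non-duplicate samples match
#' the supplied field block (up to an availability mask).
#'
#' @param ld a `lab_design`.
#' @param field optionally the matching `field_design`.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_lab_design <- function(ld, field = NULL) {
  stopifnot(inherits(ld, "data.frame"))
  need <- c("trial", "block", "day", "plate", "plate_plot", "plate_row",
            "plate_column", "cultivar", "copy", "is_standard")
  miss <- setdiff(need, names(ld))
  if (length(miss)) stop2("lab design lacks columns: ", paste(miss, collapse = ", "))

  key <- paste(ld$plate, ld$plate_plot)
  per_plot <- table(key)
  if (any(per_plot != 4L)) stop2("every plate plot must hold exactly 4 wells")
  if (any(ld$plate_column[!ld$is_standard] > 10L))
    stop2("test samples must sit in plate columns 1-10")
  if (any(ld$plate_column[ld$is_standard] < 11L))
    stop2("standards must sit in plate columns 11-12")
  spl <- ld[!duplicated(key), ]
  col_counts <- table(paste(spl$plate, spl$plate_column))
  if (any(col_counts > 2L)) stop2("more than two samples in one plate column")

  dup_sets <- attr(ld, "duplicates")
  test <- ld[!ld$is_standard & !duplicated(key), ]
  for (b in sort(unique(test$block))) {
    tb <- test[test$block == b, ]
    dups <- if (!is.null(dup_sets)) dup_sets[[as.character(b)]] %||%
      dup_sets[[match(b, sort(unique(test$block)))]] else
      unique(tb$cultivar[tb$copy == 2L])
    n_dup_samples <- sum(tb$cultivar %in% dups)
    if (length(dups) && n_dup_samples != 2L * length(dups))
      stop2("block ", b, ": duplicated-sample count must be 2 x dup_count")
    if (length(dups)) {
      per_plate <- table(factor(tb$plate[tb$cultivar %in% dups],
                                levels = unique(tb$plate)))
      if (any(per_plate < 1L) || any(per_plate > 2L))
        stop2("block ", b, ": each plate must hold 1-2 duplicated samples")
      for (cv in dups) {
        pl <- tb$plate[tb$cultivar == cv]
        if (length(pl) == 2L && pl[1] == pl[2])
          stop2("block ", b, ": both copies of ", cv, " share a plate")
      }
    }
    if (!is.null(field)) {
      fb <- field[field$block == b & field$cultivar != "EMPTY", ]
      extra <- setdiff(tb$cultivar, fb$cultivar)
      if (length(extra))
        stop2("block ", b, ": lab samples absent from field block: ",
              paste(head(extra, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.lab_design <- function(x, ...) {
  key <- paste(x$plate, x$plate_plot)
  n_samples <- sum(!x$is_standard & !duplicated(key))
  cat(sprintf(
    "Lab design: trial %s, %d blocks, %d plates over %d days, %d test samples (%d wells)\n",
    x$trial[1], length(unique(x$block)), length(unique(x$plate)),
    max(x$day), n_samples, nrow(x)))
  invisible(x)
}
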