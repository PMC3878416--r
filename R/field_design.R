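#' Generate a spatial row-column field design with replicate blocks
#'
#' Lays out one pot per cultivar per replicate block on a grid of
#' `n_rows` field rows by `n_blocks * block_width` field columns, where
#' `block_width = ceiling(n_cultivars / n_rows)`. Field rows run the length
#' of the whole field (1..`n_rows`); field columns are numbered globally, so
#' block `b` occupies the contiguous columns
#' `(b-1)*block_width + 1 .. b*block_width`. Cultivars are randomised to
#' pots independently within each block. When the cultivar count does not
#' fill the block exactly, the surplus pots in the block's last column are
#' left `EMPTY` and produce no samples.
#'
#' @param cultivars character vector of cultivar ids (unique).
#' @param n_blocks number of replicate blocks (biological replicates).
#' @param n_rows number of field rows.
#' @param trial trial label (e.g. `"2010"`).
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @return A `field_design`: a data.frame with columns `trial`, `block`,
#'   `field_row`, `field_column`, `cultivar` (one row per pot, `EMPTY`
#'   allowed), and attributes `n_rows`, `n_blocks`, `block_width`, `seed`.
#' @examples
#' fd <- generate_field_design(sprintf("CV%03d", 1:24), n_blocks = 2,
#'                             n_rows = 8, trial = "demo", seed = 1)
#' table(fd$block)
#' @export
generate_field_design <- function(cultivars, n_blocks = 5, n_rows = 8,
                                  trial = "trial1", seed = 1) {
  cultivars <- as.character(cultivars)
  if (anyDuplicated(cultivars)) {
    dups <- unique(cultivars[duplicated(cultivars)])
    stop2("duplicate cultivar ids: ", paste(dups, collapse = ", "))
  }
  if (any(cultivars == "EMPTY"))
    stop2("'EMPTY' is a reserved pot label and cannot be a cultivar id")
  stopifnot(n_blocks >= 1, n_rows >= 1, length(cultivars) >= 1)
  n <- length(cultivars)
  block_width <- ceiling(n / n_rows)
  capacity <- block_width * n_rows

  blocks <- with_seed(seed, lapply(seq_len(n_blocks), function(b) {
    # pots in column-major order; the last (capacity - n) pots sit in the
    # block's final column and stay EMPTY
    assign_ids <- c(sample_safe(cultivars), rep("EMPTY", capacity - n))
    col_local <- rep(seq_len(block_width), each = n_rows)
    row <- rep(seq_len(n_rows), times = block_width)
    data.frame(
      trial = trial, block = b, field_row = row,
      field_column = (b - 1L) * block_width + col_local,
      cultivar = assign_ids, stringsAsFactors = FALSE
    )
  }))
  fd <- do.call(rbind, blocks)
  attr(fd, "n_rows") <- n_rows
  attr(fd, "n_blocks") <- n_blocks
  attr(fd, "block_width") <- block_width
  attr(fd, "seed") <- seed
  class(fd) <- c("field_design", "data.frame")
  fd
}

#' Validate field-design invariants
#'
#' Checks that every cultivar occurs exactly once per replicate block, that
#' each block occupies a contiguous column range of the declared width, and
#' that the number of `EMPTY` pots per block equals
#' `n_rows * block_width - n_cultivars`.
#'
#' @param fd a `field_design`.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_field_design <- function(fd) {
  stopifnot(inherits(fd, "data.frame"))
  need <- c("trial", "block", "field_row", "field_column", "cultivar")
  miss <- setdiff(need, names(fd))
  if (length(miss)) stop2("field design lacks columns: ", paste(miss, collapse = ", "))
  culls <- sort(unique(fd$cultivar[fd$cultivar != "EMPTY"]))
  n_rows <- max(fd$field_row)
  bw <- ceiling(length(culls) / n_rows)
  for (b in sort(unique(fd$block))) {
    fb <- fd[fd$block == b, ]
    tab <- table(fb$cultivar[fb$cultivar != "EMPTY"])
    if (!setequal(names(tab), culls) || any(tab != 1L))
      stop2("block ", b, ": cultivars must each appear exactly once")
    cols <- range(fb$field_column)
    if (diff(cols) + 1L != bw)
      stop2("block ", b, ": column range is not contiguous of width ", bw)
    n_empty <- sum(fb$cultivar == "EMPTY")
    if (n_empty != n_rows * bw - length(culls))
      stop2("block ", b, ": unexpected number of EMPTY pots")
  }
  invisible(TRUE)
}

#' @export
print.field_design <- function(x, ...) {
  culls <- unique(x$cultivar[x$cultivar != "EMPTY"])
  cat(sprintf(
    "Field design: trial %s, %d cultivars, %d blocks x (%d rows x %d columns), %d EMPTY pots\n",
    x$trial[1], length(culls), attr(x, "n_blocks"), attr(x, "n_rows"),
    attr(x, "block_width"), sum(x$cultivar == "EMPTY")))
  invisible(x)
}
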