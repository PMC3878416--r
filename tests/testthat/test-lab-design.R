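ids648 <- sprintf("CV%05d", 1:648)

test_that("p-rep plate counts reproduce the published block configurations", {
  fd <- generate_field_design(ids648, n_blocks = 1, n_rows = 8,
                              trial = "2010", seed = 1)
  # 640 available samples + 20 auto-chosen duplicates -> 660 samples, 33 plates
  avail <- metphase:::with_seed(2, sample(ids648, 640))
  ld <- generate_lab_design(fd, available = list(avail), seed = 3)
  key <- paste(ld$plate, ld$plate_plot)
  smp <- ld[!ld$is_standard & !duplicated(key), ]
  expect_identical(nrow(smp), 660L)
  expect_identical(length(unique(ld$plate)), 33L)
  expect_identical(lengths(attr(ld, "duplicates"))[[1]], 20L)
  expect_true(validate_lab_design(ld, fd))

  # 880 samples in a block -> 44 plates (836 available of 856 + 44 dups)
  ids856 <- sprintf("CV%05d", 1:856)
  fd2 <- generate_field_design(ids856, 1, 8, trial = "2011", seed = 1)
  avail2 <- metphase:::with_seed(4, sample(ids856, 836))
  ld2 <- generate_lab_design(fd2, available = list(avail2), seed = 5)
  key2 <- paste(ld2$plate, ld2$plate_plot)
  expect_identical(sum(!ld2$is_standard & !duplicated(key2)), 880L)
  expect_identical(length(unique(ld2$plate)), 44L)
  expect_identical(lengths(attr(ld2, "duplicates"))[[1]], 44L)

  # 20 samples, no duplicates -> a single plate processed on day 1
  fd3 <- generate_field_design(sprintf("CV%d", 1:20), 1, 8, seed = 1)
  ld3 <- generate_lab_design(fd3, dup_count = 0, seed = 1)
  expect_identical(length(unique(ld3$plate)), 1L)
  expect_identical(unique(ld3$day), 1L)
})

test_that("plate geometry and duplicate constraints hold", {
  fd <- generate_field_design(sprintf("CV%03d", 1:83), n_blocks = 2,
                              n_rows = 8, seed = 7)
  ld <- generate_lab_design(fd, dup_frac = 0.04, pad_to_full_plates = FALSE,
                            seed = 8)
  expect_true(validate_lab_design(ld, fd))
  # four wells per sample, one column each, two samples per test column
  key <- paste(ld$plate, ld$plate_plot)
  for (k in unique(key)[1:20]) {
    wells <- ld[key == k, ]
    expect_identical(nrow(wells), 4L)
    expect_identical(length(unique(wells$plate_column)), 1L)
    expect_identical(length(unique(wells$cultivar)), 1L)
  }
  # standards confined to columns 11-12 on every plate, same four ids
  std <- ld[ld$is_standard, ]
  expect_true(all(std$plate_column %in% 11:12))
  expect_identical(sort(unique(std$cultivar)), paste0("STD", 1:4))
  expect_identical(nrow(std), length(unique(ld$plate)) * 16L)

  # per block: non-duplicate lab samples = the field block's cultivars,
  # duplicated-sample count = 2 x dup_count
  dups <- attr(ld, "duplicates")
  smp <- ld[!ld$is_standard & !duplicated(key), ]
  for (b in 1:2) {
    sb <- smp[smp$block == b, ]
    db <- dups[[b]]
    expect_identical(sort(sb$cultivar[!sb$cultivar %in% db]),
                     sort(setdiff(sprintf("CV%03d", 1:83), db)))
    expect_identical(sum(sb$cultivar %in% db), 2L * length(db))
    # both copies on different plates, 1-2 duplicated samples per plate
    for (cv in db)
      expect_identical(length(unique(sb$plate[sb$cultivar == cv])), 2L)
    per_plate <- table(sb$plate[sb$cultivar %in% db])
    expect_true(all(per_plate >= 1 & per_plate <= 2))
  }
})

test_that("day grouping follows processing order", {
  fd <- generate_field_design(sprintf("CV%03d", 1:140), 2, 8, seed = 2)
  ld <- generate_lab_design(fd, dup_frac = 0.03, pad_to_full_plates = FALSE,
                            plates_per_day = 3, seed = 2)
  per_day <- tapply(ld$plate, ld$day, function(p) length(unique(p)))
  expect_true(all(per_day[-length(per_day)] == 3))
  expect_lte(per_day[length(per_day)], 3)
  # day index follows plate processing order
  expect_true(all(ld$day == (ld$plate - 1) %/% 3 + 1))
})

test_that("infeasible duplicate counts are rejected with the feasible range", {
  fd <- generate_field_design(ids648[1:640], 1, 8, seed = 1)
  # 2 duplicates cannot put >= 1 duplicated sample on each of ~33 plates
  expect_error(generate_lab_design(fd, dup_count = 2, seed = 1),
               "feasible range")
  # single plate cannot host cross-plate duplicate copies
  fd20 <- generate_field_design(sprintf("CV%d", 1:18), 1, 8, seed = 1)
  expect_error(generate_lab_design(fd20, dup_count = 2, seed = 1),
               "single plate")
})

test_that("lab design is reproducible from the seed", {
  fd <- generate_field_design(sprintf("CV%03d", 1:83), 2, 8, seed = 7)
  ld1 <- generate_lab_design(fd, seed = 9, pad_to_full_plates = FALSE)
  ld2 <- generate_lab_design(fd, seed = 9, pad_to_full_plates = FALSE)
  ld3 <- generate_lab_design(fd, seed = 10, pad_to_full_plates = FALSE)
  expect_identical(ld1, ld2)
  expect_false(identical(ld1$cultivar, ld3$cultivar))
})
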