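test_that("all-zero variances give the trial mean everywhere", {
  vc0 <- variance_components(
    terms = list(t1 = c(F_block = 0), t2 = c(F_block = 0)),
    genetic_var = c(t1 = 0, t2 = 0), genetic_correlation = 0,
    residual_var = c(t1 = 0, t2 = 0))
  w <- tiny_world(n_cult = 20, vc = vc0, means = c(t1 = 93.3, t2 = 54))
  tst <- drop_standards(w$pheno)
  expect_true(all(tst$sugar[tst$trial == "t1"] == 93.3))
  expect_true(all(tst$sugar[tst$trial == "t2"] == 54))
})

test_that("technical replicates share every effect except the residual", {
  # residual zero: the four wells of a sample that differ only in effects
  # constant within the plate plot are identical
  vc_nores <- light_vc(resid = c(0, 0),
                       terms = c(F_block = 6, L_platexplot = 10, L_dayxplate = 5))
  w <- tiny_world(n_cult = 20, vc = vc_nores)
  tst <- drop_standards(w$pheno)
  spread <- tapply(tst$sugar, paste(tst$trial, tst$plate, tst$plate_plot),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))

  # residual only: pooled within-sample variance estimates the residual
  vc_res <- light_vc(vg = c(0, 0), resid = c(9, 9), terms = c(F_block = 0))
  w2 <- tiny_world(n_cult = 120, n_blocks = 3, vc = vc_res, sim_seed = 31)
  tst2 <- drop_standards(w2$pheno)
  key <- paste(tst2$trial, tst2$plate, tst2$plate_plot)
  ssw <- tapply(tst2$sugar, key, function(x) sum((x - mean(x))^2))
  pooled <- sum(ssw) / (3 * length(ssw))
  expect_lt(abs(pooled - 9) / 9, 0.1)
})

test_that("shared-cultivar genetic effects reproduce the generating correlation", {
  ids <- sprintf("CV%05d", 1:6000)
  vc <- light_vc(rho = 0.66)
  g <- metphase:::with_seed(17, metphase:::draw_genetic_effects(
    list(t1 = ids, t2 = ids), vc))
  r <- cor(g$t1[ids], g$t2[ids])
  # sampling sd of a correlation at n = 6000 is about 0.0073
  expect_lt(abs(r - 0.66), 0.03)
  expect_lt(abs(var(g$t1) - 8) / 8, 0.1)
})

test_that("draws of one term have the declared variance (chi-square bracket)", {
  # 10,000 residual-pathway draws at variance 54.0; the bracket
  # [51.9, 56.1] spans +-2.75 sampling sd of a variance at n = 10,000
  vc <- variance_components(
    terms = list(t1 = c(F_block = 0)), genetic_var = c(t1 = 0),
    genetic_correlation = 0, residual_var = c(t1 = 54))
  ids <- sprintf("CV%04d", 1:2500)
  fd <- generate_field_design(ids, 1, 8, trial = "t1", seed = 2)
  ld <- generate_lab_design(fd, pad_to_full_plates = FALSE, seed = 3)
  ph <- simulate_met(list(t1 = fd), list(t1 = ld), vc, c(t1 = 100), seed = 1)
  draws <- drop_standards(ph)$sugar - 100
  expect_gte(length(draws), 10000L)
  v <- var(draws[1:10000])
  expect_gt(v, 51.9); expect_lt(v, 56.1)
})

test_that("missingness removal is whole-sample, standard-safe and exact", {
  w <- tiny_world(n_cult = 128, n_blocks = 5, seed = 3)
  ph <- w$pheno
  expect_identical(inject_missingness(ph, 0), ph)
  key <- paste(ph$trial, ph$plate, ph$plate_plot)
  n_samples <- length(unique(key[!ph$is_standard]))
  # rate tuned to the 2010 block R1 situation: 8 of 640 samples missing
  red <- inject_missingness(ph, 8 / 640, seed = 5)
  key_red <- paste(red$trial, red$plate, red$plate_plot)
  removed <- setdiff(unique(key), unique(key_red))
  expect_identical(length(removed), as.integer(round(n_samples * 8 / 640)))
  # whole samples only, never standards
  expect_true(all(table(key_red) == 4))
  expect_identical(sum(red$is_standard), sum(ph$is_standard))
  expect_error(inject_missingness(ph, 1), "rate")
  # deterministic given the seed
  expect_identical(inject_missingness(ph, 0.05, seed = 7),
                   inject_missingness(ph, 0.05, seed = 7))
})

test_that("standards carry fixed means plus laboratory (not field) effects", {
  vc <- light_vc(vg = c(5, 5), resid = c(0, 0),
                 terms = c(F_block = 50, L_row = 0))
  w <- tiny_world(n_cult = 20, vc = vc)
  std <- w$pheno[w$pheno$is_standard, ]
  # no field, lab or residual variance on standards here: exact level per id
  expect_true(all(tapply(std$sugar, std$cultivar, function(x) diff(range(x))) == 0))
  expect_identical(sort(unique(std$cultivar)), paste0("STD", 1:4))
})
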