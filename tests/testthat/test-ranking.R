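fake_bfit <- function(values_by_trial, kind = "B") {
  trials <- names(values_by_trial)
  eb <- do.call(rbind, lapply(trials, function(tr)
    data.frame(trial = tr, cultivar = names(values_by_trial[[tr]]),
               eblup = unname(values_by_trial[[tr]]), pev_diag = 0.1,
               stringsAsFactors = FALSE)))
  structure(list(kind = kind, trials = trials,
                 fixed_estimates = setNames(rep(0, length(trials)), trials),
                 eblups = eb, converged = TRUE),
            class = "met_fit")
}

test_that("top_k truncates, orders and flags ties", {
  vals <- c(a = 3, b = 5, c = 1, d = 5, e = 2)
  f <- fake_bfit(list(t1 = vals))
  all5 <- top_k(f, "t1", 5)
  expect_identical(nrow(all5), 5L)
  # equal values break lexicographically
  expect_identical(all5$cultivar, c("b", "d", "a", "e", "c"))
  expect_error(top_k(f, "t1", 6), "exceeds")
  expect_error(top_k(f, "t9", 2), "unknown trial")
  # tie across the cutoff is flagged
  t1 <- top_k(f, "t1", 1)
  expect_true(attr(t1, "ties"))
  expect_false(attr(top_k(f, "t1", 3), "ties"))
})

test_that("rankings are invariant to constant shifts within a trial", {
  vals <- metphase:::with_seed(3, setNames(rnorm(30), sprintf("c%02d", 1:30)))
  f1 <- fake_bfit(list(t1 = vals))
  f2 <- fake_bfit(list(t1 = vals + 123.4))
  expect_identical(top_k(f1, "t1", 10)$cultivar, top_k(f2, "t1", 10)$cultivar)
})

test_that("overlap is symmetric, bounded and exact on constructed lists", {
  mk <- function(ids) {
    f <- fake_bfit(list(t1 = setNames(seq(length(ids), 1), ids)))
    top_k(f, "t1", length(ids))
  }
  a <- mk(sprintf("s%02d", 1:40))
  b <- mk(sprintf("s%02d", 16:55))   # shares s16..s40: exactly 25
  ov <- overlap(a, b)
  expect_identical(ov$count, 25L)
  expect_identical(ov$count, overlap(b, a)$count)
  expect_identical(overlap(a, a)$count, 40L)
  expect_identical(overlap(a, mk(sprintf("x%02d", 1:40)))$count, 0L)
  expect_error(overlap(a, mk(sprintf("s%02d", 1:39))), "differing k")
})

test_that("a spiked cultivar tops the model-A ranking", {
  # +5 genetic SD spike under modest non-genetic noise; 30 seeds scaled
  # down from the 100-seed screen, the spike must rank first in >= 95%
  vc <- light_vc(vg = c(4, 4), resid = c(2, 2), rho = 0.8,
                 terms = c(F_block = 2, L_platexplot = 2, L_row = 1))
  ids <- sprintf("CV%04d", 1:30)
  field <- lapply(list(t1 = "t1", t2 = "t2"), function(tr)
    generate_field_design(ids, 2, 8, trial = tr, seed = 4))
  lab <- lapply(field, function(fd)
    generate_lab_design(fd, pad_to_full_plates = FALSE, seed = 5))
  hits <- 0L
  for (s in 1:30) {
    ph <- simulate_met(field, lab, vc, c(t1 = 90, t2 = 55), seed = 600 + s,
                       genetic_shift = c(CV0007 = 5 * 2))
    tab <- drop_standards(ph)
    fit <- fit_reml(spec_model("A", tab), tab)
    if (top_k(fit, "t1", 1)$cultivar == "CV0007") hits <- hits + 1L
  }
  expect_gte(hits, 29L)
})

test_that("selection index weights and renormalises over present trials", {
  f <- fake_bfit(list(t1 = c(a = 2, b = 4, onlyone = 7),
                      t2 = c(a = 2, b = 6)))
  si <- selection_index(f, c(t1 = 0.5, t2 = 0.5))
  expect_equal(si$index[si$cultivar == "a"], 2)       # equal in both trials
  expect_equal(si$index[si$cultivar == "b"], 5)
  expect_equal(si$index[si$cultivar == "onlyone"], 7) # renormalised to trial 1
  si1 <- selection_index(f, c(t1 = 1, t2 = 0))
  expect_equal(setNames(si1$index, si1$cultivar)[c("a", "b")], c(a = 2, b = 4))
  expect_error(selection_index(f, c(t1 = 1.5, t2 = -0.5)), "non-negative")
})

test_that("the equal-weight index tracks the true genetic mean best", {
  # 12 seeds scaled down from the 20-seed screen; compares Spearman
  # correlations with the true cross-trial genetic mean
  vc <- light_vc(vg = c(6, 6), resid = c(4, 4), rho = 0.6)
  ids <- sprintf("CV%04d", 1:40)
  field <- lapply(list(t1 = "t1", t2 = "t2"), function(tr)
    generate_field_design(ids, 2, 8, trial = tr, seed = 6))
  lab <- lapply(field, function(fd)
    generate_lab_design(fd, pad_to_full_plates = FALSE, seed = 7))
  d_idx <- d_t1 <- d_t2 <- numeric(0)
  for (s in 1:12) {
    ph <- simulate_met(field, lab, vc, c(t1 = 90, t2 = 55), seed = 700 + s)
    tg <- attr(ph, "true_genetic")
    truth <- tapply(tg$effect, tg$cultivar, mean)
    tab <- drop_standards(ph)
    fit <- fit_reml(spec_model("A", tab), tab)
    si <- selection_index(fit)
    idx <- setNames(si$index, si$cultivar)[names(truth)]
    v1 <- cultivar_values(fit, "t1")[names(truth)]
    v2 <- cultivar_values(fit, "t2")[names(truth)]
    d_idx <- c(d_idx, cor(idx, truth, method = "spearman"))
    d_t1 <- c(d_t1, cor(v1, truth, method = "spearman"))
    d_t2 <- c(d_t2, cor(v2, truth, method = "spearman"))
  }
  expect_gte(mean(d_idx), mean(d_t1))
  expect_gte(mean(d_idx), mean(d_t2))
})

test_that("concordance report covers models, trials and their overlaps", {
  f1 <- fake_bfit(list(t1 = setNames(1:50, sprintf("c%02d", 1:50)),
                       t2 = setNames(c(50:21, 1:20), sprintf("c%02d", 1:50))))
  rep1 <- concordance_report(list(B = f1), k = 10)
  expect_identical(nrow(rep1$cross_trial), 1L)
  expect_null(rep1$model_pairs)
  # top 10 of t1: c41..c50; top 10 of t2: c01..c10 -> empty intersection
  expect_identical(rep1$cross_trial$count, 0L)

  f2 <- fake_bfit(list(t1 = setNames(1:50, sprintf("c%02d", 1:50)),
                       t2 = setNames(1:50, sprintf("c%02d", 1:50))))
  rep2 <- concordance_report(list(B = f1, C = f2), k = 10)
  expect_identical(rep2$cross_trial$count[rep2$cross_trial$model == "C"], 10L)
  expect_identical(nrow(rep2$model_pairs), 2L)  # one pair x two trials
  expect_identical(rep2$model_pairs$count[rep2$model_pairs$trial == "t1"], 10L)
})
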