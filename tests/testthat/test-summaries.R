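fake_fit <- function(theta, pev_blocks = list(), trials = c("t1", "t2"),
                     kind = "C", ...) {
  structure(c(list(kind = kind, trials = trials, theta = theta,
                   pev_blocks = pev_blocks, converged = TRUE), list(...)),
            class = "met_fit")
}

test_that("BLUPs shrink balanced group means and centre to zero", {
  tab <- balanced_oneway_table(g = 30, r = 5, vg = 4, ve = 2, seed = 42)
  fit <- fit_reml(spec_model("A", tab), tab)
  o <- balanced_oneway_oracle(tab$sugar, tab$cultivar, r = 5)
  expect_lt(max(abs(fit$eblups$eblup - o$blup[fit$eblups$cultivar])), 1e-4)
  expect_lt(abs(mean(fit$eblups$eblup)), 1e-6)
  expect_lt(abs(heritability(fit, "t1") - o$heritability), 1e-4)
})

test_that("relabelling cultivars permutes EBLUPs identically", {
  tab <- balanced_oneway_table(g = 12, r = 4, seed = 5)
  fit1 <- fit_reml(spec_model("A", tab), tab)
  map <- setNames(sprintf("zz%03d", rev(1:12)), sprintf("g%03d", 1:12))
  tab2 <- tab; tab2$cultivar <- map[tab$cultivar]
  fit2 <- fit_reml(spec_model("A", tab2), tab2)
  e1 <- setNames(fit1$eblups$eblup, map[fit1$eblups$cultivar])
  e2 <- setNames(fit2$eblups$eblup, fit2$eblups$cultivar)
  expect_equal(e1[sort(names(e1))], e2[sort(names(e2))], tolerance = 1e-6)
})

test_that("heritability formula behaves at its anchor points", {
  m <- 6
  # a = 0: perfect prediction
  f1 <- fake_fit(c(g_var.t1 = 2), list(t1 = matrix(0, m, m)), trials = "t1")
  expect_identical(heritability(f1, "t1"), 1)
  # a = 2 vg: heritability zero (PEV = vg on the diagonal, no covariance)
  f0 <- fake_fit(c(g_var.t1 = 2), list(t1 = diag(2, m)), trials = "t1")
  expect_equal(heritability(f0, "t1"), 0)
  expect_error(heritability(f0, "t9"), "unknown trial")
})

test_that("pairwise-PEV shortcut equals the brute-force pair loop", {
  for (m in c(5, 17, 50)) {
    A <- metphase:::with_seed(m, matrix(rnorm(m * m), m))
    P <- crossprod(A) / m
    expect_lt(abs(avg_pairwise_pev(P) - brute_pairwise_pev(P)), 1e-10)
  }
})

test_that("average PEV summarises shrinkage and replication", {
  f <- fake_fit(c(g_var.t1 = 2), list(t1 = diag(0.37, 8)), trials = "t1")
  expect_equal(avg_pev(f), 0.37)
  # more replicates -> strictly smaller average PEV
  fits <- lapply(c(2, 4, 8), function(r) {
    tab <- balanced_oneway_table(g = 20, r = r, vg = 4, ve = 2, seed = 8)
    fit_reml(spec_model("A", tab), tab)
  })
  pevs <- vapply(fits, avg_pev, numeric(1))
  expect_true(all(diff(pevs) < 0))
  # vanishing genetic variance -> total shrinkage, PEV tends to zero
  w <- tiny_world(n_cult = 30, n_blocks = 2,
                  vc = light_vc(vg = c(0, 0), rho = 0), seed = 13)
  tab0 <- drop_standards(w$pheno)
  f0 <- fit_reml(spec_model("A", tab0), tab0)
  expect_lt(avg_pev(f0), 0.05 * var(tab0$sugar))
})

test_that("likelihood-ratio arithmetic matches the published comparison", {
  # model B vs model C log likelihoods as printed
  tst <- lrt(list(loglik = -70884.82, n_params = 26),
             list(loglik = -70853.58, n_params = 27))
  expect_equal(tst$statistic, 62.48, tolerance = 1e-8)
  expect_identical(tst$df, 1)
  expect_lt(tst$p_value, 0.001)
  # identical log likelihoods: no evidence
  same <- lrt(list(loglik = -10, n_params = 3), list(loglik = -10, n_params = 4))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  # chi-square anchor: 3.84 on 1 df is the 5% point
  q <- lrt(list(loglik = 0, n_params = 1), list(loglik = 1.92, n_params = 2))
  expect_equal(q$p_value, 0.050, tolerance = 1e-3)
  # an inverted pair signals optimizer failure
  expect_error(lrt(list(loglik = -5, n_params = 1),
                   list(loglik = -6, n_params = 2)), "optimizer failure")
})

test_that("genetic correlation and covariance are consistent", {
  f <- fake_fit(c(g_var.t1 = 13.5, g_var.t2 = 6.9, g_cor = 0.66,
                  resid.t1 = 27.4, resid.t2 = 11.5))
  expect_equal(genetic_correlation(f), 0.66)
  # rho * sqrt(v1 v2): the covariance scale of the published estimate
  expect_equal(round(genetic_covariance(f), 2), 6.37)
  expect_equal(round(6.37 / sqrt(13.5 * 6.9), 2), 0.66)
  f0 <- fake_fit(c(g_var.t1 = 13.5, g_var.t2 = 6.9, g_cor = 0,
                   resid.t1 = 1, resid.t2 = 1))
  expect_identical(genetic_correlation(f0), 0)
  f1 <- fake_fit(c(g_var.t1 = 4, g_var.t2 = 9, g_cor = 1,
                   resid.t1 = 1, resid.t2 = 1))
  expect_equal(genetic_covariance(f1), 6)  # sqrt(v1 v2)
  fb <- fake_fit(c(g_var.t1 = 1e-12, g_var.t2 = 6.9, g_cor = 0.5,
                   resid.t1 = 1, resid.t2 = 1))
  expect_error(genetic_correlation(fb), "boundary")
  fa <- fake_fit(c(g_var.t1 = 1, g_var.t2 = 1, resid.t1 = 1, resid.t2 = 1),
                 kind = "B")
  expect_error(genetic_correlation(fa), "model C")
})

test_that("variance tables reproduce the published percent arithmetic", {
  vc <- vc_preset_trials()
  comp10 <- c(vc$terms[["2010"]][vc$terms[["2010"]] > 0],
              Cultivar = unname(vc$genetic_var[["2010"]]),
              Residual = unname(vc$residual_var[["2010"]]))
  tab10 <- variance_percent_table(comp10)
  expect_equal(tab10$percent[tab10$term == "F_block"], 20.5)
  expect_equal(tab10$percent[tab10$term == "Field Total"], 27.9)
  expect_equal(tab10$percent[tab10$term == "Cultivar"], 5.1)
  expect_equal(tab10$variance[tab10$term == "Field Total"], 73.3)
  expect_equal(tab10$variance[tab10$term == "Laboratory Total"], 149.0)

  comp11 <- c(vc$terms[["2011"]][vc$terms[["2011"]] > 0],
              Cultivar = unname(vc$genetic_var[["2011"]]),
              Residual = unname(vc$residual_var[["2011"]]))
  tab11 <- variance_percent_table(comp11)
  expect_equal(tab11$percent[tab11$term == "Cultivar"], 7.4)
  # 58.2 from the printed (rounded) components; the published 58.1 was
  # computed from unrounded estimates, one rounding step away
  expect_equal(tab11$percent[tab11$term == "Laboratory Total"], 58.2)
  expect_equal(tab11$percent[tab11$term == "Field Total"], 22.2)

  # single component: 100% by normalisation
  expect_equal(variance_percent_table(c(Residual = 3))$percent, 100)
})
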