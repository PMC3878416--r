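# Independent oracles, kept deliberately naive.

# Direct dense REML formula: -1/2 [log|V| + log|X'V^-1 X| + y'Py] + const,
# V = Z G Z' + R built element by element. Used to certify the sparse
# mixed-model-equations path on instances small enough to densify.
dense_reml_oracle <- function(theta, mats) {
  W <- as.matrix(mats$W); n <- mats$n; p <- mats$p
  X <- W[, 1:p, drop = FALSE]
  V <- matrix(0, n, n)
  for (k in seq_along(mats$trials)) {
    tr <- mats$trials[k]
    rows <- mats$trial_obs[[tr]]
    V[cbind(rows, rows)] <- V[cbind(rows, rows)] + theta[[paste0("resid.", tr)]]
  }
  if (ncol(W) > p) {
    G <- matrix(0, ncol(W) - p, ncol(W) - p)
    if (length(mats$gen_cols)) {
      trs <- mats$trials
      v <- sapply(trs, function(tr) theta[[paste0("g_var.", tr)]])
      for (k in seq_along(trs)) {
        ix <- mats$gen_cols[[trs[k]]] - p
        G[cbind(ix, ix)] <- v[k]
      }
      if ("g_cor" %in% names(theta)) {
        rho <- theta[["g_cor"]]
        sh <- mats$shared_cultivars
        i1 <- mats$gen_cols[[1]][match(sh, mats$gen_levels[[1]])] - p
        i2 <- mats$gen_cols[[2]][match(sh, mats$gen_levels[[2]])] - p
        G[cbind(i1, i2)] <- G[cbind(i2, i1)] <- rho * sqrt(v[1] * v[2])
      }
    }
    for (key in names(mats$term_cols)) {
      ix <- mats$term_cols[[key]] - p
      G[cbind(ix, ix)] <- theta[[paste0("v.", key)]]
    }
    Z <- W[, -(1:p), drop = FALSE]
    V <- V + Z %*% G %*% t(Z)
  }
  Vi <- solve(V); XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  y <- mats$y
  as.numeric(-0.5 * (determinant(V, log = TRUE)$modulus +
    determinant(XVX, log = TRUE)$modulus + t(y) %*% P %*% y +
    (n - p) * log(2 * pi)))
}

# Balanced one-way ANOVA method-of-moments estimators (coincide with REML
# on balanced data), plus the classic BLUP shrinkage and line-mean
# heritability.
balanced_oneway_oracle <- function(y, group, r) {
  ybar <- tapply(y, group, mean)
  g <- length(ybar)
  MSB <- r * var(ybar)
  MSW <- sum((y - ybar[group])^2) / (g * (r - 1))
  vg <- max((MSB - MSW) / r, 0)
  lambda <- vg / (vg + MSW / r)
  list(vg = vg, ve = MSW, lambda = lambda,
       blup = lambda * (ybar - mean(ybar)),
       heritability = lambda)
}

# Brute-force average pairwise prediction error variance.
brute_pairwise_pev <- function(P) {
  m <- nrow(P)
  tot <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m)
    tot <- tot + P[i, i] + P[j, j] - 2 * P[i, j]
  tot / (m * (m - 1) / 2)
}
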