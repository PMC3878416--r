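# Sparse REML machinery.
#
# The REML log likelihood is evaluated through Henderson's mixed-model
# equations: with W = [X | Z], R = blockdiag_p(s_p I) and G the joint
# covariance of all random effects,
#
#   C = W' R^-1 W + blockdiag(0_pxp, G^-1)
#   l_R = -1/2 [ log|C| + log|G| + log|R| + y'Py + (n - p) log 2pi ]
#   y'Py = y' R^-1 y - rhs' C^-1 rhs,   rhs = W' R^-1 y
#
# which equals the direct dense formula
# -1/2 [ log|V| + log|X'V^-1 X| + y'Py ] + const with V = ZGZ' + R.
# Per-trial cross-products W_p'W_p are cached so each evaluation only
# rescales numeric values on a fixed sparsity pattern and re-runs the
# numeric phase of a cached sparse Cholesky factorisation.

# ---- parameter bookkeeping -------------------------------------------------

# Natural-scale parameter vector layout for a given matrix set:
# g_var.<trial> ..., [g_cor], v.<trial>.<term> ..., resid.<trial> ...
par_layout <- function(mats) {
  spec <- mats$spec
  has_gen <- length(mats$gen_cols) > 0L
  nm <- character(0)
  if (has_gen) nm <- paste0("g_var.", mats$trials)
  free_cov <- isTRUE(spec$free_cov) && has_gen && length(mats$trials) == 2L
  if (free_cov) {
    if (!length(mats$shared_cultivars))
      stop2("model C requires cultivars shared between the two trials")
    nm <- c(nm, "g_cor")
  }
  nm <- c(nm, if (length(mats$term_cols)) paste0("v.", names(mats$term_cols)))
  nm <- c(nm, paste0("resid.", mats$trials))
  list(names = nm, free_cov = free_cov, has_gen = has_gen)
}

# natural -> unconstrained (log variances, atanh correlation)
to_unconstrained <- function(theta) {
  u <- log(pmax(theta, 1e-300))
  if ("g_cor" %in% names(theta))
    u["g_cor"] <- atanh(max(-0.999, min(0.999, theta[["g_cor"]])))
  u
}

to_natural <- function(u) {
  th <- exp(u)
  if ("g_cor" %in% names(u)) th["g_cor"] <- tanh(u[["g_cor"]])
  th
}

# ---- cached evaluation structures ------------------------------------------

sparse_keys <- function(M, N) {
  # entry keys of a column-compressed symmetric (upper) sparse matrix
  j <- rep.int(seq_len(ncol(M)), diff(M@p))
  (M@i + 1) + (j - 1) * as.double(N)
}

reml_prepare <- function(mats) {
  W <- mats$W; y <- mats$y
  N <- ncol(W)
  lay <- par_layout(mats)
  trials <- mats$trials
  p <- mats$p

  Ap <- list(); cp <- list(); dp <- numeric(length(trials)); np <- integer(length(trials))
  for (k in seq_along(trials)) {
    rows <- mats$trial_obs[[k]]
    Wk <- W[rows, , drop = FALSE]
    Ap[[k]] <- as(Matrix::forceSymmetric(Matrix::crossprod(Wk), uplo = "U"),
                  "CsparseMatrix")
    cp[[k]] <- as.numeric(Matrix::crossprod(Wk, y[rows]))
    dp[k] <- sum(y[rows]^2)
    np[k] <- length(rows)
  }

  ## G^-1 pattern: one diagonal entry per random column, plus one
  ## off-diagonal entry per shared cultivar under a free covariance
  rand_cols <- if (N > p) (p + 1L):N else integer(0)
  gdiag_i <- rand_cols
  goff_i <- integer(0); goff_j <- integer(0)
  if (lay$free_cov) {
    sh <- mats$shared_cultivars
    i1 <- mats$gen_cols[[1]][match(sh, mats$gen_levels[[1]])]
    j2 <- mats$gen_cols[[2]][match(sh, mats$gen_levels[[2]])]
    goff_i <- pmin(i1, j2); goff_j <- pmax(i1, j2)
  }
  G0 <- Matrix::sparseMatrix(i = c(gdiag_i, goff_i), j = c(gdiag_i, goff_j),
                             x = rep(1, length(gdiag_i) + length(goff_i)),
                             dims = c(N, N), symmetric = TRUE)
  G0 <- as(Matrix::forceSymmetric(G0, uplo = "U"), "CsparseMatrix")

  U <- Ap[[1]]
  for (k in seq_along(trials)[-1]) U <- U + Ap[[k]]
  U <- as(Matrix::forceSymmetric(U + G0, uplo = "U"), "CsparseMatrix")
  keyU <- sparse_keys(U, N)
  mapA <- lapply(Ap, function(A) match(sparse_keys(A, N), keyU))
  key_gdiag <- gdiag_i + (gdiag_i - 1) * as.double(N)
  key_goff <- if (length(goff_i)) goff_i + (goff_j - 1) * as.double(N) else numeric(0)
  map_gdiag <- match(key_gdiag, keyU)
  map_goff <- match(key_goff, keyU)

  ## group id of each random column: which variance parameter scales it
  ## (genetic columns of shared cultivars are tagged separately so the
  ## 2x2 inverse blocks get their own diagonal values)
  grp <- character(N - p)
  names(grp) <- NULL
  if (lay$has_gen) {
    for (k in seq_along(trials)) {
      cols <- mats$gen_cols[[k]] - p
      grp[cols] <- paste0("g_var.", trials[k])
      if (lay$free_cov) {
        shc <- mats$gen_cols[[k]][match(mats$shared_cultivars,
                                        mats$gen_levels[[k]])] - p
        grp[shc] <- paste0("g_sh.", trials[k])
      }
    }
  }
  for (key in names(mats$term_cols)) grp[mats$term_cols[[key]] - p] <- paste0("v.", key)
  grp_levels <- unique(grp)
  grp_idx <- match(grp, grp_levels)
  grp_sizes <- tabulate(grp_idx, length(grp_levels))

  env <- new.env(parent = emptyenv())
  env$chol <- NULL

  list(mats = mats, lay = lay, N = N, p = p, n = mats$n,
       trials = trials, Ap = Ap, cp = cp, dp = dp, np = np,
       U = U, nnzU = length(keyU), mapA = mapA,
       map_gdiag = map_gdiag, map_goff = map_goff,
       grp_levels = grp_levels, grp_idx = grp_idx, grp_sizes = grp_sizes,
       n_shared = length(mats$shared_cultivars), env = env)
}

# Diagonal (and shared off-diagonal) values of G^-1, plus log|G|.
ginv_values <- function(theta, prep) {
  lay <- prep$lay; trials <- prep$trials
  vals <- setNames(numeric(length(prep$grp_levels)), prep$grp_levels)
  ldG <- 0
  off <- numeric(0)
  if (lay$has_gen) {
    v <- theta[paste0("g_var.", trials)]
    if (lay$free_cov) {
      rho <- theta[["g_cor"]]
      om <- 1 - rho^2
      msh <- prep$n_shared
      vals[paste0("g_sh.", trials[1])] <- 1 / (v[1] * om)
      vals[paste0("g_sh.", trials[2])] <- 1 / (v[2] * om)
      off <- rep(-rho / (sqrt(v[1] * v[2]) * om), msh)
      ldG <- ldG + msh * (log(v[1]) + log(v[2]) + log(om))
      for (k in 1:2) {
        key <- paste0("g_var.", trials[k])
        if (key %in% prep$grp_levels) {
          vals[key] <- 1 / v[k]
          ldG <- ldG + prep$grp_sizes[match(key, prep$grp_levels)] * log(v[k])
        }
      }
    } else {
      for (k in seq_along(trials)) {
        key <- paste0("g_var.", trials[k])
        vals[key] <- 1 / v[k]
        ldG <- ldG + prep$grp_sizes[match(key, prep$grp_levels)] * log(v[k])
      }
    }
  }
  for (key in prep$grp_levels[startsWith(prep$grp_levels, "v.")]) {
    vv <- theta[[key]]
    vals[key] <- 1 / vv
    ldG <- ldG + prep$grp_sizes[match(key, prep$grp_levels)] * log(vv)
  }
  list(diag = vals[prep$grp_idx], off = off, ldG = ldG)
}

# Core evaluation: REML log likelihood, optionally with the MME solution
# and factor for downstream EBLUP/PEV extraction.
reml_eval <- function(theta, prep, want_solution = FALSE) {
  s <- theta[paste0("resid.", prep$trials)]
  if (any(!is.finite(s)) || any(s <= 0)) return(list(ll = -Inf))
  gv <- ginv_values(theta, prep)
  if (any(!is.finite(gv$diag))) return(list(ll = -Inf))

  xc <- numeric(prep$nnzU)
  rhs <- numeric(prep$N)
  yRy <- 0; ldR <- 0
  for (k in seq_along(prep$trials)) {
    w <- 1 / s[k]
    xc[prep$mapA[[k]]] <- xc[prep$mapA[[k]]] + prep$Ap[[k]]@x * w
    rhs <- rhs + prep$cp[[k]] * w
    yRy <- yRy + prep$dp[k] * w
    ldR <- ldR + prep$np[k] * log(s[k])
  }
  xc[prep$map_gdiag] <- xc[prep$map_gdiag] + gv$diag
  if (length(prep$map_goff))
    xc[prep$map_goff] <- xc[prep$map_goff] + gv$off

  C <- prep$U
  C@x <- xc
  ch <- tryCatch({
    if (is.null(prep$env$chol)) {
      prep$env$chol <- Matrix::Cholesky(C, LDL = FALSE, super = NA)
      prep$env$chol
    } else Matrix::update(prep$env$chol, C)
  }, error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  prep$env$chol <- ch

  ldC <- as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  yPy <- yRy - sum(rhs * sol)
  ll <- unname(-0.5 * (ldC + gv$ldG + ldR + yPy + (prep$n - prep$p) * log(2 * pi)))
  if (!is.finite(ll)) return(list(ll = -Inf))
  if (!want_solution) return(list(ll = ll))
  list(ll = ll, solution = sol, chol = ch, yPy = yPy)
}

#' REML log likelihood of a variance-parameter vector
#'
#' Evaluates the residual log likelihood at the supplied natural-scale
#' parameters using the sparse mixed-model-equations identity. The
#' fixed-effects constant `-(n - p)/2 * log(2*pi)` is included, so values
#' are comparable across nested models fitted to the same data (but not
#' across software with other constant conventions).
#'
#' @param theta named numeric vector: `g_var.<trial>`, optional `g_cor`,
#'   `v.<trial>.<term>`, `resid.<trial>` (see [fit_reml()] results for the
#'   naming).
#' @param mats a [build_matrices()] result.
#' @param y optional response override (defaults to the response stored in
#'   `mats`).
#' @return the REML log likelihood (scalar).
#' @export
reml_loglik <- function(theta, mats, y = NULL) {
  if (!is.null(y)) {
    stopifnot(length(y) == mats$n)
    mats$y <- y
  }
  prep <- reml_prepare(mats)
  lay <- prep$lay
  theta <- unlist(theta)
  miss <- setdiff(lay$names, names(theta))
  if (length(miss)) stop2("theta lacks parameters: ", paste(miss, collapse = ", "))
  vars <- setdiff(lay$names, "g_cor")
  if (any(theta[vars] <= 0)) stop2("variances must be positive")
  res <- reml_eval(theta[lay$names], prep)
  if (!is.finite(res$ll)) stop2("coefficient matrix not positive definite")
  res$ll
}
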