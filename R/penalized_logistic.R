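# Proximal-gradient machinery shared by the lasso, combined-lasso and
# group-lasso logistic models.
#
# Parameterization: coefficient matrix B (p x C) and per-tissue intercepts
# c (length T). For the shared-coefficient models C = 1 (every sample uses
# the single column); for the group lasso C = T and sample i uses column
# tidx[i]. The smooth part is sum_i w_i * log(1 + exp(-s_i eta_i)) with
# s = 2y - 1 and caller-chosen sample weights w (1/n pooled, or 1/n_t per
# tissue). The penalty is lambda * sqrt(C) * sum_g ||B[g, ]||_2, whose prox
# is a row-wise group soft-threshold; for C = 1 this is exactly the lasso
# soft-threshold, so one engine backs all three models.
#
# Solver: monotone FISTA (MFISTA) with backtracking line search and
# adaptive restart on rejected steps, so the objective is non-increasing
# across iterations by construction.

.intercept_init <- function(y, tidx, n_tissues) {
  vapply(seq_len(n_tissues), function(t) {
    r <- mean(y[tidx == t])
    if (!is.finite(r)) return(0)
    qlogis(min(max(r, 0.02), 0.98))
  }, numeric(1))
}

.fista_logistic <- function(x, y, tidx, n_tissues, grouped, lambda, w,
                            beta0 = NULL, intercept0 = NULL,
                            max_iter = 5000L, tol = 1e-7,
                            on_nonconvergence = c("warn", "error", "silent")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  n <- nrow(x); p <- ncol(x)
  if (lambda < 0) .stopf("'lambda' must be non-negative")
  C <- if (grouped) n_tissues else 1L
  cid <- if (grouped) tidx else rep(1L, n)
  rows_c <- split(seq_len(n), factor(cid, levels = seq_len(C)))
  rows_t <- split(seq_len(n), factor(tidx, levels = seq_len(n_tissues)))
  s <- 2 * y - 1

  eta_of <- function(B, c0) {
    eta <- c0[tidx]
    for (j in seq_len(C)) {
      r <- rows_c[[j]]
      if (length(r)) eta[r] <- eta[r] + drop(x[r, , drop = FALSE] %*% B[, j])
    }
    eta
  }
  smooth_of <- function(eta) sum(w * .softplus(-s * eta))
  grad_of <- function(eta) {
    r <- w * (plogis(eta) - y)
    gB <- matrix(0, p, C)
    for (j in seq_len(C)) {
      rj <- rows_c[[j]]
      if (length(rj)) gB[, j] <- crossprod(x[rj, , drop = FALSE], r[rj])
    }
    gc <- vapply(rows_t, function(ri) sum(r[ri]), numeric(1))
    list(B = gB, c = gc)
  }
  pen_mult <- lambda * sqrt(C)
  pen_of <- function(B) {
    if (pen_mult == 0) return(0)
    pen_mult * sum(sqrt(rowSums(B * B)))
  }
  prox <- function(V, step) {
    if (pen_mult == 0) return(V)
    rn <- sqrt(rowSums(V * V))
    shrink <- pmax(0, 1 - step * pen_mult / pmax(rn, .Machine$double.xmin))
    V * shrink
  }

  B <- if (is.null(beta0)) matrix(0, p, C) else beta0
  c0 <- if (is.null(intercept0)) .intercept_init(y, tidx, n_tissues) else intercept0
  Fx <- smooth_of(eta_of(B, c0)) + pen_of(B)
  yB <- B; yc <- c0
  tk <- 1; L <- 1
  converged <- FALSE; hits <- 0L; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta_y <- eta_of(yB, yc)
    fy <- smooth_of(eta_y)
    g <- grad_of(eta_y)
    repeat {
      step <- 1 / L
      zB <- prox(yB - step * g$B, step)
      zc <- yc - step * g$c
      dB <- zB - yB; dc <- zc - yc
      fz <- smooth_of(eta_of(zB, zc))
      quad <- fy + sum(g$B * dB) + sum(g$c * dc) +
        (L / 2) * (sum(dB * dB) + sum(dc * dc))
      if (fz <= quad + 1e-12 * max(1, abs(quad)) || L > 1e14) break
      L <- L * 2
    }
    Fz <- fz + pen_of(zB)
    if (Fz <= Fx) {
      rel <- (Fx - Fz) / max(1, abs(Fx))
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      yB <- zB + ((tk - 1) / tk1) * (zB - B)
      yc <- zc + ((tk - 1) / tk1) * (zc - c0)
      B <- zB; c0 <- zc; Fx <- Fz; tk <- tk1
      if (rel < tol) {
        hits <- hits + 1L
        if (hits >= 3L) { converged <- TRUE; break }
      } else hits <- 0L
    } else {
      # rejected step: restart momentum from the current (best) iterate
      yB <- B; yc <- c0; tk <- 1; hits <- 0L
    }
    L <- max(L * 0.9, 1e-4)
  }
  if (!converged) {
    msg <- sprintf(
      "solver stopped at max_iter = %d without meeting tol = %g (objective %.6g, lambda %.4g)",
      max_iter, tol, Fx, lambda)
    if (on_nonconvergence == "error") .stopf("%s", msg)
    if (on_nonconvergence == "warn") .warnf("%s", msg)
  }
  list(beta = B, intercept = c0, objective = Fx, n_iter = it,
       converged = converged, lambda = lambda, grouped = grouped)
}

# smallest lambda for which all coefficient rows are zero (gradient at the
# intercept-only optimum)
.lambda_max <- function(x, y, tidx, n_tissues, grouped, w) {
  C <- if (grouped) n_tissues else 1L
  cid <- if (grouped) tidx else rep(1L, length(y))
  c0 <- vapply(seq_len(n_tissues), function(t) {
    r <- mean(y[tidx == t])
    if (!is.finite(r)) return(0)
    qlogis(min(max(r, 1e-6), 1 - 1e-6))
  }, numeric(1))
  r <- w * (plogis(c0[tidx]) - y)
  G <- matrix(0, ncol(x), C)
  for (j in seq_len(C)) {
    rj <- which(cid == j)
    if (length(rj)) G[, j] <- crossprod(x[rj, , drop = FALSE], r[rj])
  }
  max(sqrt(rowSums(G * G))) / sqrt(C)
}

.lambda_grid <- function(lambda_max, n_lambda = 50L, min_ratio = 0.01) {
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = n_lambda))
}

# warm-started path fit from large to small lambda
.fit_path <- function(x, y, tidx, n_tissues, grouped, w, lambdas,
                      max_iter = 2000L, tol = 1e-7) {
  fits <- vector("list", length(lambdas))
  beta0 <- NULL; int0 <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- .fista_logistic(x, y, tidx, n_tissues, grouped, lambdas[i], w,
                                 beta0 = beta0, intercept0 = int0,
                                 max_iter = max_iter, tol = tol,
                                 on_nonconvergence = "silent")
    beta0 <- fits[[i]]$beta
    int0 <- fits[[i]]$intercept
  }
  fits
}

# mean held-out logistic deviance-style loss for a single fit
.holdout_logloss <- function(fit, x, y, tidx) {
  C <- ncol(fit$beta)
  cid <- if (C == 1L) rep(1L, length(y)) else tidx
  eta <- fit$intercept[tidx]
  for (j in seq_len(C)) {
    rj <- which(cid == j)
    if (length(rj)) eta[rj] <- eta[rj] + drop(x[rj, , drop = FALSE] %*% fit$beta[, j])
  }
  mean(.softplus(-(2 * y - 1) * eta))
}

# inner-CV lambda choice over the log-spaced grid: "min" takes the minimum
# mean held-out log-loss, "1se" the largest lambda within one standard
# error of that minimum (the sparser, stability-oriented choice)
.choose_lambda <- function(x, y, tidx, n_tissues, grouped, wmode,
                           n_lambda = 50L, inner_folds = 3L,
                           lambda_policy = c("min", "1se")) {
  lambda_policy <- match.arg(lambda_policy)
  w_of <- function(yy, tt) {
    if (wmode == "per_tissue") {
      nt <- table(factor(tt, levels = seq_len(n_tissues)))
      1 / as.numeric(nt)[tt]
    } else rep(1 / length(yy), length(yy))
  }
  lmax <- .lambda_max(x, y, tidx, n_tissues, grouped, w_of(y, tidx))
  lambdas <- .lambda_grid(lmax, n_lambda)
  strata <- interaction(y, tidx, drop = FALSE)
  fold <- .stratified_folds(strata, inner_folds)
  loss <- matrix(NA_real_, inner_folds, length(lambdas))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 1L) next
    fits <- .fit_path(x[tr, , drop = FALSE], y[tr], tidx[tr], n_tissues,
                      grouped, w_of(y[tr], tidx[tr]), lambdas)
    loss[f, ] <- vapply(fits, .holdout_logloss,
                        numeric(1), x[!tr, , drop = FALSE], y[!tr], tidx[!tr])
  }
  mean_loss <- colMeans(loss, na.rm = TRUE)
  i_min <- which.min(mean_loss)
  i_pick <- if (lambda_policy == "1se") {
    se <- apply(loss, 2, sd, na.rm = TRUE) / sqrt(sum(!is.na(loss[, i_min])))
    min(which(mean_loss <= mean_loss[i_min] + se[i_min]))
  } else i_min
  list(lambda = lambdas[i_pick], lambdas = lambdas, mean_loss = mean_loss)
}
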