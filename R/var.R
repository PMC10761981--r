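# --- VAR modeling: simulation, fitting, autocovariance ----------------------

#' VAR model container and stability
#'
#' A VAR(p) model `x_t = sum_k A_k x_{t-k} + e_t` with residual covariance
#' `Sigma`. `var_spectral_radius` returns the companion-matrix spectral radius
#' (< 1 for a stable process).
#'
#' @param A list of `n x n` coefficient matrices (or a single matrix for
#'   VAR(1)).
#' @param Sigma `n x n` residual covariance (symmetric positive definite).
#' @param labels optional channel labels.
#' @return `var_model`: list with `A`, `Sigma`, `p`, `n`, `labels`.
#' @export
var_model <- function(A, Sigma, labels = NULL) {
  if (is.matrix(A)) A <- list(A)
  n <- nrow(A[[1]])
  stopifnot(all(vapply(A, function(a) all(dim(a) == n), logical(1))),
            all(dim(Sigma) == n))
  if (any(abs(Sigma - t(Sigma)) > 1e-10) || any(eigen(Sigma, TRUE,
                                                      TRUE)$values <= 0))
    stop("Sigma must be symmetric positive definite")
  structure(list(A = A, Sigma = Sigma, p = length(A), n = n,
                 labels = labels %||% paste0("ch", seq_len(n))),
            class = "var_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

companion_matrix <- function(A) {
  p <- length(A); n <- nrow(A[[1]])
  cm <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) cm[1:n, ((k - 1) * n + 1):(k * n)] <- A[[k]]
  if (p > 1) cm[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  cm
}

#' @rdname var_model
#' @param model a `var_model`.
#' @export
var_spectral_radius <- function(model) {
  max(Mod(eigen(companion_matrix(model$A), only.values = TRUE)$values))
}

#' Simulate a VAR process
#'
#' Draws `n_samples` from a stable VAR model after a burn-in, with Gaussian
#' innovations. Used as the ground-truth source for the Granger-causality
#' estimators.
#'
#' @param model a [var_model()] (or a list of coefficient matrices plus
#'   `Sigma`).
#' @param n_samples output length.
#' @param seed RNG seed.
#' @param burn_in samples discarded at the start.
#' @return numeric matrix `n x n_samples`.
#' @export
simulate_var_network <- function(model, n_samples, seed,
                                 burn_in = 100 * model$p + 1000) {
  if (var_spectral_radius(model) >= 1)
    stop("unstable VAR specification (companion spectral radius >= 1)")
  n <- model$n; p <- model$p
  total <- n_samples + burn_in
  L <- t(chol(model$Sigma))
  with_seed(seed, {
    e <- L %*% matrix(rnorm(n * total), n, total)
    x <- matrix(0, n, total)
    x[, 1:p] <- e[, 1:p]
    for (t in (p + 1):total) {
      acc <- e[, t]
      for (k in seq_len(p)) acc <- acc + model$A[[k]] %*% x[, t - k]
      x[, t] <- acc
    }
    unname(x[, (burn_in + 1):total, drop = FALSE])
  })
}

#' Closed-form Geweke GC for the canonical bivariate VAR(1)
#'
#' For the system `x_t = ex_t`, `y_t = a x_{t-1} + ey_t` with independent
#' noises of variances `sx2`, `sy2`, the time-domain Granger causality from x
#' to y is `ln(1 + a^2 sx2 / sy2)`; the reverse direction is exactly 0.
#'
#' @param a coupling coefficient.
#' @param sx2,sy2 innovation variances (positive).
#' @return the GC value (natural log scale).
#' @export
analytic_gc_var1 <- function(a, sx2 = 1, sy2 = 1) {
  if (sx2 <= 0 || sy2 <= 0) stop("noise variances must be positive")
  log(1 + a^2 * sx2 / sy2)
}

# Multi-trial sample autocovariance Gamma_0..Gamma_q (biased, 1/T within each
# trial, pooled across trials), after per-channel demeaning across all trials.
sample_autocov <- function(data, q) {
  if (is.matrix(data)) data <- list(data)
  n <- nrow(data[[1]])
  mu <- rowMeans(do.call(cbind, data))
  data <- lapply(data, function(x) x - mu)
  total <- sum(vapply(data, ncol, integer(1)))
  G <- array(0, dim = c(n, n, q + 1))
  for (x in data) {
    T_ <- ncol(x)
    for (k in 0:min(q, T_ - 1)) {
      G[, , k + 1] <- G[, , k + 1] +
        tcrossprod(x[, (k + 1):T_, drop = FALSE], x[, 1:(T_ - k), drop = FALSE])
    }
  }
  G / total
}

# Whittle (multichannel Levinson) recursion on an autocovariance sequence.
# Returns coefficient matrices and residual covariance for order p, plus the
# forward residual covariance at every intermediate order (for BIC).
whittle_var <- function(G, p) {
  n <- dim(G)[1]
  stopifnot(dim(G)[3] >= p + 1)
  g <- lapply(0:p, function(k) matrix(G[, , k + 1], n, n))
  V <- g[[1]]; W <- g[[1]]
  A <- list(); B <- list()
  sigmas <- vector("list", p)
  for (m in seq_len(p)) {
    delta <- g[[m + 1]]
    if (m > 1) for (k in seq_len(m - 1))
      delta <- delta - A[[k]] %*% g[[m - k + 1]]
    Am <- t(solve(t(W), t(delta)))        # delta %*% solve(W)
    Bm <- t(solve(t(V), delta))           # t(delta) %*% solve(V)
    if (m > 1) {
      Ak <- lapply(seq_len(m - 1), function(k) A[[k]] - Am %*% B[[m - k]])
      Bk <- lapply(seq_len(m - 1), function(k) B[[k]] - Bm %*% A[[m - k]])
      A <- Ak; B <- Bk
    }
    A[[m]] <- Am; B[[m]] <- Bm
    V <- V - Am %*% t(delta)
    W <- W - Bm %*% delta
    V <- (V + t(V)) / 2; W <- (W + t(W)) / 2
    sigmas[[m]] <- V
  }
  list(A = A, Sigma = V, order_sigmas = sigmas)
}

#' Fit a VAR model to multichannel data
#'
#' Default method is the Levinson-Whittle recursion (LWR) on the sample
#' autocovariance sequence; ordinary least squares is available as a
#' cross-check. Channels are demeaned before fitting; the fitted model's
#' stability is verified.
#'
#' @param data `n x T` matrix, or a list of such matrices (multi-trial).
#' @param p model order.
#' @param method `"lwr"` or `"ols"`.
#' @return a [var_model()] with attribute `spectral_radius`.
#' @export
fit_var <- function(data, p, method = c("lwr", "ols")) {
  method <- match.arg(method)
  if (is.matrix(data)) data <- list(data)
  n <- nrow(data[[1]])
  if (method == "lwr") {
    G <- sample_autocov(data, p)
    fit <- whittle_var(G, p)
    A <- fit$A; Sigma <- fit$Sigma
  } else {
    mu <- rowMeans(do.call(cbind, data))
    xs <- lapply(data, function(x) x - mu)
    Y <- NULL; X <- NULL
    for (x in xs) {
      T_ <- ncol(x)
      if (T_ <= p) next
      Y <- cbind(Y, x[, (p + 1):T_, drop = FALSE])
      Xk <- do.call(rbind, lapply(seq_len(p), function(k)
        x[, (p + 1 - k):(T_ - k), drop = FALSE]))
      X <- cbind(X, Xk)
    }
    coefs <- t(solve(tcrossprod(X), X %*% t(Y)))   # n x (n p)
    A <- lapply(seq_len(p), function(k)
      coefs[, ((k - 1) * n + 1):(k * n), drop = FALSE])
    resid <- Y - coefs %*% X
    Sigma <- tcrossprod(resid) / ncol(Y)
  }
  m <- var_model(A, Sigma)
  rho <- var_spectral_radius(m)
  if (rho >= 1)
    stop(sprintf("fitted VAR is unstable (spectral radius %.4f)", rho))
  attr(m, "spectral_radius") <- rho
  m
}

#' Select the VAR model order by BIC
#'
#' Fits all orders `1..p_max` in one Levinson-Whittle pass and returns the
#' order minimizing `BIC(p) = ln det(Sigma_p) + ln(T) n^2 p / T`.
#'
#' @inheritParams fit_var
#' @param p_max largest order searched.
#' @return list with `order`, `bic` (vector over orders), `at_boundary`
#'   (TRUE with a warning when the minimum sits at `p_max`).
#' @export
select_model_order <- function(data, p_max) {
  if (is.matrix(data)) data <- list(data)
  n <- nrow(data[[1]])
  T_ <- sum(vapply(data, ncol, integer(1)))
  G <- sample_autocov(data, p_max)
  fit <- whittle_var(G, p_max)
  bic <- vapply(seq_len(p_max), function(p) {
    s <- fit$order_sigmas[[p]]
    ld <- determinant(s, logarithm = TRUE)
    if (ld$sign <= 0) return(NA_real_)
    as.numeric(ld$modulus) + log(T_) * n^2 * p / T_
  }, numeric(1))
  ord <- which.min(bic)
  at_boundary <- ord == p_max
  if (at_boundary)
    warning("BIC minimum at p_max = ", p_max, "; consider increasing the range")
  list(order = ord, bic = bic, at_boundary = at_boundary)
}

#' Model autocovariance sequence of a VAR
#'
#' `Gamma_0` solves the companion-form discrete Lyapunov equation (by the
#' doubling iteration); higher lags follow the Yule-Walker recursion
#' `Gamma_k = sum_j A_j Gamma_{k-j}`. The sequence is truncated when
#' `max|Gamma_k| < decay_tol * max|Gamma_0|`, capped at `max_lags`.
#'
#' @param model a [var_model()].
#' @param max_lags cap on the number of lags (default 1500).
#' @param decay_tol relative truncation tolerance.
#' @return array `n x n x (q + 1)` with attributes `spectral_radius`,
#'   `lags_used`, `gamma0_min_eig` (the model-diagnostic report).
#' @export
var_to_autocov <- function(model, max_lags = 1500, decay_tol = 1e-8) {
  rho <- var_spectral_radius(model)
  if (rho >= 1) stop("unstable model; autocovariance undefined")
  n <- model$n; p <- model$p
  cm <- companion_matrix(model$A)
  Q <- matrix(0, n * p, n * p)
  Q[1:n, 1:n] <- model$Sigma
  # doubling iteration for P = cm P cm' + Q
  P <- Q; X <- cm
  for (it in 1:200) {
    P <- P + X %*% P %*% t(X)
    X <- X %*% X
    if (max(abs(X)) < 1e-14) break
  }
  P <- (P + t(P)) / 2
  ev <- eigen(P[1:n, 1:n], symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Lyapunov solution is not positive definite (min eig ",
         format(min(ev)), ")")
  gammas <- vector("list", max_lags + 1)
  for (k in 0:(p - 1)) gammas[[k + 1]] <- P[1:n, (k * n + 1):((k + 1) * n)]
  g0max <- max(abs(gammas[[1]]))
  q <- p - 1
  for (m in p:max_lags) {
    gm <- matrix(0, n, n)
    for (k in seq_len(p)) gm <- gm + model$A[[k]] %*% gammas[[m - k + 1]]
    gammas[[m + 1]] <- gm
    q <- m
    if (max(abs(gm)) < decay_tol * g0max) break
  }
  G <- array(0, dim = c(n, n, q + 1))
  for (k in 0:q) G[, , k + 1] <- gammas[[k + 1]]
  attr(G, "spectral_radius") <- rho
  attr(G, "lags_used") <- q
  attr(G, "gamma0_min_eig") <- min(ev)
  G
}

# Transfer function H(lambda) = inv(I - sum_k A_k e^{-i k lambda}) on a
# uniform grid of h points over [0, pi]. Returns complex array n x n x h.
var_transfer <- function(A, h) {
  n <- nrow(A[[1]]); p <- length(A)
  lambdas <- pi * (seq_len(h) - 1) / (h - 1)
  H <- array(complex(real = 0), dim = c(n, n, h))
  for (k in seq_len(h)) {
    M <- diag(n) + 0i
    for (j in seq_len(p)) M <- M - A[[j]] * exp(-1i * j * lambdas[k])
    H[, , k] <- solve(M)
  }
  H
}
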