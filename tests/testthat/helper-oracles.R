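# Independent oracles used across the test files. These deliberately use
# naive double loops and exhaustive enumeration, never the package's own
# vectorized code paths.

# Small random right-censored dataset (distinct times almost surely).
random_survival <- function(n, p, seed, beta = NULL, censor = 0.3) {
  set.seed(seed)
  X <- matrix(runif(n * p, -0.5, 0.5), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- rnorm(p)
  y <- rexp(n, rate = exp(drop(X %*% beta)))
  status <- rep(1, n)
  if (censor > 0) status[sample.int(n, round(censor * n))] <- 0
  list(data = survival_data(y, status, X), beta = beta)
}

# Direct double-loop evaluation of the log partial likelihood (Breslow).
loglik_loop <- function(data, beta) {
  eta <- drop(data$x %*% beta)
  ut <- sort(unique(data$time[data$status == 1]))
  ll <- 0
  for (t_k in ut) {
    events <- which(data$status == 1 & data$time == t_k)
    risk <- which(data$time >= t_k)
    for (i in events) ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Explicit nested-loop evaluation of the IRLS weight/response update,
# generalized to ties through event-time multiplicities.
irls_loop <- function(data, eta, eps_w = 1e-8) {
  n <- length(data$time)
  ut <- sort(unique(data$time[data$status == 1]))
  w <- numeric(n); z <- numeric(n)
  for (i in seq_len(n)) {
    wi <- 0; ai <- 0
    for (t_k in ut[ut <= data$time[i]]) {
      d_k <- sum(data$status == 1 & data$time == t_k)
      S0 <- sum(exp(eta[data$time >= t_k]))
      wi <- wi + d_k * (exp(eta[i]) / S0 - exp(2 * eta[i]) / S0^2)
      ai <- ai + d_k * exp(eta[i]) / S0
    }
    w[i] <- wi
    z[i] <- eta[i] + (data$status[i] - ai) / max(wi, eps_w)
  }
  list(weights = w, responses = z)
}

# Contingency-table loop evaluation of normalized mutual information.
nmi_loop <- function(a, b) {
  p <- length(a)
  ca <- unique(a); cb <- unique(b)
  I <- 0
  for (i in ca) for (j in cb) {
    nij <- sum(a == i & b == j)
    if (nij > 0)
      I <- I + nij / p * log(p * nij / (sum(a == i) * sum(b == j)))
  }
  H <- function(lab) {
    q <- table(lab) / p
    -sum(q * log(q))
  }
  ha <- H(a); hb <- H(b)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  I / ((ha + hb) / 2)
}

# Weighted least squares objective of the fused subproblem (no penalty term).
wls_objective <- function(X, z, w, beta) {
  0.5 * sum(w / nrow(X) * (z - drop(X %*% beta))^2)
}

# Best exhaustive contiguous-break clustering refit of the WLS subproblem:
# enumerate all ways to place `breaks` cluster boundaries along the tau
# order, refit each pattern by collapsed-design WLS, return the minimal
# objective value.
best_pattern_wls <- function(X, z, w, tau, breaks) {
  p <- ncol(X)
  combos <- utils::combn(p - 1, breaks, simplify = FALSE)
  best <- Inf
  for (br in combos) {
    seg <- cumsum(c(1, as.integer(seq_len(p - 1) %in% br)))
    M <- matrix(0, p, max(seg))
    M[cbind(tau, seg)] <- 1
    Xc <- X %*% M
    W <- w / nrow(X)
    A <- crossprod(Xc, Xc * W)
    theta <- solve(A + diag(1e-12, ncol(A)), crossprod(Xc, W * z))
    beta <- drop(M %*% theta)
    best <- min(best, wls_objective(X, z, w, beta))
  }
  best
}

# Best exhaustive contiguous-break pattern for the Cox objective -l/n:
# each pattern refit by an unpenalized Cox fit on the collapsed design.
best_pattern_cox <- function(data, tau, breaks) {
  p <- ncol(data$x)
  combos <- utils::combn(p - 1, breaks, simplify = FALSE)
  best <- Inf
  for (br in combos) {
    seg <- cumsum(c(1, as.integer(seq_len(p - 1) %in% br)))
    M <- matrix(0, p, max(seg))
    M[cbind(tau, seg)] <- 1
    collapsed <- survival_data(data$time, data$status, data$x %*% M)
    theta <- fit_cox(collapsed)
    best <- min(best, -log_partial_likelihood(collapsed, theta) / length(data$time))
  }
  best
}
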