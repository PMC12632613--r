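# Cox partial-likelihood machinery: log-likelihood, gradient, the IRLS
# weight/working-response updates, and an unpenalized Newton/IRLS fitter.
# Ties are handled by the Breslow convention throughout, which reduces to the
# untied formulas when all event times are distinct.

# Precompute the risk-set bookkeeping shared by all evaluations on one
# dataset: ascending time order, unique event times, event multiplicities,
# and for each subject the number of event times at or before its own time
# (the index set C_i = {k : t_k <= y_i}).
cox_structure <- function(data) {
  time <- data$time
  status <- data$status
  if (sum(status) < 1) stop("no events in dataset", call. = FALSE)
  ord <- order(time)
  t_sorted <- time[ord]
  ev_times <- time[status == 1]
  ut <- sort(unique(ev_times))
  d <- as.numeric(table(factor(ev_times, levels = ut)))
  # first position of each unique event time in the ascending-sorted times;
  # the risk set R_k is everything from that position on
  first_idx <- match(ut, t_sorted)
  # per subject, |C_i| = number of unique event times <= y_i
  n_at_risk_events <- findInterval(time, ut)
  list(ord = ord, ut = ut, d = d, first_idx = first_idx,
       ci_count = n_at_risk_events, m = length(ut))
}

# Risk-set sums on the exp scale, computed with a max-shift for stability.
# Returns per-event-time S0_k = sum_{j in R_k} exp(eta_j - shift) and the
# per-subject cumulative sums over C_i of d_k/S0_k and d_k/S0_k^2
# (both on the shifted scale, which is all the callers need: every use is a
# ratio exp(eta_i - shift)/S0_k).
cox_risk_sums <- function(str, eta) {
  shift <- max(eta)
  e <- exp(eta - shift)
  e_sorted <- e[str$ord]
  tail_sum <- rev(cumsum(rev(e_sorted)))
  S0 <- tail_sum[str$first_idx]
  cumA <- cumsum(str$d / S0)       # sum_{k <= K} d_k / S0_k
  cumB <- cumsum(str$d / S0^2)
  list(shift = shift, e = e, S0 = S0, cumA = c(0, cumA), cumB = c(0, cumB))
}

#' Cox log partial likelihood
#'
#' Evaluates the Breslow log partial likelihood
#' \deqn{\ell(\beta) = \sum_{k} \left[ s_k^\top\beta - d_k \log
#'   \sum_{j \in R_k} e^{x_j^\top \beta} \right],}
#' summing over unique event times with multiplicities \eqn{d_k}, where
#' \eqn{s_k} is the covariate sum over the events at time \eqn{t_k} and
#' \eqn{R_k} the at-risk set. With distinct event times this is the ordinary
#' untied partial likelihood. Risk-set sums use a max-shifted exponential for
#' numerical stability.
#'
#' @param data a [survival_data] object.
#' @param beta numeric coefficient vector of length `ncol(data$x)`.
#' @return The log partial likelihood, a single number.
#' @export
log_partial_likelihood <- function(data, beta) {
  stopifnot(inherits(data, "survival_data"))
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$x))
    stop("beta has wrong length", call. = FALSE)
  if (any(!is.finite(beta)))
    stop("beta must be finite", call. = FALSE)
  str <- cox_structure(data)
  eta <- drop(data$x %*% beta)
  rs <- cox_risk_sums(str, eta)
  sum(eta[data$status == 1]) - sum(str$d * (log(rs$S0) + rs$shift))
}

# Gradient of the log partial likelihood with respect to beta.
cox_gradient <- function(data, beta) {
  str <- cox_structure(data)
  eta <- drop(data$x %*% beta)
  rs <- cox_risk_sums(str, eta)
  g_eta <- data$status - rs$e * rs$cumA[str$ci_count + 1L]
  drop(crossprod(data$x, g_eta))
}

# Gradient and exact (negated) Hessian of the log partial likelihood:
#   -H = X' diag(a) X - sum_k d_k u_k u_k',  u_k = S1_k / S0_k,
# with a_i = e^{eta_i} sum_{k in C_i} d_k / S0_k and S1_k the risk-set sum
# of e^eta x. The low-rank part is assembled as a crossprod over the m
# event times, so the whole evaluation is O(np^2).
cox_grad_neghess <- function(data, eta, str = cox_structure(data)) {
  X <- data$x
  rs <- cox_risk_sums(str, eta)
  a <- rs$e * rs$cumA[str$ci_count + 1L]
  g <- drop(crossprod(X, data$status - a))
  n <- nrow(X)
  eX <- X[str$ord, , drop = FALSE] * rs$e[str$ord]
  # per-column tail sums: S1[j, ] = sum over subjects with time >= t_sorted[j]
  S1 <- apply(eX[n:1, , drop = FALSE], 2, cumsum)
  S1 <- matrix(S1, nrow = n)[n:1, , drop = FALSE][str$first_idx, , drop = FALSE]
  V <- (S1 / rs$S0) * sqrt(str$d)
  negH <- crossprod(X, X * a) - crossprod(V)
  list(grad = g, neghess = negH)
}

#' IRLS weights and working responses for the penalized Cox model
#'
#' One quadratic-expansion step of the iteratively reweighted least squares
#' scheme: given the current linear predictor \eqn{\tilde\eta}, computes the
#' per-subject weight
#' \deqn{w_i = \sum_{k \in C_i} d_k\left[ \frac{e^{\tilde\eta_i}}{\sum_{j \in R_k}
#'   e^{\tilde\eta_j}} - \frac{e^{2\tilde\eta_i}}{(\sum_{j \in R_k}
#'   e^{\tilde\eta_j})^2} \right]}
#' and working response
#' \deqn{z_i = \tilde\eta_i + \frac{1}{w_i}\left( \delta_i - \sum_{k \in C_i}
#'   d_k \frac{e^{\tilde\eta_i}}{\sum_{j \in R_k} e^{\tilde\eta_j}} \right),}
#' where \eqn{C_i} indexes the event times at which subject \eqn{i} is still
#' at risk (multiplicities \eqn{d_k} handle Breslow ties; all \eqn{d_k = 1}
#' without ties). \eqn{-w} is the diagonal of the Hessian of the log partial
#' likelihood in \eqn{\eta}, and \eqn{w_i(z_i-\tilde\eta_i)} its gradient.
#' Weights below the floor `eps_w` give `z_i` equal to `eta_i` and should be
#' assigned working weight 0 downstream; a subject at risk for no event time
#' has exactly `w_i = 0` and `z_i = eta_i`.
#'
#' @param data a [survival_data] object.
#' @param eta numeric vector: current linear predictor, length `n`.
#' @param eps_w weight floor used when dividing by `w_i` (default `1e-8`).
#' @return A list with components `eta`, `weights` (`w`) and `responses` (`z`).
#' @export
irls_update <- function(data, eta, eps_w = 1e-8) {
  stopifnot(inherits(data, "survival_data"))
  eta <- as.numeric(eta)
  if (length(eta) != length(data$time) || any(!is.finite(eta)))
    stop("eta must be finite and of length n", call. = FALSE)
  str <- cox_structure(data)
  rs <- cox_risk_sums(str, eta)
  a_i <- rs$e * rs$cumA[str$ci_count + 1L]        # sum_k d_k e^eta_i / S0_k
  b_i <- rs$e^2 * rs$cumB[str$ci_count + 1L]      # sum_k d_k e^2eta_i / S0_k^2
  w <- a_i - b_i
  w <- pmax(w, 0)                                  # clip tiny negative rounding
  z <- eta + (data$status - a_i) / pmax(w, eps_w)
  list(eta = eta, weights = w, responses = z)
}

#' Fit an unpenalized Cox proportional hazards model
#'
#' Newton-type maximizer of the (optionally ridge-penalized) Breslow log
#' partial likelihood, \eqn{\ell(\beta) - (\mathrm{ridge}/2)\|\beta\|^2},
#' implemented as IRLS with the diagonal weight approximation of
#' [irls_update()] and step halving to guarantee monotone ascent. Used for
#' the preliminary estimate that seeds the coefficient ranking, and by the
#' transfer step on the source cohort. If the unpenalized fit diverges
#' (coefficients grow without bound, as under monotone likelihood), the fit
#' is retried once with `ridge = 1e-4` and a warning.
#'
#' @param data a [survival_data] object with at least one event.
#' @param ridge nonnegative ridge parameter (default 0).
#' @param init optional starting coefficient vector (default all zeros).
#' @param tol stationarity tolerance: iteration stops when the max-norm of
#'   the objective gradient falls below `tol` (default 1e-7) or the
#'   objective change stalls below 1e-12.
#' @param max_iter maximum IRLS iterations (default 200).
#' @return Numeric coefficient vector of length `p`, with names taken from
#'   the covariate columns.
#' @examples
#' set.seed(1)
#' sim <- generate_target(scenario_config(n_target = 100, p = 6, seed = 1))
#' fit_cox(sim$data)
#' @export
fit_cox <- function(data, ridge = 0, init = NULL, tol = 1e-7, max_iter = 200L) {
  stopifnot(inherits(data, "survival_data"), ridge >= 0)
  p <- ncol(data$x)
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  res <- try(cox_newton(data, beta, ridge, tol, max_iter), silent = TRUE)
  if (inherits(res, "try-error") && ridge == 0) {
    warning("unpenalized Cox fit diverged; retrying with ridge = 1e-4",
            call. = FALSE)
    res <- cox_newton(data, beta, 1e-4, tol, max_iter)
  } else if (inherits(res, "try-error")) {
    stop(attr(res, "condition")$message, call. = FALSE)
  }
  stats::setNames(res, colnames(data$x))
}

cox_newton <- function(data, beta, ridge, tol, max_iter) {
  X <- data$x
  str <- cox_structure(data)
  obj <- function(b) log_partial_likelihood(data, b) - ridge / 2 * sum(b^2)
  f <- obj(beta)
  cap <- 1e3   # coefficient magnitude treated as divergence
  for (it in seq_len(max_iter)) {
    gh <- cox_grad_neghess(data, drop(X %*% beta), str)
    grad <- gh$grad - ridge * beta
    if (max(abs(grad)) < tol) break
    H <- gh$neghess
    diag(H) <- diag(H) + ridge + 1e-10
    dir <- drop(solve(H, grad))
    # step halving for monotone ascent
    step <- 1
    beta_new <- beta + dir
    f_new <- obj(beta_new)
    halvings <- 0L
    while ((!is.finite(f_new) || f_new < f) && halvings < 20L) {
      step <- step / 2
      beta_new <- beta + step * dir
      f_new <- obj(beta_new)
      halvings <- halvings + 1L
    }
    if (!is.finite(f_new) || max(abs(beta_new)) > cap)
      stop("Cox fit diverged", call. = FALSE)
    beta <- beta_new
    f <- f_new
  }
  if (max(abs(beta)) > cap) stop("Cox fit diverged", call. = FALSE)
  beta
}
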