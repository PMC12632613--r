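# Survival-based clustering of predictors: the outer IRLS loop around the
# fusion-penalized weighted least squares subproblem, cluster extraction,
# and BIC selection of the sparsity level.

#' Survival-based clustering of predictors
#'
#' Fits a fusion-penalized Cox proportional hazards model that drives the
#' regression coefficients into homogeneous clusters. A preliminary
#' unpenalized Cox fit provides a ranking \eqn{\tau} of the coefficients; the
#' penalty then acts on the differences of rank-adjacent coefficients
#' \eqn{D_\tau\beta}, so that zero differences fuse coefficients into shared
#' values. With the default distance-to-set penalty the tuning parameter is
#' the integer number of allowed nonzero differences `k` (at most `k + 1`
#' clusters); when `k` is a vector the sparsity level is selected by BIC,
#' \eqn{-2\ell(\hat\beta) + \mathrm{df}\,\log(\#\mathrm{events})} with
#' df = number of clusters plus unpenalized columns. Covariates declared
#' `unpenalized` in the dataset are estimated freely and never fused.
#'
#' @param data a [survival_data] object.
#' @param k integer vector of candidate sparsity levels (distance family);
#'   default `1:5`.
#' @param family penalty family: `"distance"` (default), `"lasso"`,
#'   `"scad"`, or `"mcp"`.
#' @param lambda penalty level(s) for the shrinkage families; ignored for
#'   `"distance"`.
#' @param tau optional externally supplied rank mapping over the penalized
#'   columns (an integer permutation); when absent it is built from the
#'   preliminary Cox fit. The transfer-learning front end [tlscp()] supplies
#'   a merged source/target ranking here.
#' @param control list of solver settings from [scp_control()].
#' @return An object of class `"scp"`; see [print.scp()], [summary.scp()],
#'   [coef.scp()], [predict.scp()], [plot.scp()], [residuals.scp()].
#' @examples
#' sim <- generate_target(scenario_config(n_target = 150, p = 9, seed = 7))
#' fit <- scp(sim$data, k = 2)
#' fit
#' @seealso [tlscp()] for the transfer-learning variant, [cox_kmeans()] for
#'   the naive baseline.
#' @export
scp <- function(data, k = 1:5, family = "distance", lambda = NULL,
                tau = NULL, control = scp_control()) {
  stopifnot(inherits(data, "survival_data"))
  pen <- penalized_cols(data)
  if (length(pen) < 2L)
    stop("need at least two penalized covariates to cluster", call. = FALSE)
  specs <- if (family == "distance") {
    k <- sort(unique(as.integer(k)), decreasing = TRUE)  # warm-start path
    lapply(k, function(kk) penalty_spec("distance", k = kk,
                                        lambda0 = control$lambda0,
                                        schedule_growth = control$schedule_growth,
                                        lambda_max = control$lambda_max))
  } else {
    if (is.null(lambda)) stop("shrinkage families require lambda", call. = FALSE)
    lambda <- sort(unique(lambda), decreasing = TRUE)
    lapply(lambda, function(l) penalty_spec(family, lambda = l))
  }
  prelim <- fit_cox(data, ridge = control$prelim_ridge)
  if (is.null(tau)) {
    tau <- build_rank_map(prelim[pen])
  } else {
    tau <- as.integer(tau)
    if (!identical(sort(tau), seq_along(pen)))
      stop("tau is not a permutation of the penalized columns", call. = FALSE)
  }
  fits <- vector("list", length(specs))
  beta_warm <- prelim
  for (i in seq_along(specs)) {
    fits[[i]] <- scp_fit_single(data, specs[[i]], tau, prelim,
                                beta_init = beta_warm, control = control)
    beta_warm <- fits[[i]]$beta
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  tune <- if (family == "distance") k else lambda
  # ties and the argmin both resolve toward the smaller tuning value
  ord <- order(bics, tune)
  best <- fits[[ord[1L]]]
  best$bic_table <- data.frame(
    tuning = tune,
    n_clusters = vapply(fits, function(f) length(f$centers), integer(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    bic = bics,
    converged = vapply(fits, `[[`, logical(1), "converged"))[order(tune), ]
  rownames(best$bic_table) <- NULL
  best$call <- match.call()
  best
}

#' Solver settings for [scp()]
#'
#' @param max_outer maximum outer IRLS iterations (default 50).
#' @param tol convergence tolerance on the max absolute coefficient change
#'   between outer iterations (default 1e-6).
#' @param cluster_tol gap beyond which two rank-adjacent coefficients are
#'   considered distinct when extracting clusters (default 1e-6; after the
#'   terminal collapsed refit within-cluster coefficients are exactly equal,
#'   so this only guards floating-point noise).
#' @param lambda0,schedule_growth,lambda_max proximal-distance multiplier
#'   schedule, see [penalty_spec()].
#' @param prelim_ridge ridge applied to the preliminary Cox fit (default 0;
#'   a diverging preliminary fit falls back to 1e-4 automatically).
#' @return A named list of settings.
#' @export
scp_control <- function(max_outer = 50L, tol = 1e-6, cluster_tol = 1e-6,
                        lambda0 = 1, schedule_growth = 1.2, lambda_max = 1e8,
                        prelim_ridge = 0) {
  list(max_outer = as.integer(max_outer), tol = tol, cluster_tol = cluster_tol,
       lambda0 = lambda0, schedule_growth = schedule_growth,
       lambda_max = lambda_max, prelim_ridge = prelim_ridge)
}

# One fit at a fixed penalty specification: Algorithm-style outer IRLS loop
# calling the fused WLS solver, then cluster extraction and BIC.
scp_fit_single <- function(data, spec, tau, prelim, beta_init = NULL,
                           control = scp_control()) {
  X <- data$x
  pen <- penalized_cols(data)
  D <- build_fusion_matrix(tau)
  beta <- if (is.null(beta_init)) prelim else beta_init
  trace <- numeric(0)
  converged <- FALSE
  prev_obj <- Inf
  # phase 1: the IRLS loop around the proximal-distance (or shrinkage)
  # subproblem solver, iterated until the coefficients or the objective
  # settle (near-tied fusion patterns can alternate while the fit itself no
  # longer improves)
  for (it in seq_len(control$max_outer)) {
    ws <- irls_update(data, drop(X %*% beta))
    w <- ws$weights
    w[w < 1e-8] <- 0
    beta_new <- solve_fused_wls(X, ws$responses, w, D, spec,
                                beta_init = beta, pen_idx = pen,
                                polish = FALSE)
    delta <- max(abs(beta_new - beta))
    beta <- as.numeric(beta_new)
    obj <- -log_partial_likelihood(data, beta) / nrow(X)
    trace <- c(trace, obj)
    if (delta < control$tol || abs(obj - prev_obj) < 1e-10) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
  }
  # phase 2 (distance family): alternate a discrete exchange search over
  # fusion-break positions on the current working quadratic with an exact
  # Newton refit of the collapsed (cluster-constant) Cox model, until the
  # pattern and coefficients are stable
  if (spec$family == "distance") {
    for (it in seq_len(control$max_outer)) {
      ws <- irls_update(data, drop(X %*% beta))
      w <- ws$weights
      w[w < 1e-8] <- 0
      beta_pat <- solve_fused_wls(X, ws$responses, w, D, spec,
                                  beta_init = beta, pen_idx = pen,
                                  polish = TRUE, schedule = FALSE)
      cl <- extract_clusters(beta_pat[pen], tau, tol = control$cluster_tol)
      g <- length(cl$centers)
      M <- matrix(0, ncol(X), g + length(data$unpenalized))
      M[cbind(pen, cl$labels)] <- 1
      if (length(data$unpenalized))
        M[cbind(data$unpenalized, g + seq_along(data$unpenalized))] <- 1
      collapsed <- survival_data(data$time, data$status, X %*% M)
      theta <- fit_cox(collapsed,
                       init = c(cl$centers, beta_pat[data$unpenalized]))
      beta_new <- drop(M %*% theta)
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      obj <- -log_partial_likelihood(data, beta) / nrow(X)
      trace <- c(trace, obj)
      if (delta < control$tol || abs(obj - prev_obj) < 1e-12) {
        converged <- TRUE
        break
      }
      converged <- FALSE
      prev_obj <- obj
    }
  }
  names(beta) <- colnames(X)
  cl <- extract_clusters(beta[pen], tau, tol = control$cluster_tol)
  loglik <- log_partial_likelihood(data, beta)
  df <- length(cl$centers) + length(data$unpenalized)
  n_events <- sum(data$status == 1)
  structure(list(beta = beta, labels = cl$labels, centers = cl$centers,
                 k_used = spec$k, lambda_used = spec$lambda,
                 family = spec$family, loglik = loglik, df = df,
                 bic = -2 * loglik + df * log(n_events),
                 converged = converged, tau = tau, prelim = prelim,
                 trace = trace, n = nrow(X), p = ncol(X),
                 n_events = n_events, penalized = pen,
                 unpenalized = data$unpenalized,
                 feature_names = colnames(X)),
            class = "scp")
}

#' Extract coefficient clusters along the rank order
#'
#' Walks the coefficients in the order given by `tau` and opens a new cluster
#' whenever the gap to the previous coefficient exceeds `tol`. Cluster labels
#' are numbered 1, 2, ... from the smallest coefficient upward; centers are
#' the within-cluster means (exact shared values when the fit has been refit
#' on the collapsed design).
#'
#' @param beta_pen coefficients of the penalized columns.
#' @param tau rank mapping over those columns.
#' @param tol gap threshold separating clusters.
#' @return List with `labels` (integer vector aligned with `beta_pen`) and
#'   `centers` (one value per cluster).
#' @export
extract_clusters <- function(beta_pen, tau, tol = 1e-6) {
  b_sorted <- beta_pen[tau]
  new_cluster <- c(TRUE, abs(diff(b_sorted)) > tol)
  seg <- cumsum(new_cluster)
  labels <- integer(length(beta_pen))
  labels[tau] <- seg
  centers <- as.numeric(tapply(b_sorted, seg, mean))
  if (!is.null(names(beta_pen))) names(labels) <- names(beta_pen)
  list(labels = labels, centers = centers)
}
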