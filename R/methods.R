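# S3 methods for fitted "scp" objects.

#' @export
print.scp <- function(x, ...) {
  kind <- if (inherits(x, "tlscp")) "Transfer-learning survival-based" else "Survival-based"
  cat(kind, "clustering of predictors\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("  n = %d (%d events), p = %d (%d penalized)\n",
              x$n, x$n_events, x$p, length(x$penalized)))
  tune <- if (x$family == "distance") sprintf("k = %d", x$k_used)
          else sprintf("%s, lambda = %g", x$family, x$lambda_used)
  cat(sprintf("  penalty: %s; clusters found: %d\n", tune, length(x$centers)))
  cat(sprintf("  log partial likelihood = %.4f, BIC = %.4f%s\n",
              x$loglik, x$bic, if (x$converged) "" else "  (not converged)"))
  cat("  cluster centers:", paste(sprintf("%.4f", x$centers), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted predictor-clustering model
#'
#' @param object a fitted [scp()] or [tlscp()] object.
#' @param ... unused.
#' @return An object of class `"summary.scp"` with the per-cluster membership
#'   table and, when a tuning grid was used, the BIC table.
#' @export
summary.scp <- function(object, ...) {
  members <- split(object$feature_names[object$penalized], object$labels)
  out <- list(fit = object,
              clusters = data.frame(
                cluster = seq_along(object$centers),
                center = object$centers,
                size = as.integer(table(object$labels))),
              members = members,
              bic_table = object$bic_table)
  class(out) <- "summary.scp"
  out
}

#' @export
print.summary.scp <- function(x, ...) {
  print(x$fit)
  cat("\nClusters (by increasing rank position):\n")
  print(x$clusters, row.names = FALSE)
  for (i in seq_along(x$members)) {
    cat(sprintf("  cluster %s: %s\n", names(x$members)[i],
                paste(x$members[[i]], collapse = ", ")))
  }
  if (!is.null(x$bic_table)) {
    cat("\nTuning path:\n")
    print(x$bic_table, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.scp <- function(object, ...) object$beta

#' @export
logLik.scp <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' Predictions from a fitted predictor-clustering model
#'
#' @param object a fitted [scp()] object.
#' @param newdata a covariate matrix, data frame, or [survival_data] object;
#'   defaults to nothing (an error), since the fit does not retain the
#'   training covariates.
#' @param type `"lp"` for the linear predictor \eqn{x^\top\hat\beta} or
#'   `"risk"` for the relative hazard \eqn{e^{x^\top\hat\beta}}.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.scp <- function(object, newdata, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "survival_data")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata must have ", object$p, " columns", call. = FALSE)
  lp <- drop(newdata %*% object$beta)
  if (type == "risk") exp(lp) else lp
}

#' Martingale residuals for a fitted predictor-clustering model
#'
#' Computes \eqn{\delta_i - \hat\Lambda_0(y_i) e^{x_i^\top\hat\beta}} with the
#' Breslow estimate of the cumulative baseline hazard.
#'
#' @param object a fitted [scp()] object.
#' @param data the [survival_data] the model was fitted to.
#' @param ... unused.
#' @return Numeric vector of martingale residuals.
#' @export
residuals.scp <- function(object, data, ...) {
  stopifnot(inherits(data, "survival_data"))
  str <- cox_structure(data)
  eta <- drop(data$x %*% object$beta)
  rs <- cox_risk_sums(str, eta)
  # Breslow cumulative hazard at y_i on the shifted scale cancels the shift
  # through e = exp(eta - shift)
  data$status - rs$e * rs$cumA[str$ci_count + 1L]
}

#' Plot the clustered coefficient profile
#'
#' Draws the fitted coefficients in rank order, colored by cluster, with the
#' preliminary (unpenalized Cox) estimates overlaid for reference.
#'
#' @param x a fitted [scp()] object.
#' @param show_prelim overlay the preliminary estimates (default `TRUE`).
#' @param ... further arguments passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.scp <- function(x, show_prelim = TRUE, ...) {
  pen <- x$penalized
  b <- x$beta[pen][x$tau]
  lab <- x$labels[x$tau]
  plot(seq_along(b), b, col = lab + 1L, pch = 19,
       xlab = "rank position", ylab = "coefficient",
       main = sprintf("%d coefficient clusters", length(x$centers)), ...)
  if (show_prelim)
    graphics::points(seq_along(b), x$prelim[pen][x$tau], pch = 1, col = "grey50")
  graphics::segments(x0 = seq_along(b) - 0.4, x1 = seq_along(b) + 0.4,
                     y0 = b, col = lab + 1L)
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes the coefficient vector, cluster labels and centers, the selected
#' tuning value, log partial likelihood, BIC, convergence flag and rank map,
#' together with a caller-supplied configuration echo and seed, to a JSON
#' file. Used by the command-line interface; readable back with
#' [jsonlite::read_json()].
#'
#' @param fit a fitted [scp()] object.
#' @param path output path.
#' @param config named list echoed verbatim into the artifact.
#' @param seed seed to record (may be `NULL`).
#' @return Invisibly, the path.
#' @export
write_scp_json <- function(fit, path, config = list(), seed = NULL) {
  obj <- list(
    tool = "tlscp",
    version = as.character(utils::packageVersion("tlscp")),
    seed = seed,
    config = config,
    beta = as.list(fit$beta),
    labels = stats::setNames(as.list(fit$labels), fit$feature_names[fit$penalized]),
    centers = fit$centers,
    k = fit$k_used,
    lambda = fit$lambda_used,
    family = fit$family,
    n_clusters = length(fit$centers),
    loglik = fit$loglik,
    bic = fit$bic,
    converged = fit$converged,
    tau = fit$tau)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
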