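# Transfer learning for predictor clustering: merge the coefficient rankings
# of a large source cohort and a small target cohort by weighted rank
# averaging, then run the fusion-penalized fit on the target with the merged
# ranking. Only the source ranking (or coefficients) is needed, never
# individual-level source data, so the source side can be summary-level.

#' Merge two coefficient rankings by weighted rank averaging
#'
#' Given the rank vectors of the source and target preliminary coefficient
#' estimates (rank 1 = smallest coefficient, ties by first occurrence),
#' computes per-feature scores
#' \eqn{s_j = w_{S,j}\,\mathrm{rank}_S(j) + w_{T,j}\,\mathrm{rank}_T(j)} and
#' returns the permutation ordering the scores ascendingly, with score ties
#' broken by the lower feature index. The result is invariant to a common
#' positive rescaling of both weight vectors.
#'
#' @param rank_source,rank_target integer permutations of `1:p`: the ranks of
#'   the source and target coefficient estimates.
#' @param w_source,w_target nonnegative scalar or length-`p` weights;
#'   elementwise `w_source + w_target` must be positive. Scalar sample-size
#'   weights \eqn{n_S/(n_S+n_T)} and \eqn{n_T/(n_S+n_T)} are the default
#'   choice in [tlscp()]; per-feature weights (e.g. carrier counts
#'   \eqn{n_{T j}/(n_{T j}+n_{S j})}) are supported by passing vectors.
#' @return Integer permutation: the merged rank mapping \eqn{\tau}.
#' @examples
#' weighted_rank_average(1:3, 3:1, 0.5, 0.5)  # ties -> index order 1 2 3
#' @export
weighted_rank_average <- function(rank_source, rank_target,
                                  w_source, w_target) {
  p <- length(rank_source)
  check_perm <- function(r, what) {
    if (!identical(sort(as.integer(r)), seq_len(p)))
      stop(what, " is not a permutation of 1:", p, call. = FALSE)
  }
  check_perm(rank_source, "rank_source")
  if (length(rank_target) != p)
    stop("rank vectors differ in length", call. = FALSE)
  check_perm(rank_target, "rank_target")
  w_source <- rep_len(as.numeric(w_source), p)
  w_target <- rep_len(as.numeric(w_target), p)
  if (any(w_source < 0) || any(w_target < 0) || any(w_source + w_target <= 0))
    stop("weights must be nonnegative with positive elementwise sum", call. = FALSE)
  score <- w_source * rank_source + w_target * rank_target
  order(score)  # stable: score ties resolved by lower feature index
}

#' Transfer-learning survival-based clustering of predictors
#'
#' Runs [scp()] on the target cohort with a rank mapping merged from the
#' source and target cohorts. Both cohorts are fitted by unpenalized Cox
#' regression (the source fit may be replaced by externally supplied source
#' coefficients or ranks when individual-level data cannot be shared); the
#' two coefficient rankings are combined by [weighted_rank_average()], and
#' the merged ranking defines the fusion matrix for the penalized target
#' fit. Only ranking information crosses cohorts — source coefficient
#' magnitudes never enter the target fit — reflecting the working assumption
#' that the cohorts share a similar ordering of covariate effects, which is
#' weaker than similarity of the effects themselves.
#'
#' When the target's penalized covariates are a subset of the source's
#' (matched by column name), the source coefficients are restricted to the
#' overlap and re-ranked before merging.
#'
#' @param target a [survival_data] object: the (small) cohort of interest.
#' @param source either a [survival_data] object, or a named numeric vector
#'   of source coefficient estimates, or `NULL` if `source_ranks` is given.
#' @param source_ranks optional named integer vector of precomputed source
#'   ranks (rank 1 = smallest coefficient) over the penalized covariates.
#' @param weights `"auto"` for scalar sample-size ratios
#'   \eqn{w_S = n_S/(n_S+n_T)}, \eqn{w_T = n_T/(n_S+n_T)} (requires a
#'   source dataset or `n_source`), or a list with elements `source` and
#'   `target` (scalars or per-feature vectors).
#' @param n_source source sample size, needed for `"auto"` weights when the
#'   source is supplied as coefficients or ranks.
#' @param k,family,lambda,control passed to [scp()].
#' @return An object of class `c("tlscp", "scp")`, with additional fields
#'   `rank_source`, `rank_target` and `weights`.
#' @examples
#' cfg <- scenario_config(n_target = 150, n_source = 600, p = 9, seed = 11)
#' tgt <- generate_target(cfg)
#' src <- generate_source(cfg, tgt$beta)
#' fit <- tlscp(tgt$data, src$data, k = 2)
#' fit
#' @export
tlscp <- function(target, source = NULL, source_ranks = NULL,
                  weights = "auto", n_source = NULL,
                  k = 1:5, family = "distance", lambda = NULL,
                  control = scp_control()) {
  stopifnot(inherits(target, "survival_data"))
  pen <- penalized_cols(target)
  pen_names <- colnames(target$x)[pen]
  p_pen <- length(pen)

  # --- source side: ranks over the target's penalized covariates ---
  if (!is.null(source_ranks)) {
    rank_s <- align_source_ranks(source_ranks, pen_names)
  } else if (inherits(source, "survival_data")) {
    beta_s <- fit_cox(source)
    rank_s <- source_coef_to_ranks(beta_s[penalized_cols(source)], pen_names)
    if (is.null(n_source)) n_source <- length(source$time)
  } else if (is.numeric(source)) {
    rank_s <- source_coef_to_ranks(source, pen_names)
  } else {
    stop("supply a source dataset, source coefficients, or source_ranks",
         call. = FALSE)
  }

  # --- target side ---
  beta_t <- fit_cox(target, ridge = control$prelim_ridge)
  rank_t <- rank(beta_t[pen], ties.method = "first")

  # --- weights ---
  if (identical(weights, "auto")) {
    if (is.null(n_source))
      stop("auto weights need the source sample size (n_source)", call. = FALSE)
    n_t <- length(target$time)
    weights <- list(source = n_source / (n_source + n_t),
                    target = n_t / (n_source + n_t))
  }
  if (!is.list(weights) || !all(c("source", "target") %in% names(weights)))
    stop("weights must be \"auto\" or a list with elements source and target",
         call. = FALSE)

  tau <- weighted_rank_average(rank_s, rank_t,
                               weights$source, weights$target)
  fit <- scp(target, k = k, family = family, lambda = lambda,
             tau = tau, control = control)
  fit$rank_source <- stats::setNames(as.integer(rank_s), pen_names)
  fit$rank_target <- stats::setNames(as.integer(rank_t), pen_names)
  fit$weights <- weights
  fit$call <- match.call()
  class(fit) <- c("tlscp", class(fit))
  fit
}

# Ranks of source coefficients restricted to the target's penalized
# covariates; when names are available on both sides the overlap is taken by
# name and re-ranked, otherwise lengths must agree.
source_coef_to_ranks <- function(beta_s, pen_names) {
  if (!is.null(names(beta_s)) && all(pen_names %in% names(beta_s))) {
    beta_s <- beta_s[pen_names]
  } else if (length(beta_s) != length(pen_names)) {
    stop("source covariates do not cover the target's penalized covariates",
         call. = FALSE)
  }
  rank(as.numeric(beta_s), ties.method = "first")
}

align_source_ranks <- function(source_ranks, pen_names) {
  r <- source_ranks
  if (anyDuplicated(r))
    stop("source_ranks contains duplicate ranks", call. = FALSE)
  if (!is.null(names(r))) {
    miss <- setdiff(pen_names, names(r))
    if (length(miss))
      stop("source_ranks missing feature(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    r <- r[pen_names]
    # restrict to overlap, then re-rank so it is a permutation of 1:p_pen
    r <- rank(as.numeric(r), ties.method = "first")
  }
  r <- as.integer(r)
  if (!identical(sort(r), seq_along(pen_names)))
    stop("source_ranks is not a valid ranking of the penalized covariates",
         call. = FALSE)
  r
}
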