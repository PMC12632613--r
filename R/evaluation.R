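# Evaluation metrics for recovered predictor clusterings, and the naive
# Cox-regression-plus-k-means baseline.

#' Normalized mutual information between two partitions
#'
#' \deqn{\mathrm{NMI}(\mathcal C, \mathcal D) =
#'   \frac{I(\mathcal C, \mathcal D)}{[H(\mathcal C) + H(\mathcal D)]/2}}
#' with mutual information
#' \eqn{I = \sum_{ij} \frac{|C_i \cap D_j|}{p}
#'   \log\frac{p\,|C_i \cap D_j|}{|C_i||D_j|}} and entropy
#' \eqn{H(\mathcal C) = -\sum_i \frac{|C_i|}{p}\log\frac{|C_i|}{p}} (natural
#' logarithm; the base cancels). Takes values in \eqn{[0,1]}, is symmetric,
#' and is invariant to relabeling. Degenerate cases: if both partitions are
#' single-cluster (both entropies zero) the partitions are identical and the
#' value is 1; if exactly one entropy is zero the value is 0.
#'
#' @param part_a,part_b cluster label vectors over the same index set (any
#'   atomic type; labels are compared within each vector only).
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition, relabeled
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: independent
#' @export
nmi <- function(part_a, part_b) {
  p <- length(part_a)
  if (length(part_b) != p)
    stop("partitions must label the same index set", call. = FALSE)
  if (p == 0L) stop("empty partitions", call. = FALSE)
  tab <- table(part_a, part_b)
  joint <- tab / p
  pa <- rowSums(joint)
  pb <- colSums(joint)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ha <- H(pa); hb <- H(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  outer_pq <- outer(pa, pb)
  nz <- joint > 0
  I <- sum(joint[nz] * log(joint[nz] / outer_pq[nz]))
  I / ((ha + hb) / 2)
}

#' Relative squared estimation error
#'
#' \eqn{\|\hat\beta - \beta^*\|_2^2 / \|\beta^*\|_2^2}.
#'
#' @param beta_hat estimated coefficient vector.
#' @param beta_true true coefficient vector (not all zero).
#' @return A nonnegative number.
#' @export
rel_err <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true))
    stop("coefficient vectors differ in length", call. = FALSE)
  denom <- sum(beta_true^2)
  if (denom == 0) stop("beta_true must not be all zero", call. = FALSE)
  sum((beta_hat - beta_true)^2) / denom
}

#' Cox-regression-plus-k-means baseline clustering
#'
#' The naive comparator: fit an unpenalized Cox model, then run 1-D k-means
#' on the (penalized) coefficient estimates for each candidate cluster count
#' and keep the count maximizing the average silhouette width (Euclidean
#' distance, ties toward fewer clusters). This baseline does not produce
#' homogeneous coefficients; it only partitions the raw estimates.
#'
#' @param data a [survival_data] object.
#' @param k_candidates integer candidates for the number of clusters
#'   (default `2:5`; silhouette is undefined at 1, so a single cluster is
#'   returned only when all coefficients agree to within 1e-8).
#' @param restarts k-means restarts per candidate (default 10).
#' @param seed optional seed for the k-means restarts, making the baseline
#'   reproducible.
#' @return List with `labels` (over the penalized covariates), `k`,
#'   `silhouette` (average width per candidate), and `beta` (the unpenalized
#'   Cox coefficients, all columns).
#' @export
cox_kmeans <- function(data, k_candidates = 2:5, restarts = 10L, seed = NULL) {
  stopifnot(inherits(data, "survival_data"))
  if (!is.null(seed)) set.seed(seed)
  beta <- fit_cox(data)
  pen <- penalized_cols(data)
  b <- beta[pen]
  if (max(b) - min(b) < 1e-8) {
    return(list(labels = stats::setNames(rep(1L, length(b)), names(b)),
                k = 1L, silhouette = NULL, beta = beta))
  }
  sel <- kmeans_silhouette(b, k_candidates, restarts, names(b))
  c(sel, list(beta = beta))
}

# 1-D k-means over candidate cluster counts, choosing the count that
# maximizes the average silhouette width (first maximum -> smaller k).
kmeans_silhouette <- function(values, k_candidates, restarts, names = NULL) {
  k_candidates <- k_candidates[k_candidates >= 2 &
                               k_candidates <= length(unique(values))]
  if (!length(k_candidates))
    stop("no admissible candidate cluster counts", call. = FALSE)
  dmat <- stats::dist(values)
  sil <- numeric(length(k_candidates))
  fits <- vector("list", length(k_candidates))
  for (i in seq_along(k_candidates)) {
    km <- stats::kmeans(matrix(values, ncol = 1), centers = k_candidates[i],
                        nstart = restarts)
    fits[[i]] <- km
    sil[i] <- mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
  }
  best <- which.max(sil)
  list(labels = stats::setNames(fits[[best]]$cluster, names),
       k = k_candidates[best],
       silhouette = stats::setNames(sil, k_candidates))
}
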