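#' Spectrum similarity: normalized dot product and spectral angle
#'
#' The dot product (DP) is the cosine similarity between two non-negative
#' intensity vectors; the spectral angle loss (SA) is its arccosine scaled
#' to `[0, 1]`:
#' \deqn{SA = \frac{2}{\pi} \arccos \frac{s_1 \cdot s_2}{|s_1||s_2|}}
#' Both metrics perform an inherent L2 normalization, so they are invariant
#' to global intensity scaling. SA = 0 for proportional vectors and 1 for
#' orthogonal ones.
#'
#' @param s1,s2 Non-negative intensity vectors of equal length, not all
#'   zero.
#' @return A number in `[0, 1]`.
#' @examples
#' dot_product(c(1, 1), c(1, 0)) # 1/sqrt(2)
#' spectral_angle(c(1, 2, 3), c(2, 4, 6)) # 0
#' @export
dot_product <- function(s1, s2) {
  stopifnot(length(s1) == length(s2))
  n1 <- sqrt(sum(s1^2)); n2 <- sqrt(sum(s2^2))
  if (n1 == 0 || n2 == 0) {
    stop("dot product undefined for an all-zero intensity vector")
  }
  sum(s1 * s2) / (n1 * n2)
}

#' @rdname dot_product
#' @export
spectral_angle <- function(s1, s2) {
  sa_from_dp(dot_product(s1, s2))
}

#' Convert between spectral angle and dot product
#'
#' The single shared implementation of the SA/DP transform used throughout
#' the package (losses, evaluation, rescoring).
#'
#' @param dp Dot product in `[-1, 1]` (clamped).
#' @param sa Spectral angle in `[0, 1]`.
#' @return `sa_from_dp()`: SA = (2/pi) arccos(DP); `dp_from_sa()`:
#'   DP = cos(SA * pi/2).
#' @export
sa_from_dp <- function(dp) {
  (2 / pi) * acos(pmin(1, pmax(-1, dp)))
}

#' @rdname sa_from_dp
#' @export
dp_from_sa <- function(sa) {
  cos(sa * pi / 2)
}

#' Multi-task total loss
#'
#' Weighted sum of the spectral-angle losses of the whole spectrum, the
#' peptide part and the glycan part, plus the mean squared error of the
#' peptide-fraction ratio; an optional fifth term adds the B-ion spectral
#' angle for the branch-fragment model.
#'
#' @param sa_total,sa_pep,sa_gly,mse_ratio Loss components (>= 0).
#' @param weights Numeric vector of 4 (or 5, with B) non-negative weights.
#' @param sa_B Optional B-ion spectral angle.
#' @return The scalar total loss.
#' @export
total_loss <- function(sa_total, sa_pep, sa_gly, mse_ratio,
                       weights = rep(1, if (is.null(sa_B)) 4 else 5),
                       sa_B = NULL) {
  comps <- c(sa_total, sa_pep, sa_gly, mse_ratio, sa_B)
  stopifnot(length(weights) == length(comps), all(weights >= 0))
  sum(weights * comps)
}

#' Dynamic weight average for multi-task loss balancing
#'
#' Task weights are set from the convergence rate of each task: the ratio
#' of its loss in the previous epoch to the epoch before, passed through a
#' temperature-scaled softmax and rescaled so the weights sum to the task
#' count K. Faster-converging tasks (ratio < 1) receive smaller weights.
#' For the first two epochs (no history) weights are uniform.
#'
#' @param prev Per-task losses at epoch t-1 (or `NULL` before epoch 3).
#' @param prev2 Per-task losses at epoch t-2 (or `NULL`).
#' @param K Task count (inferred from `prev` when given).
#' @param temperature Softmax temperature T (default 2, the convention of
#'   the originating multi-task method).
#' @return Numeric weight vector of length K summing to K.
#' @examples
#' dwa_weights(c(0.3, 0.2), c(0.3, 0.2)) # uniform: equal ratios
#' @export
dwa_weights <- function(prev = NULL, prev2 = NULL, K = length(prev),
                        temperature = 2) {
  if (is.null(prev) || is.null(prev2)) {
    stopifnot(K >= 1)
    return(rep(1, K))
  }
  stopifnot(length(prev) == length(prev2))
  if (any(prev <= 0) || any(prev2 <= 0)) {
    stop("dynamic weight average requires positive past losses")
  }
  r <- prev / prev2
  e <- exp(r / temperature)
  length(r) * e / sum(e)
}

#' Isomer ranking score
#'
#' Combined similarity score used to rank candidate glycan structures
#' against a query spectrum:
#' \deqn{Score = \alpha (1 - SA_Y) + \beta (1 - SA_B)}
#' with default weights 0.5/0.5. When the B term is unavailable (e.g. a
#' model without branch fragments), the score degrades to
#' `(1 - sa_Y)` scaled by `alpha / alpha`, i.e. the Y term renormalized.
#'
#' @param sa_Y,sa_B Spectral angles of the glycan Y and B parts in
#'   `[0, 1]`; `sa_B = NA` drops the B term and renormalizes.
#' @param alpha,beta Term weights (default 0.5 each).
#' @return Score; in `[0, 1]` at the default weights.
#' @export
ranking_score <- function(sa_Y, sa_B, alpha = 0.5, beta = 0.5) {
  ifelse(is.na(sa_B),
         alpha * (1 - sa_Y) / alpha,
         alpha * (1 - sa_Y) + beta * (1 - sa_B))
}
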