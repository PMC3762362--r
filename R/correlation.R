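#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] for the rate-rate
#' correlation analyses.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return The correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Exact permutation tail probability of a correlation
#'
#' Enumerates all n! assignments of y to x and returns the fraction with
#' correlation at least the observed one. Serves as the small-n oracle for
#' [resampled_permutation_p()].
#'
#' @param x,y Numeric vectors (n <= 7 to keep n! manageable).
#' @param tie_tol Permuted correlations within `tie_tol` of the observed
#'   value count as reaching it.
#' @return The exact tail probability (a multiple of 1/n!).
#' @export
permutation_p_exact <- function(x, y, tie_tol = 1e-9) {
  n <- length(x)
  if (n > 7) stop("exact enumeration limited to n <= 7")
  r_obs <- pearson_r(x, y)
  perms <- permutations_all(n)
  r_all <- apply(perms, 1, function(p) stats::cor(x, y[p]))
  mean(r_all >= r_obs - tie_tol)
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))))
}

#' Gaussian-resampled permutation test for a rate-rate correlation
#'
#' Tests whether an observed Pearson correlation between two sets of
#' measured rate constants could arise by coincidence, honouring the
#' measurement uncertainty of every point. Each of `n_resamples` samples
#' draws every coordinate from the anisotropic 2D Gaussian defined by its
#' error bars, randomly permutes the assignment of y values to x values
#' (uniformly over all n! arrangements, identity included), and computes
#' the correlation coefficient. The p-value is the fraction of resampled
#' coefficients at least as large as the correlation of the measured means.
#'
#' Gaussian draws are not truncated at zero. Resampled coefficients within
#' `tie_tol` of the observed value count as reaching it, which makes the
#' vanishing-error limit agree with the exact enumeration
#' [permutation_p_exact()].
#'
#' @param x,y Measured values (length n >= 3).
#' @param sx,sy Standard errors of `x` and `y`, all > 0.
#' @param n_resamples Number of resamples (default 1e5; fewer than 1000
#'   triggers a warning).
#' @param seed Integer seed.
#' @param tie_tol Tolerance for counting ties at the observed r.
#' @return Object of class `correlation_result`: list with `r` (observed,
#'   computed on the means), `p`, `n_resamples`, `seed` and `slope0`, the
#'   slope of the origin-constrained least-squares line y = slope0 * x.
#' @export
#' @examples
#' tab <- divca_constructs()
#' tab <- tab[tab$construct != "none", ]
#' resampled_permutation_p(tab$k_V_star, tab$k_B, tab$k_V_star_se,
#'                         tab$k_B_se, n_resamples = 1e4, seed = 1)
resampled_permutation_p <- function(x, y, sx, sy, n_resamples = 1e5,
                                    seed = NULL, tie_tol = 1e-9) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (length(y) != n || length(sx) != n || length(sy) != n)
    stop("x, y, sx, sy must have equal length")
  if (any(sx <= 0) || any(sy <= 0)) stop("all SEs must be > 0")
  if (n_resamples < 1000)
    warning("fewer than 1000 resamples gives an unstable p-value")

  r_obs <- pearson_r(x, y)
  with_local_seed(seed, {
    B <- as.integer(n_resamples)
    X <- matrix(stats::rnorm(B * n, mean = rep(x, each = B),
                             sd = rep(sx, each = B)), B, n)
    Y <- matrix(stats::rnorm(B * n, mean = rep(y, each = B),
                             sd = rep(sy, each = B)), B, n)
    # uniform random permutation of the y-assignment in each resample:
    # rank the rows of an iid uniform matrix
    keys <- matrix(stats::runif(B * n), B, n)
    ranks <- t(apply(keys, 1, order))
    Yp <- matrix(Y[cbind(rep(seq_len(B), n), as.vector(ranks))], B, n)

    Xc <- X - rowMeans(X)
    Yc <- Yp - rowMeans(Yp)
    r_all <- rowSums(Xc * Yc) /
      sqrt(rowSums(Xc^2) * rowSums(Yc^2))
    p <- max(mean(r_all >= r_obs - tie_tol), 1 / B)

    slope0 <- sum(x * y) / sum(x^2)
    structure(list(r = r_obs, p = p, n_resamples = B, seed = seed,
                   slope0 = slope0),
              class = "correlation_result")
  })
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f, resampled permutation p = %.4g (%d resamples)\n",
              x$r, x$p, x$n_resamples))
  cat(sprintf("origin-constrained slope = %.4g\n", x$slope0))
  invisible(x)
}
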