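#' Counting error of a fraction
#'
#' Binomial counting statistics: `df = sqrt(f (1 - f) / N)`.
#'
#' @param f Fraction in \[0, 1\].
#' @param N Number of observations (>= 1).
#' @return The counting error.
#' @export
#' @examples
#' counting_error(0.5, 100) # 0.05
counting_error <- function(f, N) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  sqrt(f * (1 - f) / N)
}

#' Rate constant for diVCA release from the nascent branch
#'
#' The nascent branch decays by two competing first-order pathways, intact
#' dissociation from the filament (rate k_A-) and diVCA release (rate
#' k_V-*), so its mean lifetime is `tau_V* = 1/(k_A- + k_V-*)` and the
#' release fraction is `f_V- = k_V-*/(k_A- + k_V-*)`. The release rate
#' therefore follows as `k_V-* = f_V- / tau_V*`, with first-order
#' (delta-method) error propagation assuming independent errors.
#'
#' @param f_V_minus diVCA-release fraction, in \[0, 1\].
#' @param tau_V_star Mean nascent-branch lifetime (s), > 0.
#' @param f_V_minus_se,tau_V_star_se Standard errors (0 if omitted).
#' @return List with `value` (s^-1) and `se`.
#' @export
#' @examples
#' compute_kv_star(0.026, 0.7, 0.004, 0.1)
compute_kv_star <- function(f_V_minus, tau_V_star,
                            f_V_minus_se = 0, tau_V_star_se = 0) {
  if (tau_V_star <= 0) stop("tau_V_star must be > 0")
  if (f_V_minus < 0 || f_V_minus > 1) stop("f_V_minus must lie in [0, 1]")
  k <- f_V_minus / tau_V_star
  se <- sqrt((f_V_minus_se / tau_V_star)^2 +
             (f_V_minus * tau_V_star_se / tau_V_star^2)^2)
  list(value = k, se = se)
}

#' Overall second-order branch-formation rate constant
#'
#' Composes the per-subunit filament association rate with the branching
#' efficiencies of the diVCA-bound and diVCA-free arrival classes:
#' `k_B = k_A+ * (f_AV * f_B(+diVCA) + (1 - f_AV) * f_B(-diVCA))`,
#' with first-order error propagation assuming independent errors.
#' With no VCA present (`f_AV = 0`) this reduces to `k_A+ * f_B(-diVCA)`.
#'
#' @param k_A_plus Filament association rate constant
#'   (M^-1 s^-1 per subunit), >= 0.
#' @param f_AV Coincident-arrival fraction, in \[0, 1\].
#' @param f_B_plus,f_B_minus Branch-formation fractions of the +diVCA and
#'   -diVCA classes, in \[0, 1\].
#' @param k_A_plus_se,f_AV_se,f_B_plus_se,f_B_minus_se Standard errors.
#' @return List with `value` (M^-1 s^-1 per mother-filament subunit) and
#'   `se`.
#' @export
#' @examples
#' compute_kB(2.1e4, 0.83, 0.008, 0.006)$value # about 161
compute_kB <- function(k_A_plus, f_AV, f_B_plus, f_B_minus,
                       k_A_plus_se = 0, f_AV_se = 0,
                       f_B_plus_se = 0, f_B_minus_se = 0) {
  if (k_A_plus < 0) stop("k_A_plus must be >= 0")
  fr <- c(f_AV, f_B_plus, f_B_minus)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  bracket <- f_AV * f_B_plus + (1 - f_AV) * f_B_minus
  k <- k_A_plus * bracket
  d <- c(bracket,                        # d/dk_A+
         k_A_plus * (f_B_plus - f_B_minus), # d/df_AV
         k_A_plus * f_AV,                # d/df_B+
         k_A_plus * (1 - f_AV))          # d/df_B-
  se <- sqrt(sum((d * c(k_A_plus_se, f_AV_se, f_B_plus_se, f_B_minus_se))^2))
  list(value = k, se = se)
}

#' Check internal consistency of a measured rate set against the scheme
#'
#' Verifies the competing-exponential identities
#' `tau_V* = 1/(k_A- + k_V-*)` and `f_V- = k_V-*/(k_A- + k_V-*)`, and that
#' the derived release rate `f_V- / tau_V*` equals the scheme's `k_V-*`.
#' Residuals are reported relative to the supplied standard errors where
#' available.
#'
#' @param f_V_minus,tau_V_star Measured release fraction and mean nascent
#'   lifetime.
#' @param k_A_minus,k_V_minus_star Scheme rate constants (s^-1), > 0
#'   allowed to be zero for `k_V_minus_star`.
#' @param f_V_minus_se,tau_V_star_se Optional standard errors used to
#'   express residuals in SE units.
#' @param tol_se Flag threshold in SE units (default 3).
#' @return List with residuals (`tau_residual`, `f_residual`,
#'   `kv_residual`), their SE-scaled versions where SEs were given, and a
#'   `consistent` flag.
#' @export
consistency_check <- function(f_V_minus, tau_V_star, k_A_minus,
                              k_V_minus_star, f_V_minus_se = NA,
                              tau_V_star_se = NA, tol_se = 3) {
  if (k_A_minus < 0 || k_V_minus_star < 0)
    stop("scheme rates must be non-negative")
  ktot <- k_A_minus + k_V_minus_star
  if (ktot <= 0) stop("k_A_minus + k_V_minus_star must be positive")
  tau_pred <- 1 / ktot
  f_pred <- k_V_minus_star / ktot
  kv_derived <- f_V_minus / tau_V_star
  res <- list(tau_residual = tau_V_star - tau_pred,
              f_residual = f_V_minus - f_pred,
              kv_residual = kv_derived - k_V_minus_star)
  res$tau_z <- if (is.na(tau_V_star_se)) NA_real_ else
    res$tau_residual / tau_V_star_se
  res$f_z <- if (is.na(f_V_minus_se)) NA_real_ else
    res$f_residual / f_V_minus_se
  zs <- c(res$tau_z, res$f_z)
  res$consistent <- if (all(is.na(zs)))
    abs(res$tau_residual) < 1e-9 && abs(res$f_residual) < 1e-9
  else all(abs(zs) <= tol_se, na.rm = TRUE)
  res
}

#' Assemble a per-construct derived-rate table
#'
#' Convenience wrapper producing the standard summary of colocalization
#' kinetics: given measured `f_AV`, `f_V_minus`, `f_B`, `tau_V_star` and
#' `k_A_plus` (each with SE), computes `k_V_minus_star` and `k_B` with
#' propagated errors.
#'
#' @param measurements data.frame with one row per construct and columns
#'   `construct`, `k_A_plus`, `k_A_plus_se`, `f_AV`, `f_AV_se`,
#'   `f_V_minus`, `f_V_minus_se`, `f_B`, `f_B_se`, `tau_V_star`,
#'   `tau_V_star_se`, and `f_B_minus`, `f_B_minus_se` (diVCA-free
#'   branching, shared across constructs).
#' @return The input with added `k_V_star`, `k_V_star_se`, `k_B`,
#'   `k_B_se` columns.
#' @export
rate_table <- function(measurements) {
  m <- as.data.frame(measurements)
  m$k_V_star <- m$k_V_star_se <- m$k_B <- m$k_B_se <- NA_real_
  for (i in seq_len(nrow(m))) {
    kv <- compute_kv_star(m$f_V_minus[i], m$tau_V_star[i],
                          m$f_V_minus_se[i], m$tau_V_star_se[i])
    kb <- compute_kB(m$k_A_plus[i], m$f_AV[i], m$f_B[i], m$f_B_minus[i],
                     m$k_A_plus_se[i], m$f_AV_se[i], m$f_B_se[i],
                     m$f_B_minus_se[i])
    m$k_V_star[i] <- kv$value; m$k_V_star_se[i] <- kv$se
    m$k_B[i] <- kb$value; m$k_B_se[i] <- kb$se
  }
  m
}
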