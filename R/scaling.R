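#' Integral correlation length
#'
#' xi^2 = integral of r^2 C(r) dr / integral of C(r) dr, taken from 0 to
#' the zero crossing r0. C is set to 0 at both r = 0 and r = r0, so the
#' integral effectively starts at the shortest sampled distance and the
#' integrand vanishes at the crossing; quadrature is trapezoidal on the
#' observed bins. For C constant on (0, R] this gives xi = R/sqrt(3); for
#' C = 1 - r/R, xi = R/sqrt(6).
#'
#' @param cf a `correlation_function`.
#' @param r0 zero crossing; computed via [zero_crossing()] if missing.
#' @return xi (NA if r0 is undefined or the denominator integral is not
#'   positive).
#' @export
correlation_length <- function(cf, r0 = NULL) {
  if (is.null(r0)) r0 <- zero_crossing(cf)$r0
  if (is.na(r0)) return(NA_real_)
  keep <- cf$r < r0 & !is.na(cf$C)
  r <- c(0, cf$r[keep], r0)
  C <- c(0, cf$C[keep], 0)
  den <- trapz(r, C)
  if (den <= 0) return(NA_real_)
  sqrt(trapz(r, r^2 * C) / den)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Susceptibility: area under C(r) up to the zero crossing
#'
#' chi = trapezoidal area of the positive part of the correlation
#' function over (0, r0], with C taken as 0 at r = 0 and at r0. In the
#' lattice model, chi(P) peaks sharply at the critical transmission
#' probability.
#'
#' @inheritParams correlation_length
#' @return chi (NA if r0 undefined).
#' @export
susceptibility <- function(cf, r0 = NULL) {
  if (is.null(r0)) r0 <- zero_crossing(cf)$r0
  if (is.na(r0)) return(NA_real_)
  keep <- cf$r < r0 & !is.na(cf$C)
  trapz(c(0, cf$r[keep], r0), c(0, cf$C[keep], 0))
}

#' Collapse exponent gamma
#'
#' For each window size L the derivative of C with respect to the
#' rescaled distance r' = r / r0 at r' = 1 is r0 * dC/dr at the crossing,
#' taken from the same cubic fit that located r0. gamma is the power-law
#' exponent of the decay of |dC/dr'| with window size, fitted by least
#' squares on log-log values. By default the fit is against r0(L)
#' (proportional to L when scaling holds); set `x = "L"` to fit against
#' the window side itself.
#'
#' @param cfs list of `correlation_function`s over different L.
#' @param x abscissa of the power-law fit: `"r0"` (default) or `"L"`.
#' @return list with `gamma` (the reported exponent: magnitude of the
#'   power-law exponent of |dC/dr'| versus window size), `gamma_signed`
#'   (negative when the rescaled derivative grows with window size, the
#'   exponent that enters the amplitude rescaling of the collapse), the
#'   per-L table `detail` (L, r0, dC/dr', used flag), and the log-log
#'   fit.
#' @export
gamma_estimate <- function(cfs, x = c("r0", "L")) {
  x <- match.arg(x)
  det <- lapply(cfs, function(cf) {
    zc <- zero_crossing(cf)
    data.frame(L = cf$L, r0 = zc$r0,
               dC = if (zc$defined) zc$r0 * zc$slope else NA_real_)
  })
  det <- do.call(rbind, det)
  det$used <- !is.na(det$dC) & det$dC < 0
  if (sum(det$used) < 3)
    stop("need at least 3 window sizes with a defined, decaying crossing")
  xx <- log(if (x == "r0") det$r0[det$used] else det$L[det$used])
  yy <- log(-det$dC[det$used])
  fit <- lm(yy ~ xx)
  gs <- -unname(coef(fit)[2])
  list(gamma = abs(gs), gamma_signed = gs, detail = det, fit = fit)
}

#' Scaling collapse of a correlation-function family
#'
#' Maps each curve to (r / r0, C * r0^gamma), resamples all curves by
#' linear interpolation onto a common r' grid, and averages them into the
#' estimate of the dimensionless scaling function F(r'). The collapse
#' error Delta is the mean absolute deviation of the rescaled curves from
#' F. The renormalisation has no free parameters: gamma and r0 come from
#' the data, and Delta is *not* minimised over gamma.
#'
#' @param cfs list of `correlation_function`s.
#' @param gamma collapse exponent (e.g. from [gamma_estimate()]).
#' @param L_min only curves with L >= L_min enter (default 0).
#' @param r_grid common r' grid; default 50 points on (0, 1.2].
#' @return list with `r_prime`, `F` (averaged curve), `Delta` (mean
#'   absolute deviation of the rescaled curves from F), `Delta_rel`
#'   (`Delta` divided by the mean magnitude of F, an amplitude-free
#'   collapse error comparable across conditions whose correlation
#'   amplitudes differ), `curves` (matrix of rescaled curves), `L_used`.
#' @export
collapse_curves <- function(cfs, gamma, L_min = 0,
                            r_grid = seq(1.2 / 50, 1.2, length.out = 50)) {
  keep <- vapply(cfs, function(cf) cf$L >= L_min, logical(1))
  cfs <- cfs[keep]
  if (length(cfs) < 2) stop("need at least 2 curves with L >= L_min")
  curves <- sapply(cfs, function(cf) {
    r0 <- zero_crossing(cf)$r0
    if (is.na(r0)) return(rep(NA_real_, length(r_grid)))
    approx(cf$r / r0, cf$C * r0^gamma, xout = r_grid, rule = 1)$y
  })
  Fbar <- rowMeans(curves, na.rm = TRUE)
  dev <- abs(sweep(curves, 1, Fbar))
  Delta <- mean(dev, na.rm = TRUE)
  # shape-only error: each curve normalised to unit mean magnitude first,
  # so conditions with different correlation amplitudes stay comparable
  shapes <- apply(curves, 2, function(y) y / mean(abs(y), na.rm = TRUE))
  Fs <- rowMeans(shapes, na.rm = TRUE)
  Delta_shape <- mean(abs(sweep(shapes, 1, Fs)), na.rm = TRUE)
  list(r_prime = r_grid, F = Fbar, Delta = Delta,
       Delta_rel = Delta / mean(abs(Fbar), na.rm = TRUE),
       Delta_shape = Delta_shape,
       curves = curves, L_used = vapply(cfs, `[[`, numeric(1), "L"))
}

#' Chi-squared test of linear growth of the correlation length
#'
#' Fits the ordinary least-squares line R(L) to the (L, xi) points and
#' forms the statistic chi_c^2 = sum_i (xi(L_i) - R(L_i))^2 / R(L_i),
#' referred to a chi-squared distribution with n - 2 degrees of freedom
#' (two line parameters). Both tail probabilities are reported: the upper
#' tail is the conventional goodness-of-fit probability (large when the
#' points hug the line); `p_lower` is the probability of a fit at least
#' this good by chance.
#'
#' @param L window sizes.
#' @param xi correlation lengths at those sizes.
#' @return list with `slope`, `intercept`, `fitted`, `chi2`, `df`,
#'   `p_upper`, `p_lower`, `r_squared`.
#' @export
linear_scaling_test <- function(L, xi) {
  ok <- !is.na(xi)
  L <- L[ok]; xi <- xi[ok]
  if (length(L) < 3) stop("need at least 3 (L, xi) points")
  fit <- lm(xi ~ L)
  R <- unname(fitted(fit))
  if (any(R <= 0))
    stop("regression line non-positive at some L; chi-squared statistic undefined")
  chi2 <- sum((xi - R)^2 / R)
  df <- length(L) - 2L
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fitted = R, chi2 = chi2, df = df,
       p_upper = pchisq(chi2, df, lower.tail = FALSE),
       p_lower = pchisq(chi2, df),
       r_squared = summary(fit)$r.squared)
}

#' Proportionality diagnostic between xi and r0
#'
#' When the scaling collapse holds, xi(L) is proportional to r0(L); the
#' coefficient of variation of xi/r0 across L quantifies how well the
#' proportionality (and hence the collapse) is satisfied.
#'
#' @param L window sizes.
#' @param xi correlation lengths.
#' @param r0 zero crossings.
#' @param tol CV threshold above which the violation flag is raised
#'   (default 0.10).
#' @return list with `ratio` (per-L xi/r0), `cv`, `violated`.
#' @export
xi_r0_ratio <- function(L, xi, r0, tol = 0.10) {
  ok <- !is.na(xi) & !is.na(r0)
  if (sum(ok) < 2) stop("need at least 2 L with both xi and r0 defined")
  ratio <- xi[ok] / r0[ok]
  cv <- sd(ratio) / mean(ratio)
  list(L = L[ok], ratio = ratio, cv = cv, violated = cv > tol)
}

#' Saturation diagnostic for xi(L)
#'
#' Ratio of the slope of xi over the top half of the L range to the slope
#' over the bottom half. Near 1 for linear growth (critical dynamics);
#' well below 1 when xi saturates with window size (sub-/supercritical
#' dynamics, where the intrinsic correlation scale is finite).
#'
#' @param L window sizes (ascending).
#' @param xi correlation lengths.
#' @return slope ratio (top half / bottom half).
#' @export
xi_saturation_ratio <- function(L, xi) {
  ok <- !is.na(xi)
  L <- L[ok]; xi <- xi[ok]
  n <- length(L)
  if (n < 4) stop("need at least 4 (L, xi) points")
  h <- ceiling(n / 2)
  s_bot <- coef(lm(xi[1:h] ~ L[1:h]))[2]
  s_top <- coef(lm(xi[(n - h + 1):n] ~ L[(n - h + 1):n]))[2]
  unname(s_top / s_bot)
}
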