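# Spline design matrices and penalties for the four BCT parameter curves.
#
# The M-curve uses an unpenalized regression B-spline (degree 3, specified
# internal breakpoints, boundary knots at the domain edges 0 and 45 weeks).
# The S/L/T-curves use a penalized cubic B-spline on equally spaced knots
# with a second-order difference penalty; the smoothing parameter is solved
# at fit time so the trace of the smoother matrix equals the requested
# effective degrees of freedom. The penalty null space is the affine
# functions, so df = 2 reproduces a straight line exactly.

.GA_DOMAIN <- c(0, 45)

#' Build a spline design for one parameter curve
#'
#' @param t_values gestational ages (weeks) of the observations, inside
#'   \code{[0, 45]}.
#' @param curve_spec for the regression-spline branch,
#'   \code{list(basis = "bspline", degree, breakpoints)}; for the
#'   penalized branch \code{list(basis = "smooth", df, n_segments)}
#'   (\code{n_segments} defaults to 12).
#' @return list with the basis matrix \code{B} (rows = observations), the
#'   penalty matrix \code{P} (zero for the regression branch), the full
#'   knot vector, degree, branch type and df target; pass to
#'   [eval_design()] to evaluate the basis elsewhere.
#' @export
build_design <- function(t_values, curve_spec) {
  if (any(t_values < .GA_DOMAIN[1] | t_values > .GA_DOMAIN[2]))
    stop("gestational ages must lie in [0, 45] weeks")
  type <- match.arg(curve_spec$basis, c("bspline", "smooth"))
  degree <- if (is.null(curve_spec$degree)) 3L else as.integer(curve_spec$degree)
  ord <- degree + 1L
  if (type == "bspline") {
    br <- sort(curve_spec$breakpoints)
    if (any(diff(br) <= 0)) stop("breakpoints must be strictly increasing")
    if (any(br <= .GA_DOMAIN[1] | br >= .GA_DOMAIN[2]))
      stop("breakpoints must lie strictly inside (0, 45)")
    if (any(br < min(t_values) | br > max(t_values)))
      warning("breakpoint(s) outside the observed gestational-age range")
    knots <- c(rep(.GA_DOMAIN[1], ord), br, rep(.GA_DOMAIN[2], ord))
    df_target <- length(br) + ord
  } else {
    nseg <- if (is.null(curve_spec$n_segments)) 12L else as.integer(curve_spec$n_segments)
    h <- diff(.GA_DOMAIN) / nseg
    knots <- seq(.GA_DOMAIN[1] - degree * h, .GA_DOMAIN[2] + degree * h, by = h)
    df_target <- curve_spec$df
    if (is.null(df_target) || df_target < 1) stop("smoothing df must be >= 1")
  }
  B <- splines::splineDesign(knots, t_values, ord = ord)
  k <- ncol(B)
  if (length(unique(t_values)) < if (type == "bspline") k else 4)
    stop("fewer distinct gestational ages than basis dimension")
  P <- if (type == "bspline") {
    matrix(0, k, k)
  } else {
    D <- diff(diag(k), differences = 2)
    crossprod(D)
  }
  list(B = B, P = P, knots = knots, degree = degree, type = type,
       df = df_target)
}

#' @rdname build_design
#' @param design a design built by [build_design()].
#' @param t_new gestational ages at which to evaluate the basis.
#' @export
eval_design <- function(design, t_new) {
  if (any(t_new < .GA_DOMAIN[1] | t_new > .GA_DOMAIN[2]))
    stop("gestational ages must lie in [0, 45] weeks")
  splines::splineDesign(design$knots, t_new, ord = design$degree + 1L)
}

# Penalized weighted least squares: minimize ||sqrt(w)(e - B beta)||^2 +
# lambda beta' P beta. Returns coefficients and the effective df
# tr((B'WB + lambda P)^-1 B'WB).
.pwls <- function(B, P, w, e, lambda) {
  BtW <- t(B * w)
  A <- BtW %*% B
  M <- A + lambda * P
  # ridges for numerical rank safety: basis columns with little support,
  # and scale mismatch between A and a large penalty
  diag(M) <- diag(M) + 1e-6 * mean(diag(A)) + 1e-10 * mean(diag(M))
  Minv <- solve(M)
  beta <- Minv %*% (BtW %*% e)
  list(beta = drop(beta), edf = sum(diag(Minv %*% A)))
}

# Solve lambda so that the smoother trace equals the df target. The search
# is over lambda relative to the scales of B'WB and P, which keeps the
# penalized system well conditioned at both extremes.
.lambda_for_df <- function(B, P, w, df_target) {
  if (all(P == 0)) return(0)
  BtW <- t(B * w); A <- BtW %*% B
  scale <- mean(diag(A)) / mean(diag(P))
  edf_at <- function(loglam) {
    M <- A + 10^loglam * scale * P
    diag(M) <- diag(M) + 1e-6 * mean(diag(A)) + 1e-10 * mean(diag(M))
    sum(diag(solve(M, A)))
  }
  k <- ncol(B)
  if (df_target >= k - 1e-6) return(1e-8 * scale)
  lo <- -8; hi <- 9
  f_lo <- edf_at(lo) - df_target
  f_hi <- edf_at(hi) - df_target
  if (f_lo <= 0) return(10^lo * scale)  # tiny penalty already below target
  if (f_hi >= 0) return(10^hi * scale)  # target at/below null-space dimension
  10^stats::uniroot(function(l) edf_at(l) - df_target, c(lo, hi),
                    tol = 1e-3)$root * scale
}
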