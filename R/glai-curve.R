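## Parametric GLAI curve: four linear slope segments (early/late vegetative,
## slow/rapid senescence) joined by quadratic bends of half-width `bend` at
## the vegetative break tau_v and the senescence break tau_s, with a flat
## plateau at glai_max between t_M and t_o. This is the ground-truth shape
## the synthetic generator plants and the bent-cable extraction recovers.

## bent-cable transfer q(t; tau, gamma) and its antiderivative Q
qBend <- function(t, tau, gamma) {
  if (gamma <= 0) return(pmax(t - tau, 0))
  out <- numeric(length(t))
  lo <- t <= tau - gamma
  hi <- t >= tau + gamma
  mid <- !lo & !hi
  out[mid] <- (t[mid] - tau + gamma)^2 / (4 * gamma)
  out[hi] <- t[hi] - tau
  out
}

qBendInt <- function(t, tau, gamma) {
  if (gamma <= 0) return(pmax(t - tau, 0)^2 / 2)
  out <- numeric(length(t))
  hi <- t >= tau + gamma
  mid <- t > tau - gamma & !hi
  out[mid] <- (t[mid] - tau + gamma)^3 / (12 * gamma)
  out[hi] <- (t[hi] - tau)^2 / 2 + gamma^2 / 6
  out
}

#' Default GLAI curve parameters
#'
#' Phase parameters of the planted GLAI curve, in GDD6 except `glai_max`
#' (m2/m2) and the unitless shape fractions: emergence `t_e`, vegetative
#' break `tau_v`, time of maximum `t_M`, senescence onset `t_o`, senescence
#' break `tau_s`, complete senescence `t_z`; `v_frac` is the GLAI fraction
#' reached at `tau_v`, `s_frac` the fraction remaining at `tau_s`; `bend` is
#' the quadratic bend half-width at the two breaks.
#'
#' @return named numeric vector of curve parameters.
#' @export
glaiCurveParams <- function() {
  c(t_e = 60, tau_v = 350, t_M = 750, glai_max = 4.0,
    t_o = 1050, tau_s = 1500, t_z = 1900,
    v_frac = 0.3, s_frac = 0.7, bend = 30)
}

## internal: derived slopes with bend widths clipped inside their segments
curveGeometry <- function(p) {
  gv <- max(0, min(p[["bend"]], (p[["tau_v"]] - p[["t_e"]]) * 0.9,
                   (p[["t_M"]] - p[["tau_v"]]) * 0.9))
  gs <- max(0, min(p[["bend"]], (p[["tau_s"]] - p[["t_o"]]) * 0.9,
                   (p[["t_z"]] - p[["tau_s"]]) * 0.9))
  M <- p[["glai_max"]]
  list(
    M = M, gv = gv, gs = gs,
    s1 = p[["v_frac"]] * M / (p[["tau_v"]] - p[["t_e"]]),
    s2 = (1 - p[["v_frac"]]) * M / (p[["t_M"]] - p[["tau_v"]]),
    sSS = -(1 - p[["s_frac"]]) * M / (p[["tau_s"]] - p[["t_o"]]),
    sRS = -p[["s_frac"]] * M / (p[["t_z"]] - p[["tau_s"]])
  )
}

#' Evaluate a planted GLAI curve
#'
#' @param params named vector as [glaiCurveParams()].
#' @param times numeric times (GDD6).
#' @return GLAI values (m2/m2), zero outside `[t_e, t_z]`.
#' @export
glaiCurve <- function(params, times) {
  p <- params; g <- curveGeometry(p)
  out <- numeric(length(times))
  rise <- times > p[["t_e"]] & times < p[["t_M"]]
  flat <- times >= p[["t_M"]] & times <= p[["t_o"]]
  fall <- times > p[["t_o"]] & times < p[["t_z"]]
  tr <- times[rise]
  out[rise] <- g$s1 * (tr - p[["t_e"]]) +
    (g$s2 - g$s1) * qBend(tr, p[["tau_v"]], g$gv)
  out[flat] <- g$M
  tf <- times[fall]
  out[fall] <- g$M + g$sSS * (tf - p[["t_o"]]) +
    (g$sRS - g$sSS) * qBend(tf, p[["tau_s"]], g$gs)
  pmin(pmax(out, 0), g$M)
}

#' Exact integral of a planted GLAI curve over `[a, b]`
#'
#' Uses closed-form antiderivatives of the piecewise linear-plus-quadratic
#' shape, so planted areas under the curve are available without quadrature.
#'
#' @inheritParams glaiCurve
#' @param a,b integration bounds (GDD6).
#' @return integral in m2/m2 * GDD6.
#' @export
glaiCurveIntegral <- function(params, a, b) {
  p <- params; g <- curveGeometry(p)
  cum <- function(t) {  # integral of curve from -Inf to t
    t <- min(max(t, p[["t_e"]]), p[["t_z"]])
    iRise <- function(u) {
      u <- min(u, p[["t_M"]])
      g$s1 * (u - p[["t_e"]])^2 / 2 +
        (g$s2 - g$s1) * qBendInt(u, p[["tau_v"]], g$gv)
    }
    val <- iRise(t)
    if (t > p[["t_M"]])
      val <- val + g$M * (min(t, p[["t_o"]]) - p[["t_M"]])
    if (t > p[["t_o"]]) {
      u <- t
      val <- val + g$M * (u - p[["t_o"]]) +
        g$sSS * (u - p[["t_o"]])^2 / 2 +
        (g$sRS - g$sSS) * qBendInt(u, p[["tau_s"]], g$gs)
    }
    val
  }
  cum(b) - cum(a)
}

## first crossing of `level` on the rising (side="rise") or falling
## (side="fall") limb, by root bracketing on the closed-form curve
curveCrossing <- function(params, level, side = c("rise", "fall")) {
  side <- match.arg(side)
  p <- params
  f <- function(t) glaiCurve(p, t) - level
  if (level <= 0 || level > p[["glai_max"]]) return(NA_real_)
  if (side == "rise") {
    if (level == p[["glai_max"]]) return(p[["t_M"]])
    stats::uniroot(f, c(p[["t_e"]] + 1e-9, p[["t_M"]]), tol = 1e-8)$root
  } else {
    if (level == p[["glai_max"]]) return(p[["t_o"]])
    stats::uniroot(f, c(p[["t_o"]], p[["t_z"]] - 1e-9), tol = 1e-8)$root
  }
}

#' Analytic trait values of a planted GLAI curve
#'
#' Applies the 24-trait definitions (phase boundaries, durations, areas,
#' slopes, relative-duration thresholds) directly to the closed-form planted
#' curve, independently of the grid-based extraction in [extractTraits()].
#' The senescence onset uses the same 95%-of-maximum rule as the extraction.
#'
#' @inheritParams glaiCurve
#' @return named numeric vector with the 24 traits.
#' @export
trueGlaiTraits <- function(params) {
  p <- params; g <- curveGeometry(p)
  t_e <- p[["t_e"]]; t1 <- p[["tau_v"]]; tM <- p[["t_M"]]
  t2 <- p[["tau_s"]]; tz <- p[["t_z"]]
  tO <- curveCrossing(p, 0.95 * g$M, "fall")
  au <- function(a, b) glaiCurveIntegral(p, a, b)
  dx <- function(x) {
    lv <- x * g$M
    curveCrossing(p, lv, "fall") - curveCrossing(p, lv, "rise")
  }
  c(S_EV = g$s1, S_LV = g$s2, S_SS = g$sSS, S_RS = g$sRS,
    D_EV = t1 - t_e, D_LV = tM - t1, D_V = tM - t_e, D_F = tO - tM,
    D_SS = t2 - tO, D_RS = tz - t2, D_S = tz - tO, D_C = tz - t_e,
    AUC_EV = au(t_e, t1), AUC_LV = au(t1, tM), AUC_V = au(t_e, tM),
    AUC_F = au(tM, tO), AUC_SS = au(tO, t2), AUC_RS = au(t2, tz),
    AUC_S = au(tO, tz), AUC_C = au(t_e, tz),
    GLAI_M = g$M, D_75 = dx(0.75), D_50 = dx(0.50), D_25 = dx(0.25))
}
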