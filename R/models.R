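## Closed-form growth laws. All value functions are vectorized over time and
## clamp every exp() argument to +/-700 so asymptotes survive extreme inputs
## instead of overflowing to Inf/NaN.

.EXP_CLAMP <- 700

.cexp <- function(x) exp(pmin(pmax(x, -.EXP_CLAMP), .EXP_CLAMP))

#' Gompertz growth curve (growth-parameter form)
#'
#' Modified Gompertz sigmoid reparameterized in the three biologically
#' interpretable quantities: asymptotic maximum \eqn{A}, maximum specific
#' growth rate \eqn{\mu_{max}} and lag time \eqn{\lambda}:
#' \deqn{y(t) = A \exp\{-\exp[(\mu_{max} e / A)(\lambda - t) + 1]\}}
#'
#' @param times numeric vector of times.
#' @param A asymptotic maximum (> 0, signal units).
#' @param muMax maximum specific growth rate (> 0, 1/time).
#' @param lambda lag time (finite; 0 or negative means no lag).
#' @return numeric vector of signal values, monotone nondecreasing in time.
#' @examples
#' gompertzValue(c(0, 5, 50), A = 1, muMax = 0.5, lambda = 5)
#' @export
gompertzValue <- function(times, A, muMax, lambda) {
    A * .cexp(-.cexp((muMax * exp(1) / A) * (lambda - times) + 1))
}

#' Logistic growth curve (growth-parameter form)
#'
#' \deqn{y(t) = A / (1 + \exp[4\mu_{max}(\lambda - t)/A + 2])}
#'
#' @inheritParams gompertzValue
#' @return numeric vector of signal values.
#' @examples
#' logisticValue(c(0, 2, 50), A = 1, muMax = 0.3, lambda = 2)
#' @export
logisticValue <- function(times, A, muMax, lambda) {
    A / (1 + .cexp(4 * muMax * (lambda - times) / A + 2))
}

#' Richards growth curve (growth-parameter form)
#'
#' Four-parameter sigmoid with shape parameter \eqn{v}; reduces to the
#' logistic curve at \eqn{v = 1}:
#' \deqn{y(t) = A [1 + v e^{1+v} \exp((\mu_{max}/A)(1+v)^{1+1/v}(\lambda-t))]^{-1/v}}
#'
#' @inheritParams gompertzValue
#' @param v shape parameter (> 0, dimensionless).
#' @return numeric vector of signal values.
#' @export
richardsValue <- function(times, A, muMax, lambda, v) {
    inner <- v * .cexp(1 + v) *
        .cexp((muMax / A) * (1 + v)^(1 + 1 / v) * (lambda - times))
    A * (1 + inner)^(-1 / v)
}

## Baranyi adjustment function A(t): the argument of the log is the convex
## combination a*(1 - e^{-h0}) + e^{-h0} with a = e^{-v t}, always in (0, 1],
## so the log never leaves its domain for valid parameters.
.baranyiAdjust <- function(times, rate, vRate, h0) {
    a <- .cexp(-vRate * times)
    eh <- .cexp(-h0)
    times + log(a * (1 - eh) + eh) / rate
}

#' Baranyi growth curve on the log-population scale
#'
#' Baranyi-Roberts model with explicit adaptation function governed by the
#' initial physiological state \eqn{h_0} and adaptation rate \eqn{v}:
#' \deqn{y(t) = y_0 + \mu_{max} A(t) - \frac{1}{m}\ln\!\Big(1 +
#'   \frac{e^{m \mu_{max} A(t)} - 1}{e^{m (y_{max}-y_0)}}\Big)}
#' with \eqn{A(t) = t + \frac{1}{\rho}\ln(e^{-vt} + e^{-h_0} - e^{-vt-h_0})}.
#'
#' Two conventions circulate for the rate \eqn{\rho} in the adjustment
#' function.  \code{adjustment = "muMax"} (the default) uses
#' \eqn{\rho = \mu_{max}}; \code{adjustment = "vRate"} uses \eqn{\rho = v}
#' as in the original Baranyi-Roberts formulation (registered separately as
#' \code{baranyi_classic}).  The correction term is evaluated in log-sum-exp
#' form so \eqn{y(\infty) = y_{max}} holds without overflow.
#'
#' @param times numeric vector of nonnegative times.
#' @param y0 initial log-population.
#' @param yMax asymptotic log-population (> y0).
#' @param muMax maximum specific growth rate (> 0, 1/time).
#' @param vRate adaptation rate (> 0, 1/time).
#' @param h0 initial physiological state (>= 0, dimensionless).
#' @param mCurv curvature parameter (> 0, dimensionless).
#' @param adjustment which rate divides the log in the adjustment function.
#' @return numeric vector of log-population values.
#' @export
baranyiValue <- function(times, y0, yMax, muMax, vRate, h0, mCurv,
                         adjustment = c("muMax", "vRate")) {
    adjustment <- match.arg(adjustment)
    rate <- if (adjustment == "muMax") muMax else vRate
    At <- .baranyiAdjust(times, rate, vRate, h0)
    x <- mCurv * muMax * At
    B <- mCurv * (yMax - y0)
    ## log(1 + (e^x - 1)/e^B) = log(e^B + e^x - 1) - B, stabilized
    M0 <- pmax(pmax(B, x), 0)
    corr <- log(.cexp(B - M0) + .cexp(x - M0) - .cexp(-M0)) + M0 - B
    y0 + muMax * At - corr / mCurv
}

#' Hyperbolastic growth curve of type III (H3)
#'
#' Flexible saturating growth law combining a power-law rate term
#' (\eqn{\delta, \gamma}) with an arcsinh term (\eqn{\theta}):
#' \deqn{P(t) = M - \alpha \exp(-\delta t^{\gamma} - \mathrm{arcsinh}(\theta t))}
#' where \eqn{\alpha} is never a free parameter but is recomputed from the
#' initial condition \eqn{P(t_0) = P_0}:
#' \deqn{\alpha = (M - P_0)\exp(\delta t_0^{\gamma} + \mathrm{arcsinh}(\theta t_0))}
#'
#' With \eqn{\theta = 0} and \eqn{\gamma = 1} the curve degenerates to
#' simple exponential saturation; this is permitted and not special-cased.
#'
#' @param times numeric vector of times; must be nonnegative when
#'   \code{gamma} is not a whole number.
#' @param M limiting size (> P0, signal units).
#' @param delta rate coefficient (>= 0, 1/time^gamma).
#' @param gamma time exponent (> 0, dimensionless).
#' @param theta arcsinh rate (>= 0, 1/time).
#' @param P0 initial size at \code{t0} (0 < P0 < M).
#' @param t0 time of the initial condition.
#' @return numeric vector of sizes; \code{P(t0) = P0} exactly.
#' @export
h3Value <- function(times, M, delta, gamma, theta, P0, t0 = 0) {
    if (abs(gamma - round(gamma)) > 1e-12 && any(times < 0))
        stop("negative times are outside the domain of t^gamma for non-integer gamma")
    alpha <- (M - P0) * .cexp(delta * t0^gamma + asinh(theta * t0))
    M - alpha * .cexp(-delta * times^gamma - asinh(theta * times))
}

#' First- or second-order polynomial evaluated by Horner's rule
#'
#' @param times numeric vector of times.
#' @param coefficients numeric vector of length 2 (line) or 3 (parabola),
#'   constant term first.
#' @return numeric vector.
#' @export
polynomialValue <- function(times, coefficients) {
    if (!length(coefficients) %in% c(2L, 3L))
        stop("coefficients must have length 2 (first order) or 3 (second order)")
    acc <- rep(coefficients[length(coefficients)], length(times))
    for (i in rev(seq_len(length(coefficients) - 1L)))
        acc <- acc * times + coefficients[i]
    acc
}

#' Exponential decay toward an offset
#'
#' \deqn{y(t) = c + (y_0 - c) e^{-k t}}
#'
#' @param times numeric vector of times.
#' @param y0 initial value (signal units).
#' @param k decay rate (> 0, 1/time).
#' @param offset asymptotic value \eqn{c} (signal units).
#' @return numeric vector.
#' @export
expDecayValue <- function(times, y0, k, offset = 0) {
    offset + (y0 - offset) * .cexp(-k * times)
}

#' Live Cell Fraction spheroid radius trajectory
#'
#' Integrates the tumor-spheroid ODE in which only a viable rim of depth
#' \eqn{\lambda} proliferates at rate \eqn{\alpha} while cells die at rate
#' \eqn{\delta}:
#' \deqn{\frac{dr}{dt} = \frac{r}{3}\Big(\frac{(\alpha+\delta)\,3\lambda}
#'   {3\lambda + r} - \delta\Big)}
#' The unique positive fixed point is \eqn{r^* = 3\lambda\alpha/\delta};
#' trajectories starting below it increase toward it, trajectories starting
#' above decrease toward it.  For \eqn{r \ll 3\lambda} growth is exponential
#' at rate \eqn{\alpha/3}.
#'
#' Integration uses an adaptive solver (\code{deSolve::ode}, lsoda) with
#' default relative tolerance 1e-8 and absolute tolerance 1e-10 — tight
#' enough that fitting error dominates solver error.
#'
#' @param times strictly increasing times; \code{times[1]} is the
#'   initial-condition time for \code{r0}.
#' @param alpha proliferation rate (> 0, 1/time).
#' @param delta death rate (> 0, 1/time).
#' @param lambdaDepth viable-rim depth (> 0, length units).
#' @param r0 initial radius (> 0, length units).
#' @param rtol,atol solver tolerances.
#' @return numeric vector of radii aligned 1:1 with \code{times}.
#' @examples
#' lcfSimulate(0:40, alpha = 0.2, delta = 0.05, lambdaDepth = 1, r0 = 0.5)
#' @export
lcfSimulate <- function(times, alpha, delta, lambdaDepth, r0,
                        rtol = 1e-8, atol = 1e-10) {
    if (length(times) < 1L || (length(times) > 1L && any(diff(times) <= 0)))
        stop("times must be strictly increasing")
    deriv <- function(t, y, parms) {
        r <- y[1]
        list(r / 3 * ((alpha + delta) * 3 * lambdaDepth /
                          (3 * lambdaDepth + r) - delta))
    }
    if (length(times) == 1L) return(r0)
    sol <- try(deSolve::ode(y = c(r = r0), times = times, func = deriv,
                            parms = NULL, rtol = rtol, atol = atol),
               silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) != length(times) ||
        any(!is.finite(sol[, "r"])))
        stop("live-cell-fraction ODE integration failed: ",
             if (inherits(sol, "try-error")) attr(sol, "condition")$message
             else "solver returned an incomplete or non-finite trajectory")
    unname(sol[, "r"])
}
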