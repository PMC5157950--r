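#' Life-history parameter set
#'
#' Bundles every non-evolving constant of the life-cycle model: the
#' stalk:spore split, spore mortality, germination lag, the survivorship
#' time scale and maximum solitary-cell lifetime, the linear coefficients of
#' the survivorship-shape cost \eqn{\beta(c) = b_0 - b_1 c} and of the spore
#' viability \eqn{\nu(c) = a_0 - a_1 c}, the Michaelis-Menten saturation
#' constant, and the admissible division-rate range.
#'
#' Defaults follow the published model where the value is printed
#' (\code{s}, \code{T_sur}, the \code{beta_*} and \code{nu_*} coefficients,
#' the division-rate range); the remaining constants (\code{delta},
#' \code{tau}, \code{mu}, \code{R_half}) are order-of-magnitude defaults,
#' flagged as assumed by [param_sources()] and echoed as such in run
#' metadata.
#'
#' @param s fraction of aggregated cells that become spores (the remainder
#'   dies building the stalk); dimensionless in (0, 1].
#' @param delta dormant-spore death rate, per hour.
#' @param tau germination lag after a food pulse, hours.
#' @param mu rate setting how fast the solitary-cell death rate changes with
#'   time since starvation, per hour. The default \code{1/T_sur} keeps
#'   \code{mu * t <= 1} over the whole survivorship support, which makes
#'   survival monotone in the division rate at all times.
#' @param T_sur maximum lifetime of a starving solitary cell, hours.
#' @param beta_b0,beta_b1 coefficients of the survivorship exponent
#'   \eqn{\beta(c) = b_0 - b_1 c}; must give \eqn{\beta > 1} on the whole
#'   admissible division-rate range.
#' @param nu_a0,nu_a1 coefficients of the spore viability
#'   \eqn{\nu(c) = a_0 - a_1 c}; must stay within [0, 1] on the admissible
#'   range.
#' @param R_half Michaelis-Menten saturation constant, resource units.
#' @param c_min,c_max admissible division-rate range, per hour.
#' @param exhaustion_tol resource level (as a fraction of the pulse) at and
#'   below which the growth integrator declares the resource exhausted and
#'   triggers starvation.
#' @return An object of class \code{life_history_params} (a validated list).
#' @examples
#' p <- life_history_params()
#' beta_cost(0.15, p)      # 2.5
#' spore_viability(0.45, p) # 0.2
#' @export
life_history_params <- function(s = 0.8, delta = 1e-4, tau = 4, mu = 0.005,
                                T_sur = 200, beta_b0 = 3.1, beta_b1 = 4,
                                nu_a0 = 1.1, nu_a1 = 2, R_half = 1e7,
                                c_min = 0.05, c_max = 0.45,
                                exhaustion_tol = 1e-9) {
  p <- list(s = s, delta = delta, tau = tau, mu = mu, T_sur = T_sur,
            beta_b0 = beta_b0, beta_b1 = beta_b1,
            nu_a0 = nu_a0, nu_a1 = nu_a1, R_half = R_half,
            c_min = c_min, c_max = c_max, exhaustion_tol = exhaustion_tol)
  class(p) <- "life_history_params"
  validate_life_history_params(p)
}

#' Validate a life-history parameter set
#'
#' Checks positivity/range constraints, that \eqn{\beta(c) > 1} for every
#' admissible division rate (required for slow survivorship decay at short
#' times), and that \eqn{\nu(c)} stays within [0, 1] on the admissible
#' range. Both functions are linear so the endpoints suffice.
#'
#' @param p a \code{life_history_params} object or plain list with the same
#'   fields.
#' @return \code{p}, invisibly classed, or an error describing the violated
#'   constraint.
#' @export
validate_life_history_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("s", "delta", "tau", "mu", "T_sur", "beta_b0", "beta_b1",
              "nu_a0", "nu_a1", "R_half", "c_min", "c_max",
              "exhaustion_tol")) {
    if (is.null(p[[f]]) || !num1(p[[f]]))
      stop("life_history_params: field '", f, "' must be a finite number",
           call. = FALSE)
  }
  if (p$s <= 0 || p$s > 1) stop("life_history_params: need 0 < s <= 1",
                                call. = FALSE)
  if (p$delta < 0) stop("life_history_params: delta must be >= 0",
                        call. = FALSE)
  if (p$tau < 0) stop("life_history_params: tau must be >= 0", call. = FALSE)
  if (p$mu <= 0) stop("life_history_params: mu must be > 0", call. = FALSE)
  if (p$T_sur <= 0) stop("life_history_params: T_sur must be > 0",
                         call. = FALSE)
  if (p$R_half <= 0) stop("life_history_params: R_half must be > 0",
                          call. = FALSE)
  if (p$c_min <= 0 || p$c_max < p$c_min)
    stop("life_history_params: need 0 < c_min <= c_max", call. = FALSE)
  if (p$exhaustion_tol <= 0 || p$exhaustion_tol >= 1)
    stop("life_history_params: exhaustion_tol must be in (0, 1)",
         call. = FALSE)
  # beta(c) = b0 - b1*c must exceed 1 everywhere on [c_min, c_max]
  beta_lo <- min(p$beta_b0 - p$beta_b1 * p$c_min,
                 p$beta_b0 - p$beta_b1 * p$c_max)
  if (beta_lo <= 1)
    stop("life_history_params: beta(c) must be > 1 over [c_min, c_max] ",
         "(got min beta = ", signif(beta_lo, 6), "); survivorship requires ",
         "beta > 1", call. = FALSE)
  nu_ends <- c(p$nu_a0 - p$nu_a1 * p$c_min, p$nu_a0 - p$nu_a1 * p$c_max)
  if (min(nu_ends) < 0 || max(nu_ends) > 1)
    stop("life_history_params: nu(c) must lie in [0, 1] over ",
         "[c_min, c_max] (got range ", signif(min(nu_ends), 6), "..",
         signif(max(nu_ends), 6), ")", call. = FALSE)
  if (!inherits(p, "life_history_params")) class(p) <- "life_history_params"
  invisible(p)
}

#' @export
print.life_history_params <- function(x, ...) {
  cat("Life-history parameters:\n")
  cat(sprintf("  spore fraction s = %g, spore death delta = %g /h\n",
              x$s, x$delta))
  cat(sprintf("  germination lag tau = %g h, viability nu(c) = %g - %g c\n",
              x$tau, x$nu_a0, x$nu_a1))
  cat(sprintf("  survivorship: mu = %g /h, T_sur = %g h, beta(c) = %g - %g c\n",
              x$mu, x$T_sur, x$beta_b0, x$beta_b1))
  cat(sprintf("  resources: R_half = %g; division rate c in [%g, %g] /h\n",
              x$R_half, x$c_min, x$c_max))
  invisible(x)
}

#' Provenance of the default parameter values
#'
#' @return named character vector mapping each parameter of
#'   [life_history_params()] to \code{"paper"} (value printed in the source
#'   model description) or \code{"assumed"} (order-of-magnitude placeholder).
#' @export
param_sources <- function() {
  c(s = "paper", delta = "assumed", tau = "assumed", mu = "assumed",
    T_sur = "paper", beta_b0 = "paper", beta_b1 = "paper",
    nu_a0 = "paper", nu_a1 = "paper", R_half = "assumed",
    c_min = "paper", c_max = "paper", exhaustion_tol = "assumed")
}

check_c_range <- function(c, p) {
  tol <- 1e-9
  if (any(c < p$c_min - tol | c > p$c_max + tol))
    stop("division rate c outside the admissible range [", p$c_min, ", ",
         p$c_max, "]", call. = FALSE)
  invisible(TRUE)
}

#' Survivorship-shape cost of fast division
#'
#' The exponent \eqn{\beta(c) = b_0 - b_1 c} of the solitary-cell
#' survivorship family. Larger \eqn{\beta} means a slower initial decay of
#' survival; faster dividers (smaller cells) get smaller \eqn{\beta} and die
#' sooner after starvation sets in.
#'
#' @param c division rate(s), per hour, within the admissible range.
#' @param params a [life_history_params()] object.
#' @return \eqn{\beta(c)}, dimensionless, vectorised over \code{c}.
#' @export
beta_cost <- function(c, params = life_history_params()) {
  check_c_range(c, params)
  b <- params$beta_b0 - params$beta_b1 * c
  if (any(b <= 1))
    stop("beta(c) <= 1 for some admissible c; survivorship requires beta > 1",
         call. = FALSE)
  b
}

#' Spore germination viability
#'
#' The linear viability function \eqn{\nu(c) = a_0 - a_1 c}: the fraction of
#' surviving spores of a genotype with division rate \code{c} that
#' successfully germinate when food returns. Fast dividers make smaller,
#' less viable spores.
#'
#' @inheritParams beta_cost
#' @return viability in [0, 1], vectorised over \code{c}.
#' @export
spore_viability <- function(c, params = life_history_params()) {
  check_c_range(c, params)
  nu <- params$nu_a0 - params$nu_a1 * c
  if (any(nu < -1e-12 | nu > 1 + 1e-12))
    stop("nu(c) outside [0, 1] for some admissible c", call. = FALSE)
  pmin(pmax(nu, 0), 1)
}

#' Solitary-cell survival probability since starvation onset
#'
#' Probability that a starving non-aggregated cell of division rate \code{c}
#' is still alive \code{t} hours after starvation onset:
#' \deqn{S_c(t) = \frac{e^{-(\mu t)^{\beta(c)}} - e^{-(\mu T_{sur})^{\beta(c)}}}
#'                     {1 - e^{-(\mu T_{sur})^{\beta(c)}}}}
#' for \eqn{0 \le t \le T_{sur}} and 0 beyond. The curve is normalised to 1
#' at \code{t = 0} and reaches exactly 0 at the maximum lifetime
#' \code{T_sur}.
#'
#' @inheritParams beta_cost
#' @param t hours since starvation onset (vectorised; recycled against
#'   \code{c}).
#' @return survival probabilities in [0, 1].
#' @export
survival_probability <- function(c, t, params = life_history_params()) {
  if (any(t < 0)) stop("survival_probability: t must be >= 0", call. = FALSE)
  b <- beta_cost(c, params)
  n <- max(length(b), length(t))
  b <- rep_len(b, n); t <- rep_len(t, n)
  K <- exp(-(params$mu * params$T_sur)^b)
  S <- (exp(-(params$mu * t)^b) - K) / (1 - K)
  S[t >= params$T_sur] <- 0
  S[t == 0] <- 1
  pmin(pmax(S, 0), 1)
}

#' Instantaneous death rate of starving solitary cells
#'
#' The hazard \eqn{h_c(t) = -\mathrm{d}\log S_c(t)/\mathrm{d}t} implied by
#' the survivorship family. It vanishes at \code{t = 0} (slow initial decay,
#' \eqn{\beta > 1}) and diverges as \code{t} approaches the maximum lifetime
#' \code{T_sur}, where survival hits zero with finite density. Needed by the
#' continuous aggregation mechanism and by numerical cross-checks of the
#' closed-form survival curve.
#'
#' @inheritParams survival_probability
#' @return hazard in 1/hour; defined for \code{0 <= t < T_sur}.
#' @export
survival_hazard <- function(c, t, params = life_history_params()) {
  if (any(t < 0)) stop("survival_hazard: t must be >= 0", call. = FALSE)
  if (any(t >= params$T_sur))
    stop("survival_hazard: undefined at t >= T_sur (survival is zero)",
         call. = FALSE)
  b <- beta_cost(c, params)
  n <- max(length(b), length(t))
  b <- rep_len(b, n); t <- rep_len(t, n)
  K <- exp(-(params$mu * params$T_sur)^b)
  z <- (params$mu * t)^b
  # -S'/S with S un-normalised numerator e^{-z} - K
  h <- b * params$mu * (params$mu * t)^(b - 1) * exp(-z) / (exp(-z) - K)
  h[t == 0] <- 0
  h
}
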