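#' Instantaneous partitioning at starvation onset (discrete mechanism)
#'
#' When the resource runs out, each discrete-mechanism genotype splits its
#' vegetative population instantaneously: a fraction \code{alpha}
#' aggregates, the rest stays solitary. Of the aggregated cells a fraction
#' \code{s} differentiates into spores and the remaining \code{1 - s} dies
#' building the stalk and leaves the system. The three output pools sum to
#' the vegetative input exactly.
#'
#' @param state a [population_state()] that has just switched to the
#'   starvation phase (vegetative counts still present).
#' @param params a [life_history_params()].
#' @return list with \code{state} (solitary/spore pools filled, vegetative
#'   emptied, stalk removed) and \code{partition}, a data.frame with
#'   per-genotype \code{spores}, \code{solitary} and \code{stalk}.
#' @export
partition_discrete <- function(state, params) {
  stopifnot(inherits(state, "population_state"))
  if (grid_mechanism(state$grid) != "discrete")
    stop("partition_discrete: grid uses the continuous mechanism",
         call. = FALSE)
  if (state$phase != "starvation")
    stop("partition_discrete: state must be at starvation onset",
         call. = FALSE)
  X <- state$vegetative
  alpha <- state$grid$alpha
  spores_new <- params$s * alpha * X
  solitary <- (1 - alpha) * X
  stalk <- (1 - params$s) * alpha * X
  state$spores <- state$spores + spores_new
  state$solitary <- solitary
  state$solitary_onset <- solitary
  state$vegetative <- rep(0, length(X))
  list(state = state,
       partition = data.frame(spores = spores_new, solitary = solitary,
                              stalk = stalk))
}

#' Closed-form starvation mortality (discrete mechanism)
#'
#' During starvation, dormant spores decay exponentially at the constant
#' rate \code{delta}, while solitary cells follow the survivorship curve:
#' the solitary count at time \code{T} after onset equals the onset
#' snapshot times \eqn{S_c(T)}. Both pools are evaluated analytically; no
#' stepping is involved.
#'
#' @param state a [population_state()] in starvation phase, with
#'   \code{solitary_onset} holding the onset snapshot.
#' @param T starvation duration in hours (>= 0).
#' @param params a [life_history_params()].
#' @return the state advanced by \code{T} hours.
#' @export
starve_discrete <- function(state, T, params) {
  stopifnot(inherits(state, "population_state"))
  if (T < 0) stop("starve_discrete: T must be >= 0", call. = FALSE)
  if (state$phase != "starvation")
    stop("starve_discrete: state must be in starvation phase", call. = FALSE)
  if (T == 0) return(state)
  state$spores <- state$spores * exp(-params$delta * T)
  state$solitary <- state$solitary_onset *
    survival_probability(state$grid$c, T, params)
  state$clock <- state$clock + T
  state
}

#' Continuous aggregation during starvation
#'
#' Under the continuous mechanism, starving solitary cells join the
#' aggregate at per-capita rate \code{gamma} while simultaneously dying
#' according to the survivorship hazard; the two processes act
#' independently, so the solitary pool is
#' \eqn{N(t) = N_0 e^{-\gamma t} S_c(t)}. Aggregated cells accumulate as
#' \eqn{\dot A = \gamma N - \delta A} with \eqn{A(0) = 0}; this is
#' evaluated by quadrature of its variation-of-constants solution. A
#' fraction \code{s} of the aggregate counts as spores (the stalk remainder
#' is lost).
#'
#' @param N0 solitary cells at starvation onset (vector, one per genotype).
#' @param gamma aggregation rate(s), per hour, >= 0.
#' @param c division rate(s), per hour.
#' @param t hours since starvation onset (scalar).
#' @param params a [life_history_params()].
#' @return list of vectors \code{solitary}, \code{aggregated} and
#'   \code{spores} (= s * aggregated) at time \code{t}.
#' @export
continuous_starvation <- function(N0, gamma, c, t, params) {
  if (t < 0) stop("continuous_starvation: t must be >= 0", call. = FALSE)
  if (any(gamma < 0))
    stop("continuous_starvation: gamma must be >= 0", call. = FALSE)
  n <- max(length(N0), length(gamma), length(c))
  N0 <- rep_len(N0, n); gamma <- rep_len(gamma, n); c <- rep_len(c, n)
  S_t <- if (t >= params$T_sur) rep(0, n)
         else survival_probability(c, t, params)
  solitary <- N0 * exp(-gamma * t) * S_t
  aggregated <- numeric(n)
  tcap <- min(t, params$T_sur)
  for (i in seq_len(n)) {
    if (gamma[i] == 0 || N0[i] == 0 || tcap == 0) next
    g <- gamma[i]; ci <- c[i]; d <- params$delta
    # substitute v = gamma * u so the integrand is O(1)-scaled for any gamma
    f <- function(v) {
      exp(-v) * survival_probability(ci, v / g, params) * exp(d * v / g)
    }
    upper <- min(g * tcap, 745)   # e^{-745} underflows; tail is negligible
    if (upper <= 0) next
    q <- stats::integrate(f, 0, upper, rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 400L)
    aggregated[i] <- N0[i] * exp(-d * t) * q$value
  }
  list(solitary = solitary, aggregated = aggregated,
       spores = params$s * aggregated)
}

#' Time to complete aggregation (continuous mechanism)
#'
#' The smallest time after starvation onset at which the remaining solitary
#' fraction \eqn{N(t)/N_0 = e^{-\gamma t} S_c(t)} drops below
#' \code{epsilon} -- i.e. when essentially every non-aggregator has either
#' died or joined the aggregate. Always at most \code{T_sur}, where the
#' survivorship vanishes; non-increasing in \code{gamma}.
#'
#' @param g a continuous-mechanism [genotype()] (or any list with fields
#'   \code{gamma} and \code{c}).
#' @param params a [life_history_params()].
#' @param epsilon remaining-fraction threshold in (0, 1).
#' @return hours.
#' @export
aggregation_time <- function(g, params, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 1)
    stop("aggregation_time: epsilon must lie in (0, 1)", call. = FALSE)
  gamma <- g$gamma; c <- g$c
  if (is.null(gamma)) stop("aggregation_time: genotype has no gamma",
                           call. = FALSE)
  frac <- function(t) {
    s <- if (t >= params$T_sur) 0 else survival_probability(c, t, params)
    exp(-gamma * t) * s - epsilon
  }
  if (frac(0) <= 0) return(0)
  stats::uniroot(frac, c(0, params$T_sur), tol = 1e-10)$root
}

#' Germination at a food pulse
#'
#' Spores sense the new resource and germinate over a lag \code{tau}
#' (handled by the cycle driver); on completion a genotype-specific
#' fraction \eqn{\nu(c)} of the spores successfully becomes vegetative and
#' the remainder dies. If no resources are left when the lag completes, the
#' spores stay dormant for the next pulse.
#'
#' @param spores spore counts (vector).
#' @param c matching division rates.
#' @param params a [life_history_params()].
#' @param resources_available logical: is the resource still present when
#'   the germination lag completes?
#' @return list of vectors \code{recruits} (join the vegetative pool),
#'   \code{spores} (remaining dormant pool) and \code{died}.
#' @export
germinate <- function(spores, c, params, resources_available = TRUE) {
  n <- max(length(spores), length(c))
  spores <- rep_len(spores, n); c <- rep_len(c, n)
  if (!resources_available) {
    return(list(recruits = rep(0, n), spores = spores, died = rep(0, n)))
  }
  nu <- spore_viability(c, params)
  list(recruits = nu * spores, spores = rep(0, n),
       died = (1 - nu) * spores)
}
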