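#' Grow from a fresh pulse to resource exhaustion, with germination
#'
#' Internal driver of the growth phase of one cycle. Solitary survivors of
#' the previous starvation are already vegetative (see [apply_pulse()]) and
#' start eating immediately. Dormant spores germinate at \code{tau} hours
#' after the pulse provided the resource has not been exhausted by then;
#' viable recruits join the vegetative pool and growth continues until
#' exhaustion. If the resource runs out within the lag, the spores stay
#' dormant for the next pulse (germination is nutrient-triggered).
#'
#' @param state a [population_state()] in growth phase with the pulse
#'   applied.
#' @param params a [life_history_params()].
#' @return list with \code{state} at starvation onset (phase
#'   "starvation"), \code{growth_duration} in hours, and \code{germinated}
#'   (logical).
#' @keywords internal
grow_with_germination <- function(state, params) {
  germinated <- FALSE
  has_spores <- any(state$spores > 0)
  if (has_spores && params$tau > 0) {
    g1 <- integrate_growth(state, params, t_limit = params$tau)
    state <- g1$state
    dur <- g1$elapsed
    if (state$phase == "growth") {
      germ <- germinate(state$spores, state$grid$c, params,
                        resources_available = TRUE)
      state$vegetative <- state$vegetative + germ$recruits
      state$spores <- germ$spores
      germinated <- TRUE
      g2 <- integrate_growth(state, params)
      state <- g2$state
      dur <- dur + g2$elapsed
    }
  } else {
    if (has_spores) {           # tau = 0: immediate germination
      germ <- germinate(state$spores, state$grid$c, params, TRUE)
      state$vegetative <- state$vegetative + germ$recruits
      state$spores <- germ$spores
      germinated <- TRUE
    }
    g <- integrate_growth(state, params)
    state <- g$state
    dur <- g$elapsed
  }
  if (state$phase != "starvation")
    stop("grow_with_germination: growth phase did not reach exhaustion",
         call. = FALSE)
  list(state = state, growth_duration = dur, germinated = germinated)
}

#' Run one full growth-starvation cycle
#'
#' Composes the growth integration (with germination of carried spores at
#' the pulse-plus-lag instant), the starvation-onset partitioning of the
#' mechanism in use, and the analytic starvation-phase mortality for a
#' starvation period of \code{T} hours. Stalk cells are removed from the
#' system at onset (discrete mechanism) or accounted at measurement
#' (continuous mechanism, where aggregation is gradual).
#'
#' @param state a [population_state()] in growth phase with a fresh
#'   resource pulse applied (see [apply_pulse()]).
#' @param T starvation duration in hours.
#' @param params a [life_history_params()].
#' @return list with \code{state} at the end of the starvation phase
#'   (ready for the next pulse) and \code{record}, a one-row data.frame
#'   (class \code{cycle_record}) with the cycle bookkeeping: clock and
#'   durations, totals at onset, spores/solitary/stalk produced, and
#'   survivors at pulse arrival.
#' @export
run_cycle <- function(state, T, params) {
  stopifnot(inherits(state, "population_state"))
  if (T < 0) stop("run_cycle: T must be >= 0", call. = FALSE)
  if (state$phase != "growth" || state$R <= 0)
    stop("run_cycle: state must be in growth phase with a fresh pulse",
         call. = FALSE)
  mech <- grid_mechanism(state$grid)
  gw <- grow_with_germination(state, params)
  state <- gw$state
  onset_clock <- state$clock
  onset_total <- sum(state$vegetative) + sum(state$spores)
  if (mech == "discrete") {
    pd <- partition_discrete(state, params)
    state <- pd$state
    spores_onset <- sum(pd$partition$spores)
    solitary_onset <- sum(pd$partition$solitary)
    stalk_onset <- sum(pd$partition$stalk)
    state <- starve_discrete(state, T, params)
  } else {
    N0 <- state$vegetative
    state$vegetative <- rep(0, length(N0))
    state$solitary_onset <- N0
    cs <- continuous_starvation(N0, state$grid$gamma, state$grid$c, T,
                                params)
    state$solitary <- cs$solitary
    state$spores <- state$spores * exp(-params$delta * T) + cs$spores
    state$clock <- state$clock + T
    spores_onset <- 0
    solitary_onset <- sum(N0)
    stalk_onset <- (1 - params$s) * sum(cs$aggregated)
  }
  survivors <- sum(state$solitary) + sum(state$spores)
  record <- data.frame(onset_clock = onset_clock,
                       growth_duration = gw$growth_duration,
                       starvation_duration = T,
                       onset_total = onset_total,
                       spores_at_onset = spores_onset,
                       solitary_at_onset = solitary_onset,
                       stalk_at_onset = stalk_onset,
                       survivors_at_pulse = survivors)
  class(record) <- c("cycle_record", "data.frame")
  list(state = state, record = record)
}
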