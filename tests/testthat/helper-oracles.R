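# Independent reference integrators (deSolve on the full, unreduced
# systems). These never share code with the package's solution paths: the
# package reduces growth to one cumulative-growth coordinate and evaluates
# starvation in closed form; the oracles integrate every pool as a state
# variable with a fine-tolerance stiff solver.

# Full consumer-resource system: dX_i = c_i f(R) X_i, dR = -f(R) sum c X,
# stopped at the exhaustion event R <= eps.
oracle_growth <- function(X0, cvec, R0, params, t_max = 1e6) {
  total0 <- sum(X0) + R0
  eps <- params$exhaustion_tol * R0
  deriv <- function(t, y, parms) {
    X <- y[-length(y)]
    R <- y[length(y)]
    f <- max(R, 0) / (params$R_half + max(R, 0))
    list(c(cvec * f * X, -f * sum(cvec * X)))
  }
  rootf <- function(t, y, parms) y[length(y)] - eps
  out <- deSolve::lsodar(y = c(X0, R = R0), times = c(0, t_max),
                         func = deriv, rootfunc = rootf,
                         rtol = 1e-11, atol = 1e-11 * total0,
                         maxsteps = 5e5)
  last <- out[nrow(out), ]
  list(X = unname(last[2:(1 + length(X0))]), R = unname(last[length(last)]),
       elapsed = unname(last[1]))
}

# Solitary-cell decline as a hazard ODE: dN/dt = -h_c(t) N.
oracle_starve_solitary <- function(N0, c, T, params) {
  deriv <- function(t, y, parms)
    list(-survival_hazard(c, t, params) * y[1])
  out <- deSolve::lsoda(y = c(N = N0), times = c(0, T), func = deriv,
                        rtol = 1e-10, atol = 1e-10 * max(N0, 1))
  unname(out[nrow(out), 2])
}

# Continuous aggregation during starvation:
# dN/dt = -(gamma + h_c(t)) N,  dA/dt = gamma N - delta A.
oracle_continuous <- function(N0, gamma, c, T, params) {
  deriv <- function(t, y, parms) {
    h <- if (t >= params$T_sur) 0 else survival_hazard(c, t, params)
    list(c(-(gamma + h) * y[1], gamma * y[1] - params$delta * y[2]))
  }
  Tcap <- min(T, params$T_sur * (1 - 1e-9))
  out <- deSolve::lsoda(y = c(N = N0, A = 0), times = c(0, Tcap),
                        func = deriv, rtol = 1e-10,
                        atol = 1e-12 * max(N0, 1), maxsteps = 2e5)
  last <- out[nrow(out), ]
  N <- unname(last[2]); A <- unname(last[3])
  if (T >= params$T_sur) {
    # beyond the maximum lifetime every solitary cell is dead; the
    # aggregate keeps decaying at delta
    A <- A * exp(-params$delta * (T - Tcap))
    N <- 0
  }
  list(N = N, A = A)
}
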