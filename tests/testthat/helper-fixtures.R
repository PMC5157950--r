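# Shared fixtures: default parameters and small genotype grids, built in
# code at test time.

default_params <- function(...) life_history_params(...)

# the desk-scale competition grid: 9 alpha values x 5 division rates
reduced_grid <- function() {
  build_genotype_grid(
    genotype_grid_spec("discrete", c(0, 1, 0.125), c(0.05, 0.45, 0.1)))
}

make_grid <- function(alpha, c) {
  grid <- data.frame(alpha = alpha, c = c)
  attr(grid, "mechanism") <- "discrete"
  class(grid) <- c("genotype_grid", "data.frame")
  grid
}

# a winner-like genotype set shaped like the stochastic-environment sweep:
# fast-environment winners (alpha = 0), intermediate ones (alpha rising
# while c falls), and slow ones (alpha = 1 with c rising again)
winnerlike_set <- function() {
  make_grid(alpha = c(0, 0, 0.25, 0.5, 0.75, 1, 1),
            c = c(0.05, 0.15, 0.4, 0.3, 0.2, 0.3, 0.4))
}
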