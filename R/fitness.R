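#' Gaussian stabilizing-selection fitness
#'
#' Fitness of an individual with trait value `z` under stabilizing selection
#' around the optimum `z_opt`:
#' \deqn{w = \exp\left(-\frac{(z - z_{opt})^2}{2 V_S}\right)}
#' so `w = 1` exactly at the optimum and `V_S` sets how quickly fitness
#' decays with distance from it (larger `V_S` = weaker selection).
#'
#' @param z Trait value(s).
#' @param z_opt Optimum trait value.
#' @param V_S Width of the fitness function (must be positive).
#' @return Fitness value(s) in `(0, 1]`.
#' @examples
#' gaussian_fitness(0, 0, 1)    # 1 at the optimum
#' gaussian_fitness(1, 0, 50)   # ~0.99 under weak selection
#' @export
gaussian_fitness <- function(z, z_opt, V_S) {
  if (!is.numeric(V_S) || length(V_S) != 1L || V_S <= 0)
    stop("V_S must be a single positive number")
  exp(-(z - z_opt)^2 / (2 * V_S))
}

#' Truncation selection on a fitness distribution
#'
#' Assigns fitness 1 to the top half of the population ranked by Gaussian
#' fitness `w` and 0 to the rest. Exactly `ceiling(n / 2)` individuals
#' survive; ties at the median fitness are broken by stable index order
#' (earlier index wins), making the assignment deterministic.
#'
#' @param fitnesses Numeric vector of (Gaussian) fitness values.
#' @return Integer vector of 0/1 of the same length.
#' @examples
#' truncation_fitness(c(0.9, 0.5, 0.7, 0.1))  # 1 0 1 0
#' @export
truncation_fitness <- function(fitnesses) {
  if (length(fitnesses) == 0L) stop("empty fitness vector")
  n <- length(fitnesses)
  k <- ceiling(n / 2)
  ord <- order(-fitnesses)  # stable in R: ties keep index order
  out <- integer(n)
  out[ord[seq_len(k)]] <- 1L
  out
}

#' Draw effect sizes for new mutations
#'
#' New mutations draw their trait effect from a zero-mean Gaussian with
#' standard deviation `sigma_m`, so positive and negative effects are
#' equally likely and `sigma_m` controls how coarse the mutational input
#' to the trait is.
#'
#' @param n Number of draws.
#' @param sigma_m Standard deviation of effect sizes (positive).
#' @return Numeric vector of effect sizes.
#' @export
draw_effect_size <- function(n, sigma_m) {
  if (!is.numeric(sigma_m) || length(sigma_m) != 1L || sigma_m <= 0)
    stop("sigma_m must be a single positive number")
  stats::rnorm(n, mean = 0, sd = sigma_m)
}
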