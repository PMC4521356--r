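# Shared helpers and independent oracles used across the suite.

hold_neuron <- function() neuron_model(equations = "r = r")

rate_neuron <- function(tau = 10) {
  neuron_model(parameters = sprintf("tau = %g : population", tau),
               equations = "tau * dr/dt + r = sum(exc)")
}

# Passive spiking receiver with an exponentially decaying conductance.
receiver_neuron <- function(tau = 5) {
  neuron_model(
    parameters = sprintf("tau = %g : population", tau),
    equations = "tau * dg_exc/dt = -g_exc : exponential
                 dv/dt = 0.0",
    spike = "v > 1e9")
}

pop_state <- function(pop) pop[["storage"]]

# Dense reference integration of a linear scalar ODE dx/dt = a x + b from
# x0 over `elapsed` ms with exponential-Euler steps of `h` ms.
dense_linear <- function(x0, a, b, elapsed, h = 0.001) {
  n <- floor(elapsed / h)
  x <- x0
  for (i in seq_len(n)) {
    if (a == 0) x <- x + h * b
    else {
      xs <- -b / a
      x <- xs + (x - xs) * exp(a * h)
    }
  }
  rem <- elapsed - n * h
  if (rem > 0) {
    if (a == 0) x <- x + rem * b
    else {
      xs <- -b / a
      x <- xs + (x - xs) * exp(a * rem)
    }
  }
  x
}

# Brute-force 2-D convolution oracle (zero padding), matrices indexed by
# 0-based row-major population coordinates: img[x+1, y+1].
brute_conv2 <- function(img, K) {
  nx <- nrow(img); ny <- ncol(img)
  d1 <- (nrow(K) - 1) / 2; d2 <- (ncol(K) - 1) / 2
  out <- matrix(0, nx, ny)
  for (x in 0:(nx - 1)) for (y in 0:(ny - 1)) {
    s <- 0
    for (i in -d1:d1) for (j in -d2:d2) {
      xx <- x - i; yy <- y - j
      if (xx >= 0 && xx < nx && yy >= 0 && yy < ny) {
        s <- s + K[i + d1 + 1, j + d2 + 1] * img[xx + 1, yy + 1]
      }
    }
    out[x + 1, y + 1] <- s
  }
  out
}

# Write a row-major image matrix (img[x+1, y+1] at coordinate (x, y)) into a
# population with geometry c(nx, ny).
set_image <- function(pop, img) {
  set_attribute(pop, "r", as.vector(t(img)))
}

get_image <- function(pop) {
  g <- pop[["geometry"]]
  matrix(get_attribute(pop, "r"), g[1], g[2], byrow = TRUE)
}
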