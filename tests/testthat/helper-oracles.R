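# Independent fixed-step integrators and small numeric utilities used as
# oracles; deliberately simple and separate from the package's solvers.

rk4_integrate <- function(f, y0, times) {
  y <- matrix(NA_real_, length(times), length(y0))
  colnames(y) <- names(y0)
  y[1, ] <- y0
  for (i in seq_len(length(times) - 1L)) {
    h <- times[i + 1] - times[i]
    t <- times[i]
    yi <- y[i, ]
    k1 <- f(t, yi)
    k2 <- f(t + h / 2, yi + h / 2 * k1)
    k3 <- f(t + h / 2, yi + h / 2 * k2)
    k4 <- f(t + h, yi + h * k3)
    y[i + 1, ] <- yi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# max abs difference between matrices, relative to the per-column scale
rel_err <- function(a, b) {
  sc <- pmax(apply(abs(b), 2, max), 1e-12)
  max(sweep(abs(a - b), 2, sc, "/"))
}
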