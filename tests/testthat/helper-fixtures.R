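# Shared fixture builders: everything is generated in code at test time.

random_map <- function(dims = c(5, 5, 5), width = 2, origin = c(0, 0, 0),
                       seed = NULL, positive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  v <- stats::rnorm(prod(dims))
  if (positive) v <- abs(v)
  volume_map(v, width = width, origin = origin, dims = dims)
}

# smooth blob map: Gaussian bump centered in the box
blob_map <- function(dims = c(12, 12, 12), width = 2, center = NULL,
                     sigma = 6) {
  if (is.null(center)) center <- (dims - 1) / 2 * width
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * width)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  r2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  volume_map(exp(-r2 / (2 * sigma^2)), width = width, origin = c(0, 0, 0),
             dims = dims)
}

random_model <- function(n = 30, spread = 10, seed = 1) {
  set.seed(seed)
  atomic_model(stats::rnorm(n, sd = spread), stats::rnorm(n, sd = spread),
               stats::rnorm(n, sd = spread))
}

# brute-force Situs CC for the oracle tests
cc_brute <- function(a, b) {
  s <- 0; na <- 0; nb <- 0
  for (i in seq_len(a$dims[1])) for (j in seq_len(a$dims[2]))
    for (k in seq_len(a$dims[3])) {
      s <- s + a$data[i, j, k] * b$data[i, j, k]
      na <- na + a$data[i, j, k]^2
      nb <- nb + b$data[i, j, k]^2
    }
  s / sqrt(na * nb)
}

# small shared hexamer fixture, built once per test run
hexamer_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_hexamer_map(seed = 2)
    cache
  }
})
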