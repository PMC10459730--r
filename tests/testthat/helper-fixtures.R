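# Small shared fixtures, built in code at test time.

# Tiny leaf-world dataset cached per session (90 samples, 120 bands).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(sim_config(n_samples = 90, n_bands = 120,
                                            seed = 42))
    }
    cache
  }
})

# Deterministic small regression instance: y linear in a few columns.
linear_instance <- function(n = 40, p = 6, informative = 1:2, seed = 7) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, informative, drop = FALSE] %*% seq_along(informative))
    list(X = X, y = y)
  })
}

# Brute-force two-sided Mann-Whitney p by full enumeration of group
# assignments (independent of the implementation's internal path).
mw_bruteforce <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

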