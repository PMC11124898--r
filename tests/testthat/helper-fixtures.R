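# Shared fixtures, memoized so expensive simulations run once per session.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small balanced feature table straight from the simulator.
sim_feature_table <- function(environment, n_per_class, seed) {
  fixture(sprintf("tab_%s_%d_%d", environment, n_per_class, seed), function() {
    env <- environment_config(environment)
    extract_features(simulate_dataset(n_per_class, env, seed = seed))
  })
}

# Hand-built raw record with constant resistances (x_t should be 1).
constant_record <- function(r = 10000, r_rec = r) {
  sensors <- sensor_specs()$sensor_id
  structure(list(
    sample_id = "const", class_label = "normal", environment = "laboratory",
    preclean = matrix(r, 12, 60, dimnames = list(sensors, NULL)),
    resistance = matrix(r_rec, 12, 180, dimnames = list(sensors, NULL))),
    class = "enose_record")
}

# Feature table from plain numeric columns (for selection/discretization
# tests that need controlled values).
toy_table <- function(values, labels) {
  stopifnot(is.list(values))
  data.frame(sample_id = paste0("s", seq_along(labels)),
             label = labels, environment = "laboratory",
             values, stringsAsFactors = FALSE, check.names = FALSE)
}

# Literal four-loop plug-in MI in bits over two small code vectors.
brute_mi <- function(a, b) {
  n <- length(a)
  ua <- sort(unique(a)); ub <- sort(unique(b))
  total <- 0
  for (va in ua) for (vb in ub) {
    pxy <- sum(a == va & b == vb) / n
    if (pxy > 0) {
      px <- sum(a == va) / n
      py <- sum(b == vb) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

# Direct O(T^2) discrete Fourier transform magnitudes (one-sided, DC
# excluded), the independent oracle for the frequency-domain features.
brute_dft_mags <- function(x) {
  T <- length(x)
  ks <- seq_len(T %/% 2)
  vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(T) - 1) / T))
    im <- sum(x * sin(-2 * pi * k * (seq_len(T) - 1) / T))
    sqrt(re^2 + im^2)
  }, 0)
}

# Linear-scan segment assigner: the oracle for discretization tags.
brute_assign <- function(value, breakpoints) {
  tag <- 1L
  for (b in breakpoints) if (value >= b) tag <- tag + 1L
  tag
}

# A linearly separable toy classification set for capacity checks.
toy_separable <- function(n = 60, width = 20, seed = 1) {
  set.seed(seed)
  stopifnot(width >= 6)
  y <- factor(rep(c("a", "b", "c"), length.out = n))
  x <- matrix(rnorm(n * width, 0, 0.1), n, width)
  left <- 1:floor(width / 3)
  right <- (width - floor(width / 3) + 1):width
  x[y == "b", left] <- x[y == "b", left] + 1
  x[y == "c", right] <- x[y == "c", right] + 1
  list(x = x, y = y)
}
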