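# Shared fixtures and independent oracles, built in code at test time.

# Analytic fringe positions of the noiseless two-beam signal: maxima of
# 1 + cos(4*pi*n*l/lambda) sit at lambda_m = 2*n*l/m for integer order m.
# Enumerates every lambda_m strictly inside (lo, hi), increasing.
analytic_maxima <- function(n, l_um, lo, hi) {
  opl <- 2 * n * l_um * 1000  # 2nl in nm
  m_lo <- ceiling(opl / hi + 1e-9)
  m_hi <- floor(opl / lo - 1e-9)
  if (m_lo > m_hi) return(numeric(0))
  sort(opl / seq(m_lo, m_hi))
}

# Exhaustive neighbour-comparison peak scan (plateaus once, leftmost),
# independent of the package's run-length implementation.
brute_force_maxima <- function(w, p) {
  hits <- integer(0)
  i <- 2L
  while (i <= length(p) - 1L) {
    if (p[i] > p[i - 1L]) {
      j <- i
      while (j < length(p) && p[j + 1L] == p[i]) j <- j + 1L
      if (j < length(p) && p[j + 1L] < p[i]) hits <- c(hits, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(wavelength = w[hits], power = p[hits])
}

# Small labeled dataset with the full F1..F18 layout where F1 separates the
# classes by `gap`; used for classifier unit tests.
toy_dataset <- function(n_per_class = 10L, gap = 5, noise = 0.1, seed = 99L) {
  set.seed(seed)
  n <- 2L * n_per_class
  feats <- as.data.frame(matrix(rnorm(n * 17L, sd = noise), n, 17L))
  names(feats) <- paste0("F", 1:17)
  cls <- rep(c(0L, 1L), each = n_per_class)
  feats$F1 <- feats$F1 + gap * cls
  feats$F18 <- NA_integer_
  feats$label_index <- ifelse(cls == 0L, 1.35, 1.45)
  build_dataset(feats, ifelse(cls == 0L, 1.35, 1.45))
}

# Coarse, fast cavity model for pipeline-level tests.
small_model <- function(...) {
  cavity_model(wavelength_grid = default_wavelength_grid(n = 401L), ...)
}

classical_families <- c("random-forest", "gradient-boosted-trees",
                        "gaussian-naive-bayes")
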