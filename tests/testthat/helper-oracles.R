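# Independent brute-force oracles, written as plain scalar transliterations
# of the textbook formulas, kept deliberately separate from the package's
# vectorized implementations.

# Thornthwaite PET for one year of 12 monthly temperatures, scalar loops
oracleThornthwaite <- function(tmp12, latitude) {
  midJ <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  ndm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  I <- 0
  for (m in 1:12) {
    t <- max(tmp12[m], 0)
    I <- I + (t / 5)^1.514
  }
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  pet <- numeric(12)
  for (m in 1:12) {
    t <- tmp12[m]
    delta <- 0.4093 * sin(2 * pi * midJ[m] / 365 - 1.405)
    arg <- -tan(latitude * pi / 180) * tan(delta)
    arg <- min(1, max(-1, arg))
    N <- 24 / pi * acos(arg)
    K <- (N / 12) * (ndm[m] / 30)
    u <- if (t <= 0) 0
         else if (t < 26.5) 16 * (10 * t / I)^a
         else -415.85 + 32.24 * t - 0.43 * t^2
    pet[m] <- max(u, 0) * K
  }
  pet
}

# rolling k-sum with NA propagation, scalar loops
oracleRollSum <- function(d, k) {
  n <- length(d)
  out <- rep(NA_real_, n)
  for (m in k:n) {
    s <- 0
    bad <- FALSE
    for (j in (m - k + 1):m) {
      if (is.na(d[j])) bad <- TRUE else s <- s + d[j]
    }
    out[m] <- if (bad) NA_real_ else s
  }
  out
}

# quantile function of the 3-parameter log-logistic (for sampling)
oracleQll <- function(u, alpha, beta, gam) {
  gam + alpha * (u / (1 - u))^(1 / beta)
}

# per-class means by explicit loop
oracleZonalMeans <- function(field, classes) {
  labs <- sort(unique(as.vector(classes)))
  out <- numeric(0)
  for (L in labs) {
    tot <- 0; nn <- 0
    for (i in seq_along(field)) {
      if (!is.na(field[i]) && classes[i] == L) {
        tot <- tot + field[i]; nn <- nn + 1
      }
    }
    out[as.character(L)] <- tot / nn
  }
  out
}

# Gaussian random field values at given points, exponential covariance
oracleGaussianField <- function(xy, range, nfields = 1) {
  D <- as.matrix(dist(xy))
  L <- chol(exp(-D / range) + diag(1e-8, nrow(xy)))
  t(L) %*% matrix(rnorm(nrow(xy) * nfields), nrow(xy), nfields)
}

# a small ClimateSeries with sinusoidal climate, no noise
toyClimate <- function(years = 3, startYear = 2001, lat = 26) {
  mon <- rep(1:12, years)
  yr <- rep(startYear + seq_len(years) - 1, each = 12)
  climateSeries("TOY", lat, 106, 1100, yr, mon,
                tmp = 15 + 9 * cos(2 * pi * (mon - 7) / 12),
                pre = c(30, 35, 50, 90, 140, 180, 195, 165, 105, 65,
                        40, 35)[mon])
}

# construct an SpeiSeries directly from a numeric vector (for event tests)
speiFromValues <- function(values, startYear = 2001, startMonth = 1) {
  ym <- ymCode(startYear, startMonth) + seq_along(values) - 1L
  methods::new("SpeiSeries", ym = as.integer(ym),
               spei = as.numeric(values), k = 6L,
               params = vector("list", 12),
               calibration = if (length(ym)) as.integer(range(ym))
                             else c(0L, 0L))
}
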