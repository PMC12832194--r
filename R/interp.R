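## Station-to-grid interpolation: inverse-distance weighting and ordinary
## kriging with a WLS-fitted exponential variogram.

#' Grid specification helper
#' @param nrow,ncol grid dimensions.
#' @param cellsize cell edge length.
#' @param origin numeric length-2 lower-left corner (x, y).
#' @return list with the cell-centre coordinate matrix \code{xy}
#'   (ncell x 2, row-major over the grid) and the geometry fields.
#' @export
gridSpec <- function(nrow = 60L, ncol = 60L, cellsize = 250,
                     origin = c(0, 0)) {
  xs <- origin[1] + (seq_len(ncol) - 0.5) * cellsize
  ys <- origin[2] + (seq_len(nrow) - 0.5) * cellsize
  xy <- cbind(x = rep(xs, each = nrow), y = rep(ys, times = ncol))
  list(nrow = as.integer(nrow), ncol = as.integer(ncol),
       cellsize = cellsize, origin = origin, xy = xy)
}

.pairDist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Inverse-distance weighted interpolation
#'
#' Weighted mean with weights \code{1/d^power}; a cell colocated with a
#' station (distance below \code{tol}) takes that station's value exactly.
#' Predictions are bounded by the station value range.
#'
#' @param stations data.frame with columns \code{x}, \code{y},
#'   \code{value}; duplicate coordinates are an error.
#' @param grid a \code{\link{gridSpec}}.
#' @param power inverse-distance exponent (default 2).
#' @param tol colocated-station distance tolerance.
#' @return numeric matrix (\code{grid$nrow} x \code{grid$ncol}).
#' @export
idw <- function(stations, grid, power = 2, tol = 1e-9) {
  stations <- stations[!is.na(stations$value), , drop = FALSE]
  stopifnot(nrow(stations) >= 1L)
  if (anyDuplicated(stations[, c("x", "y")]))
    stop("duplicate station coordinates")
  D <- .pairDist(grid$xy, as.matrix(stations[, c("x", "y")]))
  W <- 1 / pmax(D, tol)^power
  pred <- as.vector(W %*% stations$value) / rowSums(W)
  hit <- D < tol
  if (any(hit)) {
    j <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    pred[!is.na(j)] <- stations$value[j[!is.na(j)]]
  }
  matrix(pred, grid$nrow, grid$ncol)
}

#' Exponential semivariogram function
#' @param h distances.
#' @param model a \code{\linkS4class{VariogramModel}}.
#' @return semivariance values; \code{gamma(0) = nugget} by convention
#'   here (the nugget acts between distinct points).
#' @export
variogramValues <- function(h, model) {
  ifelse(h == 0, 0, model@nugget + model@psill * (1 - exp(-h / model@range)))
}

#' Fit an exponential variogram by weighted least squares
#'
#' Empirical semivariances on equal-width distance bins up to half the
#' maximum station separation, then a WLS fit (weights \code{np/h^2},
#' gstat's default weighting) of \eqn{nugget + psill(1 - e^{-h/range})}.
#'
#' A single field realization yields notoriously variable range
#' estimates; when replicate time slices are available (\code{values}),
#' per-pair semivariances are pooled across slices before binning, which
#' is how a variogram is fitted from the pipeline's monthly fields.
#'
#' @param stations data.frame with \code{x}, \code{y} and (for a single
#'   slice) \code{value}; at least 10 stations.
#' @param nbins number of distance bins (default 15).
#' @param values optional numeric matrix (stations x slices) of replicate
#'   field values overriding \code{stations$value}.
#' @return a \code{\linkS4class{VariogramModel}}; an all-equal value set
#'   yields a pure-nugget (zero) model with a warning.
#' @export
fitVariogram <- function(stations, nbins = 15L, values = NULL) {
  if (is.null(values)) values <- cbind(stations$value)
  values <- as.matrix(values)
  ok <- stats::complete.cases(values)
  stations <- stations[ok, , drop = FALSE]
  values <- values[ok, , drop = FALSE]
  if (nrow(stations) < 10L) stop("need at least 10 stations")
  xy <- as.matrix(stations[, c("x", "y")])
  v <- as.vector(values)
  if (stats::var(v) == 0) {
    warning("all station values equal: pure-nugget (degenerate) variogram")
    return(new("VariogramModel", nugget = 0, psill = 0,
               range = max(.pairDist(xy, xy)) / 3 + 1e-9,
               empirical = data.frame(dist = numeric(), gamma = numeric(),
                                      np = integer())))
  }
  D <- .pairDist(xy, xy)
  G <- 0
  for (j in seq_len(ncol(values)))
    G <- G + 0.5 * outer(values[, j], values[, j], function(a, b) (a - b)^2)
  G <- G / ncol(values)
  iu <- upper.tri(D)
  h <- D[iu]; g <- G[iu]
  cutoff <- max(h) / 2
  keep <- h <= cutoff & h > 0
  h <- h[keep]; g <- g[keep]
  bins <- cut(h, breaks = seq(0, cutoff, length.out = nbins + 1L),
              include.lowest = TRUE)
  emp <- data.frame(
    dist = as.numeric(tapply(h, bins, mean)),
    gamma = as.numeric(tapply(g, bins, mean)),
    np = as.integer(tapply(g, bins, length)))
  emp <- emp[!is.na(emp$gamma) & emp$np > 0, ]
  svar <- stats::var(v)
  obj <- function(par) {
    n0 <- par[1]^2; ps <- par[2]^2; rg <- abs(par[3]) + 1e-9
    fit <- n0 + ps * (1 - exp(-emp$dist / rg))
    sum(emp$np / emp$dist^2 * (emp$gamma - fit)^2)
  }
  start <- c(sqrt(svar * 0.1), sqrt(svar * 0.9), cutoff / 3)
  op <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  new("VariogramModel", nugget = op$par[1]^2, psill = op$par[2]^2,
      range = abs(op$par[3]) + 1e-9, empirical = emp)
}

#' Ordinary kriging to a grid
#'
#' Solves the standard ordinary-kriging system (covariances from the
#' exponential model, Lagrange multiplier enforcing weights summing to 1)
#' once per grid, predicting every cell. Exact at stations when the nugget
#' is zero. On a singular system the station coordinates are jittered once
#' and the solve retried, then an error is raised.
#'
#' @param stations data.frame with \code{x}, \code{y}, \code{value}.
#' @param grid a \code{\link{gridSpec}}.
#' @param model a \code{\linkS4class{VariogramModel}}.
#' @return list with matrices \code{prediction} and \code{variance}
#'   (kriging variance, >= 0 up to numerical tolerance) and
#'   \code{weightSums} (per-cell sum of kriging weights, = 1).
#' @export
ordinaryKriging <- function(stations, grid, model) {
  stations <- stations[!is.na(stations$value), , drop = FALSE]
  n <- nrow(stations)
  stopifnot(n >= 2L, is(model, "VariogramModel"))
  if (anyDuplicated(stations[, c("x", "y")]))
    stop("duplicate station coordinates")
  xy <- as.matrix(stations[, c("x", "y")])
  sill <- model@nugget + model@psill
  covOf <- function(h) {
    # covariance C(h) = sill - gamma(h); C(0) = sill (nugget discontinuity)
    ifelse(h == 0, sill,
           model@psill * exp(-h / model@range))
  }
  buildSolve <- function(xy) {
    C <- covOf(.pairDist(xy, xy))
    A <- rbind(cbind(C, 1), c(rep(1, n), 0))
    c0 <- covOf(.pairDist(xy, grid$xy))       # n x ncell
    B <- rbind(c0, 1)
    solve(A, B)
  }
  lambda <- tryCatch(buildSolve(xy), error = function(e) NULL)
  if (is.null(lambda)) {
    jit <- xy + stats::runif(length(xy), -1e-6, 1e-6) * grid$cellsize
    lambda <- tryCatch(buildSolve(jit), error = function(e)
      stop("kriging system singular even after jitter"))
    xy <- jit
  }
  w <- lambda[seq_len(n), , drop = FALSE]
  mu <- lambda[n + 1L, ]
  pred <- as.vector(crossprod(w, stations$value))
  c0 <- covOf(.pairDist(xy, grid$xy))
  krigVar <- sill - colSums(w * c0) - mu
  krigVar <- pmax(krigVar, 0)
  # zero-nugget exactness: snap colocated cells to the station value
  D <- .pairDist(grid$xy, xy)
  hit <- which(D < 1e-9, arr.ind = TRUE)
  if (nrow(hit) && model@nugget == 0) {
    pred[hit[, 1]] <- stations$value[hit[, 2]]
    krigVar[hit[, 1]] <- 0
  }
  list(prediction = matrix(pred, grid$nrow, grid$ncol),
       variance = matrix(krigVar, grid$nrow, grid$ncol),
       weightSums = matrix(colSums(w), grid$nrow, grid$ncol))
}
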