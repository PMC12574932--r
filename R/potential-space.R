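# Step 1: delineate the potential space -- the cells where arable fields may
# be placed -- either from synthetic fractal gradient noise (a terrain
# surrogate) or from a real land-cover map via a logistic suitability model.

#' Fractal gradient noise parameters
#'
#' Controls for the multi-octave Perlin (lattice gradient) noise field used
#' as a terrain surrogate. `frequency` is the number of base-lattice cycles
#' across the longer grid side; each further octave multiplies the frequency
#' by `lacunarity` and the amplitude by `gain`, adding progressively finer
#' detail.
#'
#' @param frequency base cycles per grid span, > 0. Default 4.
#' @param octaves number of noise layers summed, >= 1. Default 3.
#' @param lacunarity per-octave frequency multiplier, > 1. Default 2.
#' @param gain per-octave amplitude multiplier in (0, 1). Default 0.5.
#' @param seed integer seed; the same seed always yields the same field.
#' @return list of class `perlin_params`.
#' @export
perlin_params <- function(frequency = 4, octaves = 3, lacunarity = 2,
                          gain = 0.5, seed = 1L) {
  stopifnot(frequency > 0, octaves >= 1, lacunarity > 1, gain > 0, gain < 1)
  structure(list(frequency = frequency, octaves = as.integer(octaves),
                 lacunarity = lacunarity, gain = gain, seed = as.integer(seed)),
            class = "perlin_params")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# one octave of classic 2-D Perlin noise, vectorised over the whole grid.
# X, Y are coordinate matrices in lattice units; gradients are unit vectors
# at random angles on the integer lattice drawn from the current RNG stream.
perlin_octave <- function(X, Y) {
  xi <- floor(X); yi <- floor(Y)
  xf <- X - xi; yf <- Y - yi
  nx <- max(xi) + 2L; ny <- max(yi) + 2L
  ang <- matrix(runif(ny * nx, 0, 2 * pi), ny, nx)
  gx <- cos(ang); gy <- sin(ang)
  # linear indices of the four lattice corners around each cell (1-based)
  i00 <- (yi + 1) + ny * (xi)
  i10 <- i00 + ny        # x + 1
  i01 <- i00 + 1         # y + 1
  i11 <- i10 + 1
  n00 <- gx[i00] * xf + gy[i00] * yf
  n10 <- gx[i10] * (xf - 1) + gy[i10] * yf
  n01 <- gx[i01] * xf + gy[i01] * (yf - 1)
  n11 <- gx[i11] * (xf - 1) + gy[i11] * (yf - 1)
  u <- xf^3 * (xf * (xf * 6 - 15) + 10)   # quintic fade
  v <- yf^3 * (yf * (yf * 6 - 15) + 10)
  nx0 <- n00 + u * (n10 - n00)
  nx1 <- n01 + u * (n11 - n01)
  nx0 + v * (nx1 - nx0)
}

#' Synthetic slope map from fractal gradient noise
#'
#' Generates a smooth pseudo-random surface by summing `octaves` layers of
#' lattice gradient (Perlin) noise and min-max rescales it to slope degrees
#' in \[0, 90\]. Every generated map therefore attains 0 and 90 somewhere.
#' Low values are read as gentle (farmable) terrain by the categorisation
#' functions. Deterministic given `params$seed`.
#'
#' @param nrow,ncol grid dimensions.
#' @param params a [perlin_params] object.
#' @param resolution cell size in meters (metadata only). Default 10.
#' @return continuous [ag_grid] with values in \[0, 90\].
#' @examples
#' s <- generate_perlin_slope(64, 64, perlin_params(seed = 42))
#' range(s$values)
#' @export
generate_perlin_slope <- function(nrow, ncol, params = perlin_params(),
                                  resolution = 10) {
  stopifnot(inherits(params, "perlin_params"), nrow >= 1, ncol >= 1)
  span <- max(nrow, ncol)
  col0 <- matrix(rep(seq_len(ncol) - 0.5, each = nrow), nrow, ncol)
  row0 <- matrix(rep(seq_len(nrow) - 0.5, times = ncol), nrow, ncol)
  out <- with_seed(params$seed, {
    acc <- matrix(0, nrow, ncol)
    freq <- params$frequency
    amp <- 1
    for (o in seq_len(params$octaves)) {
      acc <- acc + amp * perlin_octave(col0 / span * freq, row0 / span * freq)
      freq <- freq * params$lacunarity
      amp <- amp * params$gain
    }
    acc
  })
  rng <- range(out)
  if (rng[2] > rng[1]) {
    out <- (out - rng[1]) / (rng[2] - rng[1]) * 90
  } else {
    out[] <- 45   # degenerate flat field
  }
  ag_grid(out, resolution = resolution)
}

#' Potential space
#'
#' A binary mask of cells available for field placement (1 = available),
#' optionally carrying the continuous source map it was derived from.
#'
#' @param mask binary [ag_grid].
#' @param source_map optional continuous [ag_grid] with the same shape.
#' @param provenance one of `"perlin_threshold"`, `"perlin_share"`,
#'   `"hybrid"`, `"external"`.
#' @return object of class `ag_potential_space`.
#' @export
potential_space <- function(mask, source_map = NULL,
                            provenance = c("external", "perlin_threshold",
                                           "perlin_share", "hybrid")) {
  stopifnot_grid(mask)
  stopifnot_binary(mask)
  provenance <- match.arg(provenance)
  if (!is.null(source_map)) {
    stopifnot_grid(source_map)
    if (source_map$nrow != mask$nrow || source_map$ncol != mask$ncol)
      stop("source_map shape must match mask", call. = FALSE)
  }
  structure(list(mask = mask, source_map = source_map,
                 provenance = provenance),
            class = "ag_potential_space")
}

#' @export
print.ag_potential_space <- function(x, ...) {
  n <- sum(!is.na(x$mask$values))
  k <- sum(x$mask$values == 1, na.rm = TRUE)
  cat(sprintf("<ag_potential_space> %d x %d, %.1f%% available (%s)\n",
              x$mask$nrow, x$mask$ncol, 100 * k / n, x$provenance))
  invisible(x)
}

#' Categorise a slope map into potential space
#'
#' `categorize_by_threshold()` marks every cell at or below a slope
#' threshold as available (gentle terrain is farmable).
#' `categorize_by_share()` instead marks the requested share of cells with
#' the lowest slope values; the realised share is within one cell of the
#' request, and ties are broken by row-major scan order so the result is
#' deterministic.
#'
#' @param slope_map continuous [ag_grid] with values in \[0, 90\].
#' @param threshold slope threshold in degrees, within \[0, 90\].
#' @return an `ag_potential_space`.
#' @examples
#' s <- generate_perlin_slope(32, 32, perlin_params(seed = 7))
#' ps <- categorize_by_share(s, 0.6)
#' mean(ps$mask$values)
#' @export
categorize_by_threshold <- function(slope_map, threshold) {
  stopifnot_grid(slope_map)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 90)
    stop("`threshold` must be a single value in [0, 90]", call. = FALSE)
  m <- slope_map$values
  mask <- ifelse(is.na(m), NA_real_, as.numeric(m <= threshold))
  potential_space(ag_grid(mask, slope_map$resolution), slope_map,
                  "perlin_threshold")
}

#' @rdname categorize_by_threshold
#' @param share fraction of valid cells to make available, in (0, 1].
#' @export
categorize_by_share <- function(slope_map, share) {
  stopifnot_grid(slope_map)
  if (!is.numeric(share) || length(share) != 1L || share <= 0 || share > 1)
    stop("`share` must be a single value in (0, 1]", call. = FALSE)
  m <- slope_map$values
  valid <- which(!is.na(m))
  k <- min(length(valid), ceiling(share * length(valid)))
  # row-major position for the deterministic tie-break
  nr <- slope_map$nrow
  rm_order <- ((valid - 1L) %% nr) * slope_map$ncol + ((valid - 1L) %/% nr)
  chosen <- valid[order(m[valid], rm_order)[seq_len(k)]]
  mask <- matrix(NA_real_, slope_map$nrow, slope_map$ncol)
  mask[valid] <- 0
  mask[chosen] <- 1
  potential_space(ag_grid(mask, slope_map$resolution), slope_map,
                  "perlin_share")
}

#' Import an external mask as potential space
#'
#' @param mask binary [ag_grid] (for instance read with [read_raster()]).
#' @return an `ag_potential_space` with provenance `"external"`.
#' @export
load_external <- function(mask) {
  stopifnot_grid(mask)
  stopifnot_binary(mask)
  potential_space(mask, NULL, "external")
}

#' Hybrid-world suitability model
#'
#' `fit_hybrid()` fits one cell-wise binomial logistic regression of arable
#' membership on covariate rasters, treating cells as independent
#' observations (iteratively reweighted least squares, gradient tolerance
#' 1e-8, at most 100 iterations). With no covariates the model is
#' intercept-only and the fitted probability is the arable mean.
#' `apply_hybrid()` converts fitted probabilities into a potential-space
#' mask: an independent Bernoulli draw per cell followed by synchronous
#' majority-vote smoothing sweeps in which each cell adopts the strict
#' majority state of its neighborhood (ties keep the current state). The
#' smoothing clusters the mask spatially, typically yielding a potential
#' space larger than the arable land it was fitted to.
#'
#' @param landcover_arable binary [ag_grid]; 1 = arable cells.
#' @param covariates list of continuous [ag_grid]s, all the same shape.
#' @return `fit_hybrid()`: object of class `hybrid_params` with elements
#'   `coefficients` (intercept first), `converged`, `smoothing_iterations`
#'   (default 2) and `smoothing_connectivity` (default 8).
#' @examples
#' arable <- ag_grid(matrix(rbinom(100, 1, 0.4), 10, 10))
#' hp <- fit_hybrid(arable, list())
#' plogis(hp$coefficients)  # arable mean
#' @export
fit_hybrid <- function(landcover_arable, covariates = list(),
                       smoothing_iterations = 2L,
                       smoothing_connectivity = 8) {
  stopifnot_grid(landcover_arable)
  stopifnot_binary(landcover_arable)
  for (cv in covariates) {
    stopifnot_grid(cv)
    if (cv$nrow != landcover_arable$nrow || cv$ncol != landcover_arable$ncol)
      stop("covariate shape must match the arable grid", call. = FALSE)
  }
  y <- as.vector(landcover_arable$values)
  df <- data.frame(y = y)
  for (i in seq_along(covariates))
    df[[paste0("x", i)]] <- as.vector(covariates[[i]]$values)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  structure(list(coefficients = unname(stats::coef(fit)),
                 converged = fit$converged,
                 smoothing_iterations = as.integer(smoothing_iterations),
                 smoothing_connectivity = match_connectivity(smoothing_connectivity)),
            class = "hybrid_params")
}

# sum of 0/1 neighbor states (NA treated as absent) and neighbor counts
neighbor_tally <- function(state, connectivity) {
  nr <- nrow(state); nc <- ncol(state)
  ones <- ifelse(is.na(state), 0, state)
  pres <- ifelse(is.na(state), 0, 1)
  pad <- function(m) rbind(0, cbind(0, m, 0), 0)
  po <- pad(ones); pp <- pad(pres)
  shifts4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  shifts8 <- c(shifts4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  shifts <- if (connectivity == 8L) shifts8 else shifts4
  s1 <- matrix(0, nr, nc); sp <- matrix(0, nr, nc)
  for (d in shifts) {
    ri <- (2 + d[1]):(nr + 1 + d[1])
    ci <- (2 + d[2]):(nc + 1 + d[2])
    s1 <- s1 + po[ri, ci]
    sp <- sp + pp[ri, ci]
  }
  list(ones = s1, total = sp)
}

majority_smooth <- function(state, iterations, connectivity) {
  for (i in seq_len(iterations)) {
    t <- neighbor_tally(state, connectivity)
    new <- state
    new[!is.na(state) & 2 * t$ones > t$total] <- 1
    new[!is.na(state) & 2 * t$ones < t$total] <- 0
    state <- new
  }
  state
}

#' @rdname fit_hybrid
#' @param params a `hybrid_params` object.
#' @param seed integer seed for the Bernoulli draws.
#' @param smoothing_iterations number of synchronous majority-vote sweeps
#'   (>= 0); defaults to the value stored in `params`.
#' @param smoothing_connectivity neighborhood for the vote, 4 or 8.
#' @param extent an [ag_grid] defining the output shape; required for an
#'   intercept-only model (no covariates), ignored otherwise.
#' @return `apply_hybrid()`: an `ag_potential_space` with provenance
#'   `"hybrid"`.
#' @export
apply_hybrid <- function(params, covariates = list(), seed = 1L,
                         smoothing_iterations = NULL,
                         smoothing_connectivity = NULL, extent = NULL) {
  stopifnot(inherits(params, "hybrid_params"))
  if (length(params$coefficients) != length(covariates) + 1L)
    stop(sprintf("model has %d covariate weight(s) but %d covariate grid(s) supplied",
                 length(params$coefficients) - 1L, length(covariates)),
         call. = FALSE)
  if (is.null(smoothing_iterations))
    smoothing_iterations <- params$smoothing_iterations
  if (is.null(smoothing_connectivity))
    smoothing_connectivity <- params$smoothing_connectivity
  smoothing_connectivity <- match_connectivity(smoothing_connectivity)
  if (length(covariates) == 0L) {
    if (is.null(extent))
      stop("an intercept-only model needs `extent` to define the output shape",
           call. = FALSE)
    stopifnot_grid(extent)
    ref <- extent
  } else {
    ref <- covariates[[1]]
  }
  eta <- matrix(params$coefficients[1], ref$nrow, ref$ncol)
  for (i in seq_along(covariates)) {
    cv <- covariates[[i]]
    if (cv$nrow != ref$nrow || cv$ncol != ref$ncol)
      stop("covariate grids must share one shape", call. = FALSE)
    eta <- eta + params$coefficients[i + 1L] * cv$values
  }
  p <- stats::plogis(eta)
  state <- with_seed(seed, {
    draw <- matrix(NA_real_, ref$nrow, ref$ncol)
    ok <- !is.na(p)
    draw[ok] <- stats::rbinom(sum(ok), 1L, p[ok])
    draw
  })
  state <- majority_smooth(state, smoothing_iterations, smoothing_connectivity)
  potential_space(ag_grid(state, ref$resolution), NULL, "hybrid")
}
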