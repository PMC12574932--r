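# FRAGSTATS-style landscape metrics with deliberately simple, brute-force
# verifiable raster definitions. Patch-level metrics are computed for one
# focal class; contagion uses all classes of the map. NA cells are outside
# the landscape: they contribute edge where they touch the class, and are
# excluded from the landscape area.

METRIC_NAMES <- c("np", "area_mn", "area_sd", "lpi", "contag", "ed",
                  "enn_mn", "enn_sd", "shape_mn", "lsi", "frac_mn", "para_mn")

#' Patches of a class
#'
#' Maximal connected components of one class of a categorical map.
#'
#' @param class_map categorical [ag_grid].
#' @param class_id focal class value.
#' @param connectivity 4 or 8 (default 8, the usual patch rule).
#' @return list of 0-based `(row, col)` cell matrices, one per patch, in
#'   row-major discovery order; empty list when the class is absent.
#' @export
patches <- function(class_map, class_id, connectivity = 8) {
  stopifnot_grid(class_map)
  connectivity <- match_connectivity(connectivity)
  bin <- matrix(as.numeric(!is.na(class_map$values) &
                             class_map$values == class_id),
                class_map$nrow, class_map$ncol)
  lab <- cc_label(bin, connectivity, FALSE)
  k <- attr(lab, "n_components")
  if (k == 0) return(list())
  ord <- order(as.vector(lab))
  idx <- seq_len(length(lab))[ord]
  labs <- as.vector(lab)[ord]
  first <- match(seq_len(k), labs)
  bounds <- c(first, length(labs) + 1L)
  lapply(seq_len(k), function(i)
    index_to_cells(idx[bounds[i]:(bounds[i + 1L] - 1L)], class_map$nrow))
}

# per-patch perimeter in cell faces: for each patch cell, faces adjacent to
# a different label (other class, other patch is impossible under 4-adj,
# NA, or the grid boundary)
patch_perimeters <- function(lab, k) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  per <- numeric(k)
  for (sh in list(pad[1:nr, 2:(nc + 1)], pad[3:(nr + 2), 2:(nc + 1)],
                  pad[2:(nr + 1), 1:nc], pad[2:(nr + 1), 3:(nc + 2)])) {
    mism <- core > 0 & sh != core
    if (any(mism)) {
      t <- tabulate(core[mism], nbins = k)
      per <- per + t
    }
  }
  per
}

# boundary cells of each patch (any rook neighbor outside the patch)
patch_boundary_cells <- function(lab, k) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  b <- core > 0 & (pad[1:nr, 2:(nc + 1)] != core |
                   pad[3:(nr + 2), 2:(nc + 1)] != core |
                   pad[2:(nr + 1), 1:nc] != core |
                   pad[2:(nr + 1), 3:(nc + 2)] != core)
  idx <- which(b)
  split(idx, core[idx])
}

#' Landscape metric profile of one class
#'
#' Computes the metric set used for landscape profiling and calibration:
#' `np` (number of patches), `area_mn`/`area_sd` (mean/sd patch area, ha;
#' `area_sd` is the sample sd and missing for a single patch), `lpi`
#' (largest patch index, percent of landscape area), `contag` (contagion
#' over all classes, percent; missing for a single-class map), `ed` (edge
#' density, m per ha of landscape, counting grid-boundary edges), `enn_mn` /
#' `enn_sd` (Euclidean nearest neighbour distance between patch cell
#' centres, m; missing with fewer than two patches), `shape_mn` (mean patch
#' shape index `0.25 p / sqrt(a)`), `lsi` (landscape shape index
#' `0.25 E / sqrt(A)` over the class), `frac_mn` (mean fractal dimension
#' `2 ln(0.25 p) / ln(a)`) and `para_mn` (mean perimeter-area ratio, m per
#' m^2). Perimeters are in meters, areas in square meters inside the
#' formulas. Metrics undefined for a configuration are returned as `NA`,
#' never as a silent zero.
#'
#' @param class_map categorical [ag_grid]; must contain at least one non-NA
#'   cell.
#' @param class_id focal class value.
#' @param connectivity patch rule, 4 or 8. Default 8.
#' @param metrics character vector of metric names to compute (subset of
#'   `agriscape:::METRIC_NAMES`); `NULL` computes all. Restricting the set
#'   skips the expensive nearest-neighbour scan.
#' @return named numeric vector (a metric profile).
#' @examples
#' m <- matrix(0, 10, 10); m[3:4, 3:4] <- 1
#' compute_profile(ag_grid(m), 1)[c("np", "area_mn", "lpi", "shape_mn")]
#' @export
compute_profile <- function(class_map, class_id, connectivity = 8,
                            metrics = NULL) {
  stopifnot_grid(class_map)
  connectivity <- match_connectivity(connectivity)
  if (is.null(metrics)) metrics <- METRIC_NAMES
  bad <- setdiff(metrics, METRIC_NAMES)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  v <- class_map$values
  n_valid <- sum(!is.na(v))
  if (n_valid == 0) stop("empty landscape: all cells are NA", call. = FALSE)
  res <- class_map$resolution
  land_m2 <- n_valid * res^2
  land_ha <- land_m2 / 1e4
  bin <- matrix(as.numeric(!is.na(v) & v == class_id),
                class_map$nrow, class_map$ncol)
  lab <- cc_label(bin, connectivity, FALSE)
  k <- attr(lab, "n_components")
  out <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
  areas_cells <- if (k > 0) tabulate(as.vector(lab)[as.vector(lab) > 0], k)
                 else integer(0)
  areas_m2 <- areas_cells * res^2
  per_m <- patch_perimeters(lab, k) * res
  if ("np" %in% metrics) out["np"] <- k
  if (k > 0) {
    if ("area_mn" %in% metrics) out["area_mn"] <- mean(areas_m2) / 1e4
    if ("area_sd" %in% metrics && k > 1) out["area_sd"] <- sd(areas_m2) / 1e4
    if ("lpi" %in% metrics) out["lpi"] <- 100 * max(areas_m2) / land_m2
    if ("ed" %in% metrics) out["ed"] <- sum(per_m) / land_ha
    if ("shape_mn" %in% metrics)
      out["shape_mn"] <- mean(0.25 * per_m / sqrt(areas_m2))
    if ("para_mn" %in% metrics) out["para_mn"] <- mean(per_m / areas_m2)
    if ("frac_mn" %in% metrics) {
      la <- log(areas_m2)
      fr <- ifelse(la == 0, NA_real_, 2 * log(0.25 * per_m) / la)
      out["frac_mn"] <- mean(fr)
    }
    if ("lsi" %in% metrics) out["lsi"] <- 0.25 * sum(per_m) / sqrt(sum(areas_m2))
    if (any(c("enn_mn", "enn_sd") %in% metrics) && k > 1) {
      enn <- patch_enn(lab, k, res)
      if ("enn_mn" %in% metrics) out["enn_mn"] <- mean(enn)
      if ("enn_sd" %in% metrics) out["enn_sd"] <- sd(enn)
    }
  } else if ("ed" %in% metrics) out["ed"] <- 0
  if ("contag" %in% metrics) out["contag"] <- contagion(class_map)
  out
}

# min center-to-center distance from each patch to any other patch of the
# class; boundary cells suffice because the minimum is attained there
patch_enn <- function(lab, k, res) {
  bnd <- patch_boundary_cells(lab, k)
  nr <- nrow(lab)
  coords <- lapply(seq_len(k), function(i) {
    idx <- bnd[[as.character(i)]]
    cbind((idx - 1L) %% nr, (idx - 1L) %/% nr)
  })
  enn <- rep(Inf, k)
  for (i in seq_len(k - 1L)) {
    a <- coords[[i]]
    for (j in (i + 1L):k) {
      b <- coords[[j]]
      d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
      dm <- sqrt(min(d2))
      enn[i] <- min(enn[i], dm)
      enn[j] <- min(enn[j], dm)
    }
  }
  enn * res
}

# contagion index over all classes, rook adjacencies double counted
contagion <- function(class_map) {
  v <- class_map$values
  classes <- sort(unique(v[!is.na(v)]))
  m <- length(classes)
  if (m < 2) return(NA_real_)
  g <- adjacency_counts(class_map$values, classes)
  p <- as.numeric(table(factor(v[!is.na(v)], levels = classes)))
  p <- p / sum(p)
  rs <- rowSums(g)
  acc <- 0
  for (i in seq_len(m)) {
    if (rs[i] == 0) next
    q <- p[i] * g[i, ] / rs[i]
    q <- q[q > 0]
    acc <- acc + sum(q * log(q))
  }
  100 * (1 + acc / (2 * log(m)))
}

#' Scaled similarity between two metric profiles
#'
#' Per-metric scaled distance `d_i = min(1, |g_i - r_i| / max(|r_i|,
#' 1e-9))`, clipped at 1 so one wild metric cannot dominate; the returned
#' score is `1 - mean(d_i)`, where 1 indicates a perfect match and 0 a
#' complete mismatch. Used as the genetic-algorithm fitness.
#'
#' @param generated,reference named numeric metric profiles.
#' @param subset metric names to compare; default: all names shared by both.
#' @return similarity score in \[0, 1\].
#' @export
profile_distance <- function(generated, reference,
                             subset = intersect(names(generated),
                                                names(reference))) {
  if (length(subset) == 0) stop("no shared metrics to compare", call. = FALSE)
  miss <- subset[!(subset %in% names(generated)) |
                 !(subset %in% names(reference))]
  if (length(miss)) stop("metrics absent from a profile: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  g <- generated[subset]; r <- reference[subset]
  if (anyNA(g) || anyNA(r))
    stop("NA metric values in the compared subset", call. = FALSE)
  d <- pmin(1, abs(g - r) / pmax(abs(r), 1e-9))
  1 - mean(d)
}

#' Read and write metric profiles as CSV
#'
#' Two-column CSV (`metric`, `value`).
#'
#' @param profile named numeric vector.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(metric = names(profile),
                              value = unname(profile)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$metric)
}
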