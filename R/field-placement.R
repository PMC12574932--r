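# Step 2: tessellate part of the potential space into discrete arable
# fields. Two algorithms share one parameter set: place-and-conquer grows
# each field segment by segment inside the free space (slower, more
# realistic shapes), dead-leaves over-tessellates with random rectangles and
# then prunes the smallest fields down to the requested coverage (faster).

#' Field establishment parameters
#'
#' Shared parameters of both placement algorithms. Sizes are in hectares and
#' converted to cells with the grid resolution (one hectare is 100 cells at
#' 10 m); shapes are length:width ratios >= 1. `coverage` is the fraction of
#' the potential space to be covered by fields.
#'
#' @param mean_size,sd_size mean and standard deviation of field size (ha).
#' @param size_distribution `"normal"` (truncated at one cell by redraw,
#'   at most 100 redraws then clamped) or `"lognormal"` (moment-matched to
#'   the given mean and sd).
#' @param mean_shape,sd_shape mean and sd of the length:width ratio; draws
#'   are truncated at 1.
#' @param coverage target fraction of potential-space cells covered by
#'   fields, in (0, 1].
#' @param seed integer seed.
#' @return list of class `field_params`.
#' @export
field_params <- function(mean_size = 1.5, sd_size = 0.5,
                         size_distribution = c("normal", "lognormal"),
                         mean_shape = 2, sd_shape = 0.5,
                         coverage = 0.7, seed = 1L) {
  size_distribution <- match.arg(size_distribution)
  stopifnot(mean_size > 0, sd_size >= 0, mean_shape >= 1, sd_shape >= 0,
            coverage > 0, coverage <= 1)
  structure(list(mean_size = mean_size, sd_size = sd_size,
                 size_distribution = size_distribution,
                 mean_shape = mean_shape, sd_shape = sd_shape,
                 coverage = coverage, seed = as.integer(seed)),
            class = "field_params")
}

round_half_up <- function(x) floor(x + 0.5)

# redraw-until-valid with a cap, then clamp; draws from the current RNG
draw_truncated <- function(draw_fn, lower, max_redraws = 100L) {
  for (i in seq_len(max_redraws)) {
    x <- draw_fn()
    if (x >= lower) return(x)
  }
  lower
}

#' Draw the cell dimensions of one field
#'
#' Draws a field size (ha) and a shape ratio from the configured
#' distributions and converts them to segment geometry: a field of `A` cells
#' and ratio `rho` is laid as `n_segments = max(1, round(A /
#' segment_length))` one-cell-wide segments of up to `segment_length =
#' round(sqrt(A * rho))` cells. Lognormal sizes are parameterised by moment
#' matching (`sdlog^2 = log(1 + (sd/mean)^2)`). Uses the current RNG stream;
#' seed control belongs to the calling placement function.
#'
#' @param params a [field_params].
#' @param resolution grid cell size in meters.
#' @return list with `target_cells`, `n_segments`, `segment_length`,
#'   `size_ha`, `shape`.
#' @export
draw_field_dims <- function(params, resolution = 10) {
  cell_ha <- resolution^2 / 1e4
  size_ha <-
    if (params$size_distribution == "normal") {
      draw_truncated(function() rnorm(1, params$mean_size, params$sd_size),
                     cell_ha)
    } else {
      if (params$sd_size == 0) params$mean_size else {
        sdlog2 <- log(1 + (params$sd_size / params$mean_size)^2)
        meanlog <- log(params$mean_size) - sdlog2 / 2
        max(cell_ha, rlnorm(1, meanlog, sqrt(sdlog2)))
      }
    }
  shape <- draw_truncated(function() rnorm(1, params$mean_shape, params$sd_shape), 1)
  target <- max(1L, round_half_up(size_ha / cell_ha))
  seg_len <- max(1L, round_half_up(sqrt(target * shape)))
  n_seg <- max(1L, round_half_up(target / seg_len))
  list(target_cells = as.integer(target), n_segments = as.integer(n_seg),
       segment_length = as.integer(seg_len), size_ha = size_ha, shape = shape)
}

new_field <- function(cells, field_id, farmer_id = NA_integer_,
                      crop_id = NA_character_) {
  structure(list(cells = cells, field_id = as.integer(field_id),
                 farmer_id = farmer_id, crop_id = crop_id),
            class = "ag_field")
}

new_landscape <- function(fields, space, params, algorithm,
                          coverage_reached = TRUE) {
  structure(list(fields = fields, space = space, params = params,
                 algorithm = algorithm, coverage_reached = coverage_reached),
            class = "ag_landscape")
}

#' @export
print.ag_landscape <- function(x, ...) {
  sizes <- vapply(x$fields, function(f) nrow(f$cells), integer(1))
  cat(sprintf("<ag_landscape> %d fields (%s), %.1f%% of potential space covered\n",
              length(x$fields), x$algorithm, 100 * realized_coverage(x)))
  if (length(sizes))
    cat(sprintf("  field size: %d-%d cells (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
  if (!x$coverage_reached)
    cat("  note: potential space exhausted before the coverage target\n")
  invisible(x)
}

#' Realised field coverage of the potential space
#'
#' @param landscape an `ag_landscape`.
#' @return total field cells divided by potential-space mask cells.
#' @export
realized_coverage <- function(landscape) {
  stopifnot(inherits(landscape, "ag_landscape"))
  mask_n <- sum(landscape$space$mask$values == 1, na.rm = TRUE)
  if (mask_n == 0) return(0)
  sum(vapply(landscape$fields, function(f) nrow(f$cells), integer(1))) / mask_n
}

# choose a window of length L inside [lo, hi] containing `center`,
# preferring symmetric placement and sliding to fit
seg_window <- function(lo, hi, center, L) {
  left <- center - (L - 1L) %/% 2L
  right <- left + L - 1L
  if (left < lo) { right <- min(hi, right + (lo - left)); left <- lo }
  if (right > hi) { left <- max(lo, left - (right - hi)); right <- hi }
  c(left, right)
}

# best placement of a run of up to L free cells on `rowvec` maximising
# 4-adjacency with the previous segment's interval [p1, p2]; ties go to the
# smaller offset. Returns c(start, end) or NULL when no placement touches
# the previous segment.
best_aligned_run <- function(rowvec, p1, p2, L) {
  r <- rle(rowvec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL; best_ov <- 0L
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    if (b < p1 || a > p2) next        # cannot touch the previous segment
    len <- min(L, b - a + 1L)
    s <- a:(b - len + 1L)
    ov <- pmin(s + len - 1L, p2) - pmax(s, p1) + 1L
    ov[ov < 0L] <- 0L
    i <- which.max(ov)                # first max = smallest offset
    if (ov[i] > best_ov) { best_ov <- ov[i]; best <- c(s[i], s[i] + len - 1L) }
  }
  if (best_ov < 1L) NULL else best
}

# grow one place-and-conquer field in the free matrix M (TRUE = free).
# Works along rows; callers transpose for vertical orientation. Returns the
# occupied (row, col) 1-based index matrix in M's frame.
grow_pac_field <- function(M, anchor_r, anchor_c, dims) {
  nr <- nrow(M); nc <- ncol(M)
  # segment 1: maximal free interval through the anchor, windowed to length
  rv <- M[anchor_r, ]
  left <- anchor_c
  while (left > 1L && rv[left - 1L]) left <- left - 1L
  right <- anchor_c
  while (right < nc && rv[right + 1L]) right <- right + 1L
  w <- seg_window(left, right, anchor_c, dims$segment_length)
  segs <- list(list(row = anchor_r, c1 = w[1], c2 = w[2]))
  placed <- w[2] - w[1] + 1L
  n_placed <- 1L
  for (side in c(1L, -1L)) {
    prev <- segs[[1]]
    row <- anchor_r + side
    while (n_placed < dims$n_segments && placed < dims$target_cells &&
           row >= 1L && row <= nr) {
      run <- best_aligned_run(M[row, ], prev$c1, prev$c2, dims$segment_length)
      if (is.null(run)) break
      n_placed <- n_placed + 1L
      placed <- placed + run[2] - run[1] + 1L
      prev <- list(row = row, c1 = run[1], c2 = run[2])
      segs[[length(segs) + 1L]] <- prev
      row <- row + side
    }
    if (n_placed >= dims$n_segments || placed >= dims$target_cells) break
  }
  do.call(rbind, lapply(segs, function(s)
    cbind(row = rep.int(s$row, s$c2 - s$c1 + 1L), col = s$c1:s$c2)))
}

#' Place fields with the place-and-conquer algorithm
#'
#' Repeatedly draws field dimensions, picks a uniform-random free anchor
#' cell and orientation, and grows the field as stacked one-cell-wide
#' segments: the first segment runs through the anchor, each further segment
#' is laid on the adjacent parallel line at the offset that maximises
#' contact with the previous segment, using free cells only. Growth proceeds
#' on one side of the first segment and switches to the other side when
#' blocked, so fields can wrap around obstacles. A field stops when all its
#' segments are placed, its target size is reached, or no aligned free run
#' remains; placement stops after the field with which realised coverage
#' first reaches the target (overshoot at most one field). Field shape and
#' size are thus a joint product of the parameters and the constraints of
#' the space.
#'
#' @param space an `ag_potential_space`.
#' @param params a [field_params].
#' @return an `ag_landscape`. If the space is exhausted before the coverage
#'   target the landscape is returned with `coverage_reached = FALSE` and a
#'   warning, never an error.
#' @examples
#' s <- generate_perlin_slope(40, 40, perlin_params(seed = 5))
#' ps <- categorize_by_share(s, 0.6)
#' land <- establish_pac(ps, field_params(mean_size = 0.5, coverage = 0.6, seed = 9))
#' land
#' @export
establish_pac <- function(space, params) {
  stopifnot(inherits(space, "ag_potential_space"),
            inherits(params, "field_params"))
  res <- space$mask$resolution
  free <- !is.na(space$mask$values) & space$mask$values == 1
  mask_n <- sum(free)
  if (mask_n == 0) stop("potential space has no free cell", call. = FALSE)
  target_total <- params$coverage * mask_n
  fields <- list()
  placed_total <- 0L
  with_seed(params$seed, {
    free_t <- t(free)   # kept in sync for vertical growth
    while (placed_total < target_total) {
      free_idx <- which(free)
      if (!length(free_idx)) break
      dims <- draw_field_dims(params, res)
      anchor <- free_idx[sample.int(length(free_idx), 1L)]
      ar <- (anchor - 1L) %% nrow(free) + 1L
      ac <- (anchor - 1L) %/% nrow(free) + 1L
      horizontal <- runif(1) < 0.5
      cells <- if (horizontal) {
        grow_pac_field(free, ar, ac, dims)
      } else {
        cc <- grow_pac_field(free_t, ac, ar, dims)
        cbind(row = cc[, 2], col = cc[, 1])
      }
      free[cbind(cells[, 1], cells[, 2])] <- FALSE
      free_t[cbind(cells[, 2], cells[, 1])] <- FALSE
      placed_total <- placed_total + nrow(cells)
      fields[[length(fields) + 1L]] <-
        new_field(cbind(row = cells[, 1] - 1L, col = cells[, 2] - 1L),
                  length(fields) + 1L)
    }
  })
  reached <- placed_total >= target_total
  if (!reached)
    warning("potential space exhausted before reaching the coverage target",
            call. = FALSE)
  new_landscape(fields, space, params, "pac", reached)
}

#' Place fields with the modified dead-leaves algorithm
#'
#' Phase 1 fills the potential space completely by stamping random
#' rectangles (dimensions from [draw_field_dims()], uniform-random centre
#' and orientation), each new rectangle occluding earlier ones, until every
#' mask cell is covered or 10,000 consecutive stamps cover nothing new.
#' Surviving 4-connected same-id regions become fields (occluded fragments
#' that fall apart are split). Phase 2 then deletes fields from the smallest
#' up until the remaining coverage is at or below the target -- pruning the
#' smallest patches avoids over-fragmentation of the landscape.
#'
#' @inheritParams establish_pac
#' @return an `ag_landscape`.
#' @export
establish_dl <- function(space, params) {
  stopifnot(inherits(space, "ag_potential_space"),
            inherits(params, "field_params"))
  res <- space$mask$resolution
  mask <- !is.na(space$mask$values) & space$mask$values == 1
  nr <- nrow(mask); nc <- ncol(mask)
  mask_n <- sum(mask)
  if (mask_n == 0) stop("potential space has no free cell", call. = FALSE)
  idmat <- matrix(0, nr, nc)
  with_seed(params$seed, {
    uncovered <- mask_n
    consec <- 0L
    next_id <- 0
    while (uncovered > 0L && consec < 10000L) {
      dims <- draw_field_dims(params, res)
      w <- dims$n_segments; l <- dims$segment_length
      if (runif(1) < 0.5) { tmp <- w; w <- l; l <- tmp }
      cr <- sample.int(nr, 1L); cc <- sample.int(nc, 1L)
      r1 <- max(1L, cr - (w - 1L) %/% 2L); r2 <- min(nr, r1 + w - 1L)
      c1 <- max(1L, cc - (l - 1L) %/% 2L); c2 <- min(nc, c1 + l - 1L)
      sel <- mask[r1:r2, c1:c2, drop = FALSE]
      if (any(sel)) {
        block <- idmat[r1:r2, c1:c2, drop = FALSE]
        newly <- sum(sel & block == 0)
        next_id <- next_id + 1
        block[sel] <- next_id
        idmat[r1:r2, c1:c2] <- block
        if (newly > 0L) { uncovered <- uncovered - newly; consec <- 0L }
        else consec <- consec + 1L
      } else consec <- consec + 1L
    }
  })
  # same-id 4-connected regions become individual fields
  lab <- cc_label(idmat, 4L, TRUE)
  k <- attr(lab, "n_components")
  fields <- vector("list", k)
  if (k > 0) {
    ord <- order(as.vector(lab))
    idx <- seq_len(nr * nc)[ord]
    labs <- as.vector(lab)[ord]
    first <- match(seq_len(k), labs)
    bounds <- c(first, length(labs) + 1L)
    for (i in seq_len(k)) {
      cell_idx <- idx[bounds[i]:(bounds[i + 1L] - 1L)]
      fields[[i]] <- new_field(index_to_cells(cell_idx, nr), i)
    }
  }
  # phase 2: smallest-first removal down to the coverage target
  sizes <- vapply(fields, function(f) nrow(f$cells), integer(1))
  ord <- order(sizes, seq_along(sizes))
  remaining <- sum(sizes)
  removed <- logical(length(fields))
  for (i in ord) {
    if (remaining / mask_n <= params$coverage + 1e-12) break
    removed[i] <- TRUE
    remaining <- remaining - sizes[i]
  }
  fields <- fields[!removed]
  for (i in seq_along(fields)) fields[[i]]$field_id <- i
  new_landscape(fields, space, params, "dl",
                coverage_reached = TRUE)
}

# ---- landscape (de)serialisation ------------------------------------------

#' Save and load a landscape as JSON
#'
#' Fields are stored with run-length-encoded linear cell indices, so the
#' file is compact plain text and round-trips the landscape exactly.
#'
#' @param landscape an `ag_landscape`.
#' @param path file path (`.json`).
#' @return `read_landscape()` returns the restored `ag_landscape`.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "ag_landscape"))
  nr <- landscape$space$mask$nrow
  enc <- function(cells) {
    idx <- sort(cells_to_index(cells, nr))
    if (!length(idx)) return(list(starts = integer(0), lengths = integer(0)))
    breaks <- c(0L, which(diff(idx) != 1L), length(idx))
    starts <- idx[breaks[-length(breaks)] + 1L]
    lens <- diff(breaks)
    list(starts = starts, lengths = lens)
  }
  mask <- landscape$space$mask
  mv <- as.vector(mask$values)
  obj <- list(
    nrow = nr, ncol = mask$ncol, resolution = mask$resolution,
    provenance = landscape$space$provenance,
    algorithm = landscape$algorithm,
    coverage_reached = landscape$coverage_reached,
    params = unclass(landscape$params),
    mask_ones = enc(index_to_cells(which(!is.na(mv) & mv == 1), nr)),
    mask_na = enc(index_to_cells(which(is.na(mv)), nr)),
    fields = lapply(landscape$fields, function(f)
      list(field_id = f$field_id, farmer_id = f$farmer_id,
           crop_id = f$crop_id, cells = enc(f$cells)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nr <- obj$nrow; nc <- obj$ncol
  dec <- function(rl) {
    if (length(rl$starts) == 0) return(integer(0))
    unlist(mapply(function(s, l) s + 0:(l - 1L), rl$starts, rl$lengths,
                  SIMPLIFY = FALSE))
  }
  mv <- rep(0, nr * nc)
  mv[dec(obj$mask_ones)] <- 1
  mv[dec(obj$mask_na)] <- NA_real_
  space <- potential_space(ag_grid(matrix(mv, nr, nc), obj$resolution),
                           NULL, obj$provenance)
  params <- do.call(field_params, obj$params[c(
    "mean_size", "sd_size", "size_distribution", "mean_shape", "sd_shape",
    "coverage", "seed")])
  fields <- lapply(seq_len(nrow_or_len(obj$fields)), function(i) {
    f <- field_row(obj$fields, i)
    new_field(index_to_cells(dec(f$cells), nr), f$field_id,
              if (is.null(f$farmer_id)) NA_integer_ else f$farmer_id,
              if (is.null(f$crop_id)) NA_character_ else f$crop_id)
  })
  new_landscape(fields, space, params, obj$algorithm, obj$coverage_reached)
}

# jsonlite may simplify the field list to a data frame; normalise access
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
field_row <- function(x, i) {
  if (is.data.frame(x)) {
    list(field_id = x$field_id[i], farmer_id = x$farmer_id[i],
         crop_id = x$crop_id[i],
         cells = list(starts = x$cells$starts[[i]],
                      lengths = x$cells$lengths[[i]]))
  } else x[[i]]
}
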