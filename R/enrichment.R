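# Step 3: enrich the landscape with farmer and crop identities and extract
# the categorical raster views (field map, arable land excluding borders,
# crop map, farmer map, potential space).

#' Farmer assignment parameters
#'
#' The number of farmers is emergent: farmers are created one at a time,
#' each drawing a number of fields from the configured distribution, until
#' no field is left (the last farmer may receive fewer than drawn).
#'
#' @param mean_fields,sd_fields mean and sd of fields per farmer.
#' @param distribution `"uniform"` (on a mean/sd-matched interval),
#'   `"normal"`, or `"lognormal"` (moment-matched); draws are rounded and
#'   truncated at 1.
#' @param mode `"spatial"` (each farmer takes a random field plus its
#'   nearest unassigned fields by centroid distance) or `"random"`.
#' @param seed integer seed.
#' @return list of class `farmer_params`.
#' @export
farmer_params <- function(mean_fields = 4, sd_fields = 2,
                          distribution = c("normal", "uniform", "lognormal"),
                          mode = c("spatial", "random"), seed = 1L) {
  distribution <- match.arg(distribution)
  mode <- match.arg(mode)
  stopifnot(mean_fields >= 1, sd_fields >= 0)
  structure(list(mean_fields = mean_fields, sd_fields = sd_fields,
                 distribution = distribution, mode = mode,
                 seed = as.integer(seed)),
            class = "farmer_params")
}

draw_n_fields <- function(params) {
  x <- switch(params$distribution,
    uniform = {
      h <- sqrt(3) * params$sd_fields    # half-width matching the sd
      runif(1, params$mean_fields - h, params$mean_fields + h)
    },
    normal = rnorm(1, params$mean_fields, params$sd_fields),
    lognormal = {
      if (params$sd_fields == 0) params$mean_fields else {
        sdlog2 <- log(1 + (params$sd_fields / params$mean_fields)^2)
        rlnorm(1, log(params$mean_fields) - sdlog2 / 2, sqrt(sdlog2))
      }
    })
  max(1L, round_half_up(x))
}

field_centroids <- function(fields) {
  t(vapply(fields, function(f) colMeans(f$cells), numeric(2)))
}

#' Distribute fields among farmers
#'
#' Assigns every field exactly one farmer id (1, 2, ...). Farmers are
#' created sequentially; each draws its number of fields `n` from the
#' configured distribution and receives, in spatial mode, a uniform-random
#' unassigned field plus its `n - 1` nearest unassigned fields by centroid
#' Euclidean distance, or, in random mode, `n` uniform-random unassigned
#' fields. The loop ends when no field is unassigned, so the last farmer
#' may get fewer than drawn.
#'
#' @param landscape an `ag_landscape` with at least one field.
#' @param params a [farmer_params].
#' @return the landscape with `farmer_id` set on every field.
#' @export
distribute_farmers <- function(landscape, params) {
  stopifnot(inherits(landscape, "ag_landscape"),
            inherits(params, "farmer_params"))
  nf <- length(landscape$fields)
  if (nf == 0) stop("landscape has no fields", call. = FALSE)
  cent <- field_centroids(landscape$fields)
  assignment <- rep(NA_integer_, nf)
  with_seed(params$seed, {
    farmer <- 0L
    while (anyNA(assignment)) {
      farmer <- farmer + 1L
      open <- which(is.na(assignment))
      n <- min(draw_n_fields(params), length(open))
      take <- if (params$mode == "random") {
        open[sample.int(length(open), n)]
      } else {
        seed_field <- open[sample.int(length(open), 1L)]
        d <- sqrt((cent[open, 1] - cent[seed_field, 1])^2 +
                  (cent[open, 2] - cent[seed_field, 2])^2)
        open[order(d, open)[seq_len(n)]]   # seed field itself is at d = 0
      }
      assignment[take] <- farmer
    }
  })
  for (i in seq_len(nf)) landscape$fields[[i]]$farmer_id <- assignment[i]
  landscape
}

#' Crop portfolio
#'
#' A list of crops with the share of arable land each should occupy.
#'
#' @param crops character vector of unique crop identifiers.
#' @param shares positive fractions summing to 1 (tolerance 1e-9).
#' @return data frame of class `crop_portfolio`.
#' @export
crop_portfolio <- function(crops, shares) {
  if (length(crops) == 0) stop("portfolio must contain at least one crop",
                               call. = FALSE)
  if (length(crops) != length(shares) || anyDuplicated(crops))
    stop("`crops` must be unique and match `shares` in length", call. = FALSE)
  if (any(shares <= 0) || abs(sum(shares) - 1) > 1e-9)
    stop("`shares` must be positive and sum to 1", call. = FALSE)
  structure(data.frame(crop_id = as.character(crops), share = shares,
                       stringsAsFactors = FALSE),
            class = c("crop_portfolio", "data.frame"))
}

#' Distribute crops over fields
#'
#' Assigns exactly one crop to each entire field. Fields are visited in a
#' seeded random order; each is given the crop with the largest remaining
#' area deficit (target share x total field area minus area already
#' assigned). The per-crop error between realised and target share is
#' bounded by the largest field's share of the total area, so landscapes
#' with more or smaller fields match the portfolio better.
#'
#' @param landscape an `ag_landscape` with at least one field.
#' @param portfolio a [crop_portfolio].
#' @param seed integer seed for the field order.
#' @return the landscape with `crop_id` set on every field.
#' @export
distribute_crops <- function(landscape, portfolio, seed = 1L) {
  stopifnot(inherits(landscape, "ag_landscape"))
  if (!inherits(portfolio, "crop_portfolio"))
    stop("`portfolio` must be a crop_portfolio", call. = FALSE)
  nf <- length(landscape$fields)
  if (nf == 0) stop("landscape has no fields", call. = FALSE)
  areas <- vapply(landscape$fields, function(f) nrow(f$cells), integer(1))
  total <- sum(areas)
  deficit <- portfolio$share * total
  order_idx <- with_seed(seed, sample.int(nf))
  crop_of <- character(nf)
  for (i in order_idx) {
    k <- which.max(deficit)     # first max: portfolio order breaks ties
    crop_of[i] <- portfolio$crop_id[k]
    deficit[k] <- deficit[k] - areas[i]
  }
  for (i in seq_len(nf)) landscape$fields[[i]]$crop_id <- crop_of[i]
  landscape
}

#' Assign farmers or crops from a lookup table
#'
#' Direct mapping of identities to named fields; fields absent from the
#' table keep their current identity. The table can be a two-column data
#' frame (`field_id`, identity) as read from CSV.
#'
#' @param landscape an `ag_landscape`.
#' @param table data frame whose first column is `field_id` and second
#'   column the identity to assign.
#' @return the updated landscape.
#' @export
assign_farmers_by_table <- function(landscape, table) {
  assign_by_table(landscape, table, "farmer_id", as.integer)
}

#' @rdname assign_farmers_by_table
#' @export
assign_crops_by_table <- function(landscape, table) {
  assign_by_table(landscape, table, "crop_id", as.character)
}

assign_by_table <- function(landscape, table, slot, cast) {
  stopifnot(inherits(landscape, "ag_landscape"))
  if (nrow(table) == 0) return(landscape)
  ids <- vapply(landscape$fields, function(f) f$field_id, integer(1))
  unknown <- setdiff(table[[1]], ids)
  if (length(unknown))
    stop("unknown field_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pos <- match(table[[1]], ids)
  for (j in seq_along(pos))
    landscape$fields[[pos[j]]][[slot]] <- cast(table[[2]][j])
  landscape
}

#' Extract a categorical raster view of the landscape
#'
#' Produces the raster maps of the generated landscape: `"field"` (cell
#' value = field id, 0 elsewhere), `"arable_no_borders"` (1 on field cells
#' whose four rook neighbors all belong to the same field -- border cells,
#' including cells on the grid edge, become 0), `"crop"` and `"farmer"`
#' (integer identity codes; for crops the code-to-label mapping is attached
#' as the `legend` attribute), and `"potential_space"` (the binary mask).
#'
#' @param landscape an `ag_landscape`.
#' @param view one of `"field"`, `"arable_no_borders"`, `"crop"`,
#'   `"farmer"`, `"potential_space"`.
#' @return categorical [ag_grid]; crop views carry a `legend` attribute
#'   (named integer vector mapping labels to raster codes).
#' @export
extract_view <- function(landscape,
                         view = c("field", "arable_no_borders", "crop",
                                  "farmer", "potential_space")) {
  stopifnot(inherits(landscape, "ag_landscape"))
  view <- match.arg(view)
  mask <- landscape$space$mask
  nr <- mask$nrow; nc <- mask$ncol
  if (view == "potential_space") return(mask)
  fid <- matrix(0, nr, nc)
  for (f in landscape$fields)
    fid[cells_to_index(f$cells, nr)] <- f$field_id
  if (view == "field") return(ag_grid(fid, mask$resolution))
  if (view == "arable_no_borders") {
    pad <- matrix(-1, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- fid
    core <- pad[2:(nr + 1), 2:(nc + 1)]
    interior <- core > 0 &
      pad[1:nr, 2:(nc + 1)] == core & pad[3:(nr + 2), 2:(nc + 1)] == core &
      pad[2:(nr + 1), 1:nc] == core & pad[2:(nr + 1), 3:(nc + 2)] == core
    return(ag_grid(matrix(as.numeric(interior), nr, nc), mask$resolution))
  }
  slot <- if (view == "crop") "crop_id" else "farmer_id"
  vals <- lapply(landscape$fields, `[[`, slot)
  if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1))))
    stop(sprintf("%s view requires every field to carry a %s; run %s first",
                 view, slot,
                 if (view == "crop") "distribute_crops()" else "distribute_farmers()"),
         call. = FALSE)
  if (view == "crop") {
    labels <- sort(unique(unlist(vals)))
    codes <- stats::setNames(seq_along(labels), labels)
    out <- matrix(0, nr, nc)
    for (f in landscape$fields)
      out[cells_to_index(f$cells, nr)] <- codes[[f$crop_id]]
    g <- ag_grid(out, mask$resolution)
    attr(g, "legend") <- codes
    return(g)
  }
  out <- matrix(0, nr, nc)
  for (f in landscape$fields)
    out[cells_to_index(f$cells, nr)] <- f$farmer_id
  ag_grid(out, mask$resolution)
}

#' Write a view's legend as JSON
#'
#' Crop rasters encode opaque crop labels as integer codes; this writes the
#' sidecar legend (code to label) next to the raster.
#'
#' @param view a grid returned by [extract_view()] with a `legend`
#'   attribute.
#' @param path output path (`.json`).
#' @export
write_legend <- function(view, path) {
  legend <- attr(view, "legend")
  if (is.null(legend)) stop("view carries no legend", call. = FALSE)
  jsonlite::write_json(as.list(legend), path, auto_unbox = TRUE)
  invisible(path)
}
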