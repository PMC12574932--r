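# Configuration-driven orchestration of the three-step workflow, plus the
# double-gradient (potential space x arable cover) experiment. A run is
# fully reproducible from its configuration: every stochastic step draws
# its seed deterministically from the master seed.

#' Pipeline run configuration
#'
#' Validates and assembles the configuration of one generator run. The
#' configuration round-trips through YAML ([read_run_config()] /
#' [write_run_config()]) unchanged, and an identical configuration yields
#' byte-identical outputs.
#'
#' @param nrow,ncol grid dimensions. Default 200 x 200 (2 km x 2 km at
#'   10 m).
#' @param resolution cell size in meters.
#' @param potential list: `method` (`"perlin_share"`, `"perlin_threshold"`
#'   or `"external"`), plus `share` or `threshold`, fractal-noise controls
#'   (`frequency`, `octaves`, `lacunarity`, `gain`), or `path` to an
#'   external mask raster.
#' @param features optional list of feature specs, each a list with `kind`
#'   (`"road"`/`"river"`) and `width` (odd).
#' @param placement list: `algorithm` (`"pac"`/`"dl"`) plus
#'   [field_params()] arguments.
#' @param farmers optional list of [farmer_params()] arguments.
#' @param crops optional list with `crops` and `shares` for
#'   [crop_portfolio()].
#' @param views raster views to write (see [extract_view()]).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(nrow = 200, ncol = 200, resolution = 10,
                       potential = list(method = "perlin_share", share = 0.6),
                       features = NULL,
                       placement = list(algorithm = "pac"),
                       farmers = NULL, crops = NULL,
                       views = c("field", "potential_space"),
                       seed = 1L) {
  method <- potential$method %||% "perlin_share"
  if (!method %in% c("perlin_share", "perlin_threshold", "external"))
    stop("unknown potential-space method: ", method, call. = FALSE)
  if (method == "perlin_share" && is.null(potential$share))
    stop("method 'perlin_share' requires `potential$share`", call. = FALSE)
  if (method == "perlin_threshold" && is.null(potential$threshold))
    stop("method 'perlin_threshold' requires `potential$threshold`",
         call. = FALSE)
  if (method == "external" && is.null(potential$path))
    stop("method 'external' requires `potential$path`", call. = FALSE)
  bad_views <- setdiff(views, c("field", "arable_no_borders", "crop",
                                "farmer", "potential_space"))
  if (length(bad_views))
    stop("unknown view(s): ", paste(bad_views, collapse = ", "), call. = FALSE)
  if ("crop" %in% views && is.null(crops))
    stop("crop view requested but no crop portfolio configured", call. = FALSE)
  if ("farmer" %in% views && is.null(farmers))
    stop("farmer view requested but no farmer parameters configured",
         call. = FALSE)
  for (f in features %||% list())
    if (!(f$kind %||% "") %in% c("road", "river"))
      stop("feature kind must be 'road' or 'river'", call. = FALSE)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 resolution = resolution, potential = potential,
                 features = features, placement = placement,
                 farmers = farmers, crops = crops, views = views,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full generation pipeline
#'
#' Executes potential-space delineation, optional road/river carving, field
#' placement and optional enrichment as configured, then writes the
#' requested raster views (ESRI ASCII), the serialised landscape
#' (`landscape.json`), the arable-class metric profile (`profile.csv`), the
#' effective configuration (`config.yaml`) and, for crop views, the code
#' legend (`crop_legend.json`) into `out_dir`. Inconsistent configurations
#' fail validation before any computation; identical configurations produce
#' byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory, created if missing.
#' @return `out_dir`, invisibly; the generated `ag_landscape` is attached
#'   as attribute `landscape`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- function(k) derive_seed(cfg$seed, k)
  pot <- cfg$potential
  slope <- NULL
  if ((pot$method %||% "perlin_share") == "external") {
    space <- load_external(read_raster(pot$path))
  } else {
    slope <- generate_perlin_slope(
      cfg$nrow, cfg$ncol,
      perlin_params(frequency = pot$frequency %||% 4,
                    octaves = pot$octaves %||% 3,
                    lacunarity = pot$lacunarity %||% 2,
                    gain = pot$gain %||% 0.5,
                    seed = s(1L)),
      resolution = cfg$resolution)
    space <- if (pot$method == "perlin_share")
      categorize_by_share(slope, pot$share)
    else categorize_by_threshold(slope, pot$threshold)
  }
  for (i in seq_along(cfg$features %||% list())) {
    f <- cfg$features[[i]]
    cost_map <- slope %||% stop("features need a slope map; use a perlin method",
                                call. = FALSE)
    gen <- if (f$kind == "road") generate_road else generate_river
    cells <- gen(cost_map, width = f$width %||% 1L, seed = s(100L + i))
    space <- exclude_from_potential(space, cells)
  }
  pl <- cfg$placement
  fp <- field_params(mean_size = pl$mean_size %||% 1.5,
                     sd_size = pl$sd_size %||% 0.5,
                     size_distribution = pl$size_distribution %||% "normal",
                     mean_shape = pl$mean_shape %||% 2,
                     sd_shape = pl$sd_shape %||% 0.5,
                     coverage = pl$coverage %||% 0.7,
                     seed = s(2L))
  land <- if ((pl$algorithm %||% "pac") == "pac") establish_pac(space, fp)
          else establish_dl(space, fp)
  if (!is.null(cfg$farmers)) {
    fa <- cfg$farmers
    land <- distribute_farmers(land, farmer_params(
      mean_fields = fa$mean_fields %||% 4, sd_fields = fa$sd_fields %||% 2,
      distribution = fa$distribution %||% "normal",
      mode = fa$mode %||% "spatial", seed = s(3L)))
  }
  if (!is.null(cfg$crops)) {
    land <- distribute_crops(
      land, crop_portfolio(cfg$crops$crops, cfg$crops$shares), seed = s(4L))
  }
  if (!is.null(slope)) write_raster(slope, file.path(out_dir, "slope.asc"))
  for (v in cfg$views) {
    g <- extract_view(land, v)
    write_raster(g, file.path(out_dir, paste0(v, ".asc")))
    if (!is.null(attr(g, "legend")))
      write_legend(g, file.path(out_dir, paste0(v, "_legend.json")))
  }
  write_landscape(land, file.path(out_dir, "landscape.json"))
  prof <- compute_profile(arable_class_map(land), 1)
  write_profile(prof, file.path(out_dir, "profile.csv"))
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  structure(invisible(out_dir), landscape = land)
}

#' Double-gradient landscape experiment
#'
#' Generates landscapes over a factorial (or Latin-hypercube subsampled)
#' design crossing the share of potential space, the share of that space
#' covered by arable fields, and field size and shape levels, then profiles
#' the seminatural class: potential-space cells not converted to fields
#' (class 2; arable fields are class 1, the matrix outside the potential
#' space class 3). An arable share of 0 leaves the whole potential space
#' seminatural.
#'
#' @param space_shares,arable_shares,sizes,shapes,seeds numeric factor
#'   levels; `sizes` in hectares, `shapes` as length:width ratios, `seeds`
#'   integer.
#' @param nrow,ncol,resolution grid geometry. Default 100 x 100 at 10 m.
#' @param lhs_n if not `NULL`, draw this many Latin-hypercube samples over
#'   the four parameter factors (each crossed with every seed) instead of
#'   the full factorial.
#' @param design_seed seed for the Latin-hypercube draw.
#' @param metrics seminatural-class metrics to report.
#' @return long-format data frame: one row per design point x metric, with
#'   columns `space_share`, `arable_share`, `mean_size`, `mean_shape`,
#'   `seed`, `metric`, `value`.
#' @export
run_gradient_experiment <- function(space_shares, arable_shares, sizes,
                                    shapes, seeds,
                                    nrow = 100, ncol = 100, resolution = 10,
                                    lhs_n = NULL, design_seed = 1L,
                                    metrics = c("np", "area_mn", "lpi",
                                                "frac_mn", "para_mn",
                                                "enn_mn")) {
  stopifnot(length(space_shares) > 0, length(arable_shares) > 0,
            length(sizes) > 0, length(shapes) > 0, length(seeds) > 0)
  design <- if (is.null(lhs_n)) {
    expand.grid(space_share = space_shares, arable_share = arable_shares,
                mean_size = sizes, mean_shape = shapes, seed = seeds)
  } else {
    u <- with_seed(design_seed, lhs::randomLHS(lhs_n, 4L))
    level <- function(uu, lv) lv[pmin(length(lv), floor(uu * length(lv)) + 1L)]
    pts <- data.frame(space_share = level(u[, 1], space_shares),
                      arable_share = level(u[, 2], arable_shares),
                      mean_size = level(u[, 3], sizes),
                      mean_shape = level(u[, 4], shapes))
    merge(pts, data.frame(seed = seeds))
  }
  rows <- lapply(seq_len(base::nrow(design)), function(i) {
    d <- design[i, ]
    slope <- generate_perlin_slope(nrow, ncol,
                                   perlin_params(seed = d$seed),
                                   resolution = resolution)
    space <- categorize_by_share(slope, d$space_share)
    mv <- space$mask$values
    cls <- matrix(3, nrow, ncol)
    cls[which(!is.na(mv) & mv == 1)] <- 2
    cls[which(is.na(mv))] <- NA
    if (d$arable_share > 0) {
      land <- suppressWarnings(establish_pac(space, field_params(
        mean_size = d$mean_size, sd_size = 0, mean_shape = d$mean_shape,
        sd_shape = 0, coverage = d$arable_share, seed = d$seed)))
      for (f in land$fields) cls[cells_to_index(f$cells, nrow)] <- 1
    }
    prof <- compute_profile(ag_grid(cls, resolution), 2, metrics = metrics)
    data.frame(space_share = d$space_share, arable_share = d$arable_share,
               mean_size = d$mean_size, mean_shape = d$mean_shape,
               seed = d$seed, metric = names(prof), value = unname(prof),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
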