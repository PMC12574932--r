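# Pattern-oriented calibration: an elitist genetic algorithm searches the
# generator's parameter space for settings whose landscapes reproduce a
# reference metric profile; the calibrated settings can then produce any
# number of statistically equivalent maps.

#' Generate a landscape in one call
#'
#' Convenience wrapper around the three-step workflow used by the fitness
#' function, the pipeline and the equivalent-map generator: a fractal-noise
#' slope map is categorised by share into potential space and tessellated
#' into fields. All randomness derives from `seed`.
#'
#' @param nrow,ncol grid dimensions.
#' @param resolution cell size in meters. Default 10.
#' @param space_share share of the grid available as potential space.
#' @param coverage fraction of the potential space covered by fields.
#' @param mean_size,sd_size field size distribution (ha).
#' @param size_distribution `"normal"` or `"lognormal"`.
#' @param mean_shape,sd_shape field length:width ratio distribution.
#' @param frequency,octaves fractal-noise controls (see [perlin_params()]).
#' @param algorithm `"pac"` or `"dl"`.
#' @param seed integer seed.
#' @return an `ag_landscape`.
#' @export
generate_landscape <- function(nrow, ncol, resolution = 10,
                               space_share = 0.6, coverage = 0.7,
                               mean_size = 1, sd_size = 0.5,
                               size_distribution = "normal",
                               mean_shape = 2, sd_shape = 0.5,
                               frequency = 4, octaves = 3,
                               algorithm = c("pac", "dl"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  slope <- generate_perlin_slope(
    nrow, ncol,
    perlin_params(frequency = frequency, octaves = round(octaves),
                  seed = seed),
    resolution = resolution)
  space <- categorize_by_share(slope, space_share)
  fp <- field_params(mean_size = mean_size, sd_size = sd_size,
                     size_distribution = size_distribution,
                     mean_shape = mean_shape, sd_shape = sd_shape,
                     coverage = coverage, seed = seed)
  fn <- if (algorithm == "pac") establish_pac else establish_dl
  suppressWarnings(fn(space, fp))
}

#' Genetic algorithm configuration
#'
#' Conventional elitist-GA defaults: tournament selection (k = 3), uniform
#' crossover, per-gene Gaussian mutation with sigma = 10 percent of the
#' gene range, one elite copied unchanged. Fitness of a chromosome is the
#' mean [profile_distance()] score of `replicates_per_eval` generated
#' landscapes against the reference profile, damping generator noise.
#'
#' @param population population size, >= 2. Default 20.
#' @param generations maximum generations. Default 30.
#' @param crossover_prob,mutation_prob operator probabilities in (0, 1).
#' @param elitism chromosomes carried over unchanged, < population.
#' @param replicates_per_eval landscapes generated per fitness evaluation.
#' @param metric_subset metric names defining the optimisation goal.
#' @param seed integer master seed; all evaluation seeds derive from it.
#' @param stop_fitness optional early-stop threshold on best fitness.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population = 20, generations = 30,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      elitism = 1, replicates_per_eval = 3,
                      metric_subset = c("np", "area_mn", "area_sd"),
                      seed = 1L, stop_fitness = NULL) {
  stopifnot(population >= 2, elitism < population, generations >= 1,
            crossover_prob > 0, crossover_prob < 1,
            mutation_prob > 0, mutation_prob < 1,
            replicates_per_eval >= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism),
                 replicates_per_eval = as.integer(replicates_per_eval),
                 metric_subset = metric_subset,
                 seed = as.integer(seed),
                 stop_fitness = stop_fitness),
            class = "ga_config")
}

#' Binary arable-class map of a landscape
#'
#' Collapses the field view to field presence (1) versus everything else
#' (0); the class map on which reference and generated metric profiles are
#' computed during calibration.
#'
#' @param landscape an `ag_landscape`.
#' @return binary [ag_grid].
#' @export
arable_class_map <- function(landscape) {
  fv <- extract_view(landscape, "field")
  ag_grid(matrix(as.numeric(fv$values > 0), fv$nrow, fv$ncol),
          fv$resolution)
}

# derive a deterministic evaluation seed below 2^31
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 10007 + counter) %% 2147483629)
}

#' Fitness of a parameter chromosome
#'
#' Decodes the genes into generator parameters (unnamed parameters fall
#' back to the `context` defaults), generates `replicates_per_eval`
#' landscapes with seeds derived from `eval_seed`, and returns the mean
#' similarity of their arable-class metric profiles to the reference.
#' Degenerate parameters that produce no fields score 0 rather than
#' erroring.
#'
#' @param genes named numeric vector; names must be arguments of
#'   [generate_landscape()] (e.g. `space_share`, `coverage`, `mean_size`).
#' @param reference named reference metric profile.
#' @param cfg a [ga_config()].
#' @param context list with `nrow`, `ncol`, `resolution` and any fixed
#'   generator arguments.
#' @param eval_seed base seed for this evaluation's replicates.
#' @return fitness in \[0, 1\].
#' @export
ga_fitness <- function(genes, reference, cfg, context, eval_seed = cfg$seed) {
  scores <- vapply(seq_len(cfg$replicates_per_eval), function(r) {
    args <- c(list(nrow = context$nrow, ncol = context$ncol,
                   resolution = context$resolution %||% 10,
                   seed = derive_seed(eval_seed, r - 1L)),
              context$fixed %||% list(), as.list(genes))
    land <- tryCatch(do.call(generate_landscape, args),
                     error = function(e) NULL)
    if (is.null(land) || length(land$fields) == 0) return(0)
    prof <- compute_profile(arable_class_map(land), 1,
                            metrics = cfg$metric_subset)
    if (anyNA(prof[cfg$metric_subset])) return(0)
    profile_distance(prof, reference, cfg$metric_subset)
  }, numeric(1))
  mean(scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate generator parameters with a genetic algorithm
#'
#' Searches the bounded parameter space for a chromosome whose generated
#' landscapes best match the reference metric profile. Tournament selection
#' (k = 3), uniform crossover, clipped Gaussian mutation and elitism; the
#' elite's cached fitness is carried over, so the best-fitness trace is
#' non-decreasing by construction. Fully seeded: identical inputs yield an
#' identical search.
#'
#' @param reference named reference metric profile.
#' @param bounds named list of `c(low, high)` per searched gene; names are
#'   [generate_landscape()] arguments and define the gene order.
#' @param cfg a [ga_config()].
#' @param context see [ga_fitness()].
#' @param fitness_fn optional replacement fitness `function(genes,
#'   eval_seed)` (used to benchmark the optimiser on analytic functions).
#' @return list with `best` (named gene vector), `best_fitness`, `trace`
#'   (best fitness per generation, including the initial population as
#'   generation 0) and `generations_run`.
#' @export
run_ga <- function(reference, bounds, cfg = ga_config(),
                   context = list(nrow = 100, ncol = 100, resolution = 10),
                   fitness_fn = NULL) {
  gene_names <- names(bounds)
  stopifnot(length(gene_names) > 0, !is.null(gene_names))
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  stopifnot(all(hi > lo))
  k <- length(bounds)
  if (is.null(fitness_fn)) {
    fitness_fn <- function(genes, eval_seed)
      ga_fitness(genes, reference, cfg, context, eval_seed)
  }
  counter <- 0L
  evaluate <- function(genes) {
    counter <<- counter + 1L
    fitness_fn(stats::setNames(genes, gene_names),
               derive_seed(cfg$seed, counter * 1000L))
  }
  with_seed(cfg$seed, {
    pop <- matrix(runif(cfg$population * k, lo, hi),
                  nrow = cfg$population, ncol = k, byrow = TRUE)
    fit <- apply(pop, 1, evaluate)
    trace <- max(fit)
    best_i <- which.max(fit)
    best <- pop[best_i, ]; best_fit <- fit[best_i]
    gen <- 0L
    while (gen < cfg$generations &&
           (is.null(cfg$stop_fitness) || best_fit < cfg$stop_fitness)) {
      gen <- gen + 1L
      elite_ord <- order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]
      newpop <- matrix(NA_real_, cfg$population, k)
      newfit <- rep(NA_real_, cfg$population)
      newpop[seq_len(cfg$elitism), ] <- pop[elite_ord, , drop = FALSE]
      newfit[seq_len(cfg$elitism)] <- fit[elite_ord]
      tournament <- function() {
        cand <- sample.int(cfg$population, 3L, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      for (i in (cfg$elitism + 1L):cfg$population) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        child <- if (runif(1) < cfg$crossover_prob) {
          pick <- runif(k) < 0.5
          ifelse(pick, p1, p2)
        } else p1
        mut <- runif(k) < cfg$mutation_prob
        child[mut] <- child[mut] + rnorm(sum(mut), 0, 0.1 * (hi - lo)[mut])
        child <- pmin(pmax(child, lo), hi)
        newpop[i, ] <- child
        newfit[i] <- evaluate(child)
      }
      pop <- newpop; fit <- newfit
      gbest <- which.max(fit)
      if (fit[gbest] > best_fit) { best_fit <- fit[gbest]; best <- pop[gbest, ] }
      trace <- c(trace, max(fit))
    }
    list(best = stats::setNames(best, gene_names),
         best_fitness = best_fit,
         trace = trace,
         generations_run = gen)
  })
}

#' Generate landscapes equivalent to a calibrated reference
#'
#' Runs the generator `n` times with the calibrated parameters and `n`
#' distinct seeds, and summarises the spread of both the optimised and any
#' held-out metrics across the sample, mirroring the equivalent-map
#' workflow: maps share the calibrated metric values statistically while
#' differing in spatial arrangement.
#'
#' @param best named gene vector (from [run_ga()]).
#' @param n number of maps, >= 1.
#' @param seed integer seed; map i uses a seed derived from `seed` and `i`.
#' @param context as in [ga_fitness()].
#' @param metrics metric names to profile (optimised plus held-out).
#' @return list with `landscapes`, `profiles` (one row per map) and
#'   `summary` (quartiles per metric).
#' @export
generate_equivalents <- function(best, n, seed = 1L,
                                 context = list(nrow = 100, ncol = 100,
                                                resolution = 10),
                                 metrics = c("np", "area_mn", "area_sd",
                                             "contag", "lpi", "frac_mn",
                                             "lsi", "shape_mn")) {
  stopifnot(n >= 1)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  landscapes <- lapply(seeds, function(s) {
    args <- c(list(nrow = context$nrow, ncol = context$ncol,
                   resolution = context$resolution %||% 10, seed = s),
              context$fixed %||% list(), as.list(best))
    do.call(generate_landscape, args)
  })
  profiles <- do.call(rbind, lapply(seq_along(landscapes), function(i) {
    p <- compute_profile(arable_class_map(landscapes[[i]]), 1,
                         metrics = metrics)
    data.frame(map = i, seed = seeds[i], t(p))
  }))
  summ <- do.call(rbind, lapply(metrics, function(m) {
    q <- stats::quantile(profiles[[m]], c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(metric = m, q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
  list(landscapes = landscapes, profiles = profiles, summary = summ)
}
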