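test_that("field dimensions follow the size/shape arithmetic", {
  p <- field_params(mean_size = 1, sd_size = 0, mean_shape = 1, sd_shape = 0)
  d <- draw_field_dims(p, resolution = 10)
  expect_equal(d$target_cells, 100L)
  expect_equal(d$segment_length, 10L)
  expect_equal(d$n_segments, 10L)
  p4 <- field_params(mean_size = 1, sd_size = 0, mean_shape = 4, sd_shape = 0)
  d4 <- draw_field_dims(p4, resolution = 10)
  expect_equal(d4$segment_length, 20L)
  expect_equal(d4$n_segments, 5L)
  # coarser grids change the hectare-to-cell conversion
  d50 <- draw_field_dims(p, resolution = 50)
  expect_equal(d50$target_cells, 4L)
})

test_that("lognormal sizes are moment-matched", {
  p <- field_params(mean_size = 1, sd_size = 0.5,
                    size_distribution = "lognormal")
  draws <- agriscape:::with_seed(3, replicate(1e5, draw_field_dims(p)$size_ha))
  expect_equal(mean(draws), 1, tolerance = 0.02)
  expect_equal(sd(draws), 0.5, tolerance = 0.05)
})

test_that("place-and-conquer fills a free square with one exact field", {
  ps <- load_external(ag_grid(matrix(1, 10, 10)))
  land <- establish_pac(ps, field_params(mean_size = 1, sd_size = 0,
                                         mean_shape = 1, sd_shape = 0,
                                         coverage = 1, seed = 2))
  expect_length(land$fields, 1)
  expect_equal(nrow(land$fields[[1]]$cells), 100)
  expect_equal(realized_coverage(land), 1)
})

test_that("an isolated cell yields a one-cell field by truncation", {
  m <- matrix(0, 8, 8); m[4, 4] <- 1
  ps <- load_external(ag_grid(m))
  land <- establish_pac(ps, field_params(mean_size = 0.25, sd_size = 0,
                                         coverage = 1, seed = 1))
  expect_length(land$fields, 1)
  expect_equal(nrow(land$fields[[1]]$cells), 1)
})

test_that("both algorithms respect disjointness, containment and connectivity", {
  for (seed in 1:6) {
    ps <- fixture_space(50, 0.6, seed = seed)
    fp <- field_params(mean_size = 1, coverage = 0.8, seed = seed)
    for (land in list(establish_pac(ps, fp), establish_dl(ps, fp))) {
      expect_valid_fields(land)
      sizes <- vapply(land$fields, function(f) nrow(f$cells), integer(1))
      expect_equal(realized_coverage(land),
                   sum(sizes) / sum(ps$mask$values))
    }
  }
})

test_that("realised coverage lands within one-field slack of the request", {
  for (seed in 1:6) {
    ps <- fixture_space(50, 0.6, seed = seed)
    land <- establish_pac(ps, field_params(mean_size = 1, coverage = 0.8,
                                           seed = seed))
    sizes <- vapply(land$fields, function(f) nrow(f$cells), integer(1))
    slack <- max(sizes) / sum(ps$mask$values)
    expect_gte(realized_coverage(land), 0.8 - slack)
    expect_lte(realized_coverage(land), 0.8 + slack)
  }
})

test_that("dead leaves covers the mask fully at coverage 1 and prunes smallest-first", {
  ps <- fixture_space(50, 0.6, seed = 3)
  full <- establish_dl(ps, field_params(mean_size = 1, coverage = 1, seed = 3))
  expect_equal(realized_coverage(full), 1)
  pruned <- establish_dl(ps, field_params(mean_size = 1, coverage = 0.7,
                                          seed = 3))
  expect_lte(realized_coverage(pruned), 0.7 + 1e-12)
  kept <- vapply(pruned$fields, function(f) nrow(f$cells), integer(1))
  removed_sizes <- setdiff_sizes(full, pruned)
  if (length(removed_sizes)) expect_gte(min(kept), max(removed_sizes))
})

test_that("coverage response is monotone in the coverage parameter", {
  ps <- fixture_space(40, 0.6, seed = 9)
  cov_grid <- seq(0.05, 1, length.out = 20)
  got <- vapply(cov_grid, function(cv) {
    realized_coverage(suppressWarnings(
      establish_pac(ps, field_params(mean_size = 0.5, coverage = cv, seed = 9))))
  }, numeric(1))
  expect_true(all(diff(got) >= -1e-12))
})

test_that("elongated shape draws make elongated fields", {
  elong <- function(shape, seed) {
    ps <- load_external(ag_grid(matrix(1, 60, 60)))
    land <- establish_pac(ps, field_params(mean_size = 1, sd_size = 0,
                                           mean_shape = shape, sd_shape = 0,
                                           coverage = 0.5, seed = seed))
    mean(vapply(land$fields, function(f) {
      h <- diff(range(f$cells[, 1])) + 1
      w <- diff(range(f$cells[, 2])) + 1
      max(h, w) / min(h, w)
    }, numeric(1)))
  }
  wins <- sum(vapply(1:25, function(s) elong(3, s) > elong(1, s), logical(1)))
  expect_gte(wins, 24)
})

test_that("placement is deterministic in (mask, params, seed)", {
  ps <- fixture_space(40, 0.6, seed = 5)
  fp <- field_params(mean_size = 1, coverage = 0.7, seed = 11)
  a <- establish_pac(ps, fp); b <- establish_pac(ps, fp)
  expect_identical(a$fields, b$fields)
  a2 <- establish_dl(ps, fp); b2 <- establish_dl(ps, fp)
  expect_identical(a2$fields, b2$fields)
})

test_that("extreme demands on a tiny mask complete without error", {
  # fields far larger than the space: truncation absorbs the demand and the
  # whole mask ends up covered by (possibly single-cell) fields
  m <- matrix(0, 10, 10); m[1, 1:3] <- 1; m[5, 7] <- 1
  ps <- load_external(ag_grid(m))
  land <- establish_pac(ps, field_params(mean_size = 5, sd_size = 0,
                                         coverage = 1, seed = 1))
  expect_true(land$coverage_reached)
  expect_equal(realized_coverage(land), 1)
  expect_valid_fields(land)
})

test_that("landscapes round-trip through JSON serialisation", {
  ps <- fixture_space(30, 0.6, seed = 8)
  land <- establish_pac(ps, field_params(mean_size = 0.5, coverage = 0.6,
                                         seed = 8))
  land <- distribute_farmers(land, farmer_params(seed = 2))
  land <- distribute_crops(land, crop_portfolio(c("wheat", "maize"),
                                                c(0.6, 0.4)), seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_landscape(land, f)
  back <- read_landscape(f)
  expect_equal(length(back$fields), length(land$fields))
  for (i in seq_along(land$fields)) {
    o <- land$fields[[i]]; b <- back$fields[[i]]
    expect_setequal(paste(o$cells[, 1], o$cells[, 2]),
                    paste(b$cells[, 1], b$cells[, 2]))
    expect_equal(b$farmer_id, o$farmer_id)
    expect_equal(b$crop_id, o$crop_id)
  }
  expect_equal(back$space$mask$values, land$space$mask$values)
})
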