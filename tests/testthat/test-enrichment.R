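make_land <- function(n = 30, share = 0.6, coverage = 0.6, mean_size = 0.3,
                      seed = 1) {
  establish_pac(fixture_space(n, share, seed),
                field_params(mean_size = mean_size, sd_size = 0.1,
                             coverage = coverage, seed = seed))
}

test_that("farmer assignment partitions the fields", {
  land <- make_land(seed = 4)
  land <- distribute_farmers(land, farmer_params(mean_fields = 4,
                                                 sd_fields = 2, seed = 7))
  ids <- vapply(land$fields, function(f) f$farmer_id, integer(1))
  expect_false(anyNA(ids))
  expect_equal(sort(unique(ids)), seq_len(max(ids)))
  # one field -> one farmer
  one <- land
  one$fields <- land$fields[1]
  one <- distribute_farmers(one, farmer_params(seed = 1))
  expect_equal(one$fields[[1]]$farmer_id, 1L)
})

test_that("a one-field-per-farmer draw yields as many farmers as fields", {
  land <- make_land(seed = 5)
  land <- distribute_farmers(land, farmer_params(mean_fields = 1,
                                                 sd_fields = 0,
                                                 distribution = "uniform",
                                                 seed = 2))
  ids <- vapply(land$fields, function(f) f$farmer_id, integer(1))
  expect_equal(sort(ids), seq_along(land$fields))
})

test_that("spatial farmer assignment clusters fields more than random", {
  land <- make_land(40, coverage = 0.7, mean_size = 0.2, seed = 6)
  expect_gte(length(land$fields), 30)
  mean_within <- function(mode, seed) {
    l <- distribute_farmers(land, farmer_params(mean_fields = 4, sd_fields = 0,
                                                mode = mode, seed = seed))
    cent <- agriscape:::field_centroids(l$fields)
    ids <- vapply(l$fields, function(f) f$farmer_id, integer(1))
    mean(unlist(lapply(split(seq_along(ids), ids), function(ix) {
      if (length(ix) < 2) return(NULL)
      as.vector(dist(cent[ix, , drop = FALSE]))
    })))
  }
  wins <- sum(vapply(1:20, function(s)
    mean_within("spatial", s) < mean_within("random", s), logical(1)))
  expect_gte(wins, 19)
})

test_that("crop distribution consumes the portfolio with a bounded error", {
  land <- make_land(40, coverage = 0.7, mean_size = 0.2, seed = 12)
  pf <- crop_portfolio(c("a", "b", "c"), c(0.5, 0.3, 0.2))
  land <- distribute_crops(land, pf, seed = 11)
  areas <- vapply(land$fields, function(f) nrow(f$cells), integer(1))
  crops <- vapply(land$fields, function(f) f$crop_id, character(1))
  total <- sum(areas)
  realized <- vapply(pf$crop_id, function(cr) sum(areas[crops == cr]) / total,
                     numeric(1))
  expect_equal(sum(realized), 1)
  expect_lte(max(abs(realized - pf$share)), max(areas) / total)
  # error shrinks when mean field size halves
  small <- make_land(40, coverage = 0.7, mean_size = 0.1, seed = 12)
  small <- distribute_crops(small, pf, seed = 11)
  a2 <- vapply(small$fields, function(f) nrow(f$cells), integer(1))
  c2 <- vapply(small$fields, function(f) f$crop_id, character(1))
  r2 <- vapply(pf$crop_id, function(cr) sum(a2[c2 == cr]) / sum(a2),
               numeric(1))
  expect_lt(max(abs(r2 - pf$share)), max(abs(realized - pf$share)))
})

test_that("single-crop portfolios and forced splits behave exactly", {
  land <- make_land(seed = 3)
  all_one <- distribute_crops(land, crop_portfolio("only", 1), seed = 1)
  expect_true(all(vapply(all_one$fields, function(f) f$crop_id,
                         character(1)) == "only"))
  # four equal fields, two crops at 0.5/0.5 -> two fields each
  four <- land
  four$fields <- lapply(1:4, function(i)
    agriscape:::new_field(cbind(row = i - 1L, col = 0:3), i))
  four <- distribute_crops(four, crop_portfolio(c("x", "y"), c(0.5, 0.5)),
                           seed = 5)
  tab <- table(vapply(four$fields, function(f) f$crop_id, character(1)))
  expect_equal(as.vector(tab[c("x", "y")]), c(2L, 2L))
  expect_error(distribute_crops(land, list()), "crop_portfolio")
})

test_that("table assignment touches exactly the listed fields", {
  land <- make_land(seed = 9)
  land <- distribute_farmers(land, farmer_params(seed = 1))
  before <- vapply(land$fields, function(f) f$farmer_id, integer(1))
  expect_identical(assign_farmers_by_table(land, data.frame(field_id = integer(0),
                                                            farmer_id = integer(0))),
                   land)
  upd <- assign_farmers_by_table(land, data.frame(field_id = c(1, 3),
                                                  farmer_id = c(99, 98)))
  after <- vapply(upd$fields, function(f) f$farmer_id, integer(1))
  expect_equal(after[c(1, 3)], c(99L, 98L))
  expect_equal(after[-c(1, 3)], before[-c(1, 3)])
  expect_error(assign_crops_by_table(land, data.frame(field_id = 10^6,
                                                      crop_id = "z")),
               "unknown field_id")
  full <- assign_crops_by_table(land, data.frame(
    field_id = seq_along(land$fields),
    crop_id = rep("w", length(land$fields))))
  expect_true(all(vapply(full$fields, function(f) f$crop_id,
                         character(1)) == "w"))
})

test_that("raster views reproduce field geometry and border logic", {
  # a single 3x3 field: only the centre survives border removal
  ps <- load_external(ag_grid(matrix(1, 5, 5)))
  land <- agriscape:::new_landscape(
    list(agriscape:::new_field(as.matrix(expand.grid(row = 1:3, col = 1:3)), 1L)),
    ps, field_params(), "pac")
  v <- extract_view(land, "arable_no_borders")
  expect_equal(sum(v$values), 1)
  expect_equal(v$values[3, 3], 1)
  # field view recounts each field's cells
  land2 <- make_land(seed = 10)
  fv <- extract_view(land2, "field")
  for (f in land2$fields)
    expect_equal(sum(fv$values == f$field_id), nrow(f$cells))
  # bijection between nonzero raster ids and the field list
  expect_setequal(setdiff(unique(as.vector(fv$values)), 0),
                  vapply(land2$fields, function(f) f$field_id, integer(1)))
  # empty landscape -> all-zero field view
  empty <- land2
  empty$fields <- list()
  expect_true(all(extract_view(empty, "field")$values == 0))
  # identity views demand identities
  expect_error(extract_view(land2, "crop"), "distribute_crops")
  land2 <- distribute_crops(land2, crop_portfolio(c("b", "a"), c(0.5, 0.5)),
                            seed = 1)
  cv <- extract_view(land2, "crop")
  legend <- attr(cv, "legend")
  expect_equal(names(legend), c("a", "b"))
  for (f in land2$fields)
    expect_true(all(cv$values[agriscape:::cells_to_index(f$cells, cv$nrow)] ==
                      legend[[f$crop_id]]))
  expect_equal(extract_view(land2, "potential_space")$values,
               land2$space$mask$values)
})
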