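# Independent oracles used to verify package computations. These are
# deliberately written with naive direct-definition algorithms (R loops,
# igraph graphs) distinct from the package's implementations.

# component count by igraph on an explicitly built adjacency graph
oracle_component_count <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(!is.na(mask) & mask == 1)
  if (!length(fg)) return(0L)
  coord <- cbind((fg - 1L) %% nr, (fg - 1L) %/% nr)
  id <- seq_along(fg)
  lookup <- new.env()
  for (i in id) assign(paste(coord[i, 1], coord[i, 2]), i, envir = lookup)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1),
                    c(0,1), c(1,-1), c(1,0), c(1,1))
  edges <- c()
  for (i in id) {
    for (d in offs) {
      key <- paste(coord[i, 1] + d[1], coord[i, 2] + d[2])
      j <- mget(key, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# plain O(V^2) Dijkstra over the same cost model, built independently:
# 8-neighbour steps, weight = step length * mean of endpoint cell costs
oracle_dijkstra_cost <- function(cost, start, end) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- nr * nc
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  s <- start[1] + 1 + start[2] * nr
  e <- end[1] + 1 + end[2] * nr
  dist[s] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    if (u == e) break
    done[u] <- TRUE
    ur <- (u - 1) %% nr; uc <- (u - 1) %/% nr
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- ur + dr; c2 <- uc + dc
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) next
      v <- r2 + 1 + c2 * nr
      if (is.na(cost[u]) || is.na(cost[v])) next
      step <- sqrt(dr^2 + dc^2)
      w <- step * (cost[u] + cost[v]) / 2
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist[e]
}

# direct-definition landscape metric oracle: naive loops over cells
oracle_profile <- function(mat, class_id, res, connectivity = 8) {
  nr <- nrow(mat); nc <- ncol(mat)
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  is_cls <- function(r, c) inb(r, c) && !is.na(mat[r, c]) && mat[r, c] == class_id
  # flood fill with an explicit stack
  lab <- matrix(0L, nr, nc)
  k <- 0L
  offs <- if (connectivity == 8)
    list(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else list(c(-1,0),c(1,0),c(0,-1),c(0,1))
  for (cc in 1:nc) for (rr in 1:nr) {
    if (!is_cls(rr, cc) || lab[rr, cc] != 0L) next
    k <- k + 1L
    stack <- list(c(rr, cc)); lab[rr, cc] <- k
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in offs) {
        r2 <- cur[1] + d[1]; c2 <- cur[2] + d[2]
        if (is_cls(r2, c2) && lab[r2, c2] == 0L) {
          lab[r2, c2] <- k
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  n_valid <- sum(!is.na(mat))
  land_m2 <- n_valid * res^2
  land_ha <- land_m2 / 1e4
  out <- c(np = k, area_mn = NA, area_sd = NA, lpi = NA, contag = NA,
           ed = 0, enn_mn = NA, enn_sd = NA, shape_mn = NA, lsi = NA,
           frac_mn = NA, para_mn = NA)
  if (k > 0) {
    areas <- numeric(k); perims <- numeric(k)
    for (cc in 1:nc) for (rr in 1:nr) {
      p <- lab[rr, cc]
      if (p == 0L) next
      areas[p] <- areas[p] + res^2
      for (d in list(c(-1,0),c(1,0),c(0,-1),c(0,1))) {
        r2 <- rr + d[1]; c2 <- cc + d[2]
        if (!inb(r2, c2) || lab[r2, c2] != p) perims[p] <- perims[p] + res
      }
    }
    out["area_mn"] <- mean(areas) / 1e4
    if (k > 1) out["area_sd"] <- sd(areas) / 1e4
    out["lpi"] <- 100 * max(areas) / land_m2
    out["ed"] <- sum(perims) / land_ha
    out["shape_mn"] <- mean(0.25 * perims / sqrt(areas))
    out["para_mn"] <- mean(perims / areas)
    out["frac_mn"] <- mean(2 * log(0.25 * perims) / log(areas))
    out["lsi"] <- 0.25 * sum(perims) / sqrt(sum(areas))
    if (k > 1) {
      enn <- rep(Inf, k)
      cells <- lapply(seq_len(k), function(p) which(lab == p, arr.ind = TRUE))
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        a <- cells[[i]]; b <- cells[[j]]
        dm <- Inf
        for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b)))
          dm <- min(dm, sqrt(sum((a[x, ] - b[y, ])^2)))
        enn[i] <- min(enn[i], dm); enn[j] <- min(enn[j], dm)
      }
      out["enn_mn"] <- mean(enn * res)
      out["enn_sd"] <- sd(enn * res)
    }
  }
  # contagion over all classes, counting each rook adjacency from both sides
  classes <- sort(unique(mat[!is.na(mat)]))
  m <- length(classes)
  if (m >= 2) {
    g <- matrix(0, m, m)
    for (cc in 1:nc) for (rr in 1:nr) {
      if (is.na(mat[rr, cc])) next
      a <- match(mat[rr, cc], classes)
      for (d in list(c(-1,0),c(1,0),c(0,-1),c(0,1))) {
        r2 <- rr + d[1]; c2 <- cc + d[2]
        if (inb(r2, c2) && !is.na(mat[r2, c2]))
          g[a, match(mat[r2, c2], classes)] <-
            g[a, match(mat[r2, c2], classes)] + 1
      }
    }
    pr <- as.numeric(table(factor(mat[!is.na(mat)], levels = classes)))
    pr <- pr / sum(pr)
    acc <- 0
    for (i in 1:m) {
      if (sum(g[i, ]) == 0) next
      q <- pr[i] * g[i, ] / sum(g[i, ])
      q <- q[q > 0]
      acc <- acc + sum(q * log(q))
    }
    out["contag"] <- 100 * (1 + acc / (2 * log(m)))
  }
  out
}

# Moran's I with queen (8-neighbour) binary weights by direct double sum
oracle_morans_i <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  m <- mean(mat)
  dev <- mat - m
  num <- 0; s0 <- 0
  for (cc in 1:nc) for (rr in 1:nr) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- rr + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      num <- num + dev[rr, cc] * dev[r2, c2]
      s0 <- s0 + 1
    }
  }
  (nr * nc / s0) * num / sum(dev^2)
}

# brute-force Chebyshev dilation
oracle_dilate <- function(cells, radius, nr, nc) {
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    for (dr in -radius:radius) for (dc in -radius:radius) {
      r <- cells[i, 1] + dr; c <- cells[i, 2] + dc
      if (r >= 0 && r < nr && c >= 0 && c < nc) out <- rbind(out, c(r, c))
    }
  }
  unique(out)
}

# shared fixture: a seeded potential space on a fractal slope map
fixture_space <- function(n = 50, share = 0.6, seed = 1) {
  categorize_by_share(
    generate_perlin_slope(n, n, perlin_params(seed = seed)), share)
}

# check that every field is 4-connected, inside the mask, and disjoint
expect_valid_fields <- function(land) {
  mask <- land$space$mask
  all_idx <- integer(0)
  for (f in land$fields) {
    idx <- f$cells[, 1] + 1L + f$cells[, 2] * mask$nrow
    expect_true(all(mask$values[idx] == 1))
    bin <- matrix(0, mask$nrow, mask$ncol)
    bin[idx] <- 1
    expect_equal(connected_components(ag_grid(bin), 4)$n, 1L)
    all_idx <- c(all_idx, idx)
  }
  expect_equal(length(all_idx), length(unique(all_idx)))
}

# multiset difference of field sizes between a full and a pruned tessellation
setdiff_sizes <- function(full, pruned) {
  fs <- sort(vapply(full$fields, function(f) nrow(f$cells), integer(1)))
  ps <- sort(vapply(pruned$fields, function(f) nrow(f$cells), integer(1)))
  for (s in ps) fs <- fs[-match(s, fs)]
  fs
}

METRIC_NAMES_T <- c("np", "area_mn", "area_sd", "lpi", "contag", "ed",
                    "enn_mn", "enn_sd", "shape_mn", "lsi", "frac_mn",
                    "para_mn")
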