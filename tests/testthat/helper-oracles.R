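# Independent brute-force oracles used to cross-check the package's
# vectorized implementations.

# Classic scalar crossing-parity point-in-polygon (pnpoly-style), combined
# over multiple polygons by the even-odd rule.
oracle_point_in_polygons <- function(px, py, polys) {
  inside <- FALSE
  for (poly in polys) {
    n <- nrow(poly)
    j <- n
    for (i in seq_len(n)) {
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > py) != (yj > py)) {
        xint <- (poly[j, 1] - poly[i, 1]) * (py - yi) / (yj - yi) + poly[i, 1]
        if (px < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# Direct voxel loop mean dose.
oracle_mean_dose <- function(grid, mask) {
  total <- 0; count <- 0
  for (k in seq_len(grid$shape[3])) {
    for (j in seq_len(grid$shape[2])) {
      for (i in seq_len(grid$shape[1])) {
        if (mask$included[i, j, k] && !is.na(grid$values[i, j, k])) {
          total <- total + grid$values[i, j, k]
          count <- count + 1
        }
      }
    }
  }
  total / count
}

# Independent loop implementation of iterative outlier-excluded 3-sigma
# limit estimation (re-screens all observations each pass).
oracle_chart <- function(values, estimator = "sd", max_iter = 10) {
  inc <- rep(TRUE, length(values))
  iter <- 0
  repeat {
    v <- values[inc]
    m <- sum(v) / length(v)
    s <- if (estimator == "sd") {
      if (length(v) > 1) sqrt(sum((v - m)^2) / (length(v) - 1)) else 0
    } else {
      if (length(v) > 1) {
        steps <- abs(v[-1] - v[-length(v)])
        (sum(steps) / length(steps)) / 1.128
      } else 0
    }
    u <- m + 3 * s
    l <- m - 3 * s
    ninc <- values >= l & values <= u
    if (all(ninc == inc)) break
    if (iter >= max_iter) break
    inc <- ninc
    iter <- iter + 1
  }
  list(mu = m, sigma = s, ucl = u, lcl = l, excluded = which(!inc))
}

# Random simple polygon: convex hull of random points (always non-self-
# intersecting).
random_convex_polygon <- function(n = 8, scale = 20) {
  pts <- matrix(stats::runif(2 * n, 0, scale), ncol = 2)
  hull <- grDevices::chull(pts)
  pts[hull, , drop = FALSE]
}

# Small random grid + mask pair for mean-dose checks.
random_grid_and_mask <- function(max_side = 10) {
  shp <- sample(2:max_side, 3, replace = TRUE)
  g <- dose_grid(stats::runif(3, -10, 10), stats::runif(3, 0.5, 3), shp,
                 stats::runif(prod(shp), 0, 70))
  inc <- array(stats::runif(prod(shp)) < 0.4, dim = shp)
  if (!any(inc)) inc[1, 1, 1] <- TRUE
  m <- structure(list(shape = shp, included = inc), class = "voxel_mask")
  list(grid = g, mask = m)
}

# Two-sided summary pair with given mean doses (role swap helper).
make_summary_pair <- function(case_id, ref_doses, local_doses,
                              params = NULL) {
  list(reference = plan_dose_summary(case_id, "reference", ref_doses),
       local = plan_dose_summary(case_id, "local", local_doses,
                                 params = params))
}
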