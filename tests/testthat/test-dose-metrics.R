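grid_10 <- function(values = runif(1000, 0, 70)) {
  # voxel centers at odd mm 1, 3, ..., 19 along each axis
  dose_grid(c(1, 1, 1), c(2, 2, 2), c(10, 10, 10), values)
}

square <- function(x0, y0, side) {
  matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side, x0, y0 + side),
         ncol = 2, byrow = TRUE)
}

test_that("square contour rasterizes to the expected slice mask", {
  g <- grid_10()
  s <- rt_structure("PTV1", list(list(z = 5, vertices = square(0, 0, 20))))
  m <- rasterize_structure(s, g)
  expect_equal(sum(m$included), 100)          # full 10x10 slice
  expect_true(all(which(m$included, arr.ind = TRUE)[, 3] == 3))  # z = 5 slice

  # contour entirely outside the grid -> empty mask error naming the structure
  far <- rt_structure("cord", list(list(z = 5, vertices = square(100, 100, 5))))
  expect_error(rasterize_structure(far, g), "empty mask.*cord")
})

test_that("concentric squares combine by the even-odd rule into a ring", {
  g <- grid_10()
  ring <- rt_structure("ring", list(
    list(z = 5, vertices = square(0, 0, 20)),
    list(z = 5, vertices = square(4, 4, 12))))
  m <- rasterize_structure(ring, g)
  # brute-force even-odd oracle over every voxel center on that slice
  expected <- 0
  for (x in seq(1, 19, 2)) for (y in seq(1, 19, 2)) {
    if (oracle_point_in_polygons(x, y, list(square(0, 0, 20), square(4, 4, 12)))) {
      expected <- expected + 1
    }
  }
  expect_equal(sum(m$included), expected)
  # and equals outer minus inner counts
  outer_n <- sum(rasterize_structure(
    rt_structure("o", list(list(z = 5, vertices = square(0, 0, 20)))), g)$included)
  inner_n <- sum(rasterize_structure(
    rt_structure("i", list(list(z = 5, vertices = square(4, 4, 12)))), g)$included)
  expect_equal(sum(m$included), outer_n - inner_n)
})

test_that("rasterization agrees with a point-in-polygon oracle on random polygons", {
  set.seed(101)
  g <- dose_grid(c(0.5, 0.5, 0), c(1, 1, 2), c(20, 20, 3), rep(1, 1200))
  for (rep in 1:100) {
    poly <- random_convex_polygon(n = sample(4:10, 1))
    s <- tryCatch(rt_structure("s", list(list(z = 2, vertices = poly))),
                  error = function(e) NULL)
    if (is.null(s)) next
    m <- tryCatch(rasterize_structure(s, g), error = function(e) NULL)
    got <- if (is.null(m)) matrix(FALSE, 20, 20) else m$included[, , 2]
    for (i in seq(1, 20, by = 3)) for (j in seq(1, 20, by = 3)) {
      expect_identical(got[i, j],
                       oracle_point_in_polygons(i - 0.5, j - 0.5, list(poly)),
                       label = sprintf("rep %d voxel (%d,%d)", rep, i, j))
    }
  }
})

test_that("mean dose matches the brute-force voxel loop and symmetry cases", {
  g <- grid_10(rep(2, 1000))
  s <- rt_structure("any", list(list(z = 5, vertices = square(0, 0, 20))))
  m <- rasterize_structure(s, g)
  expect_equal(mean_dose(g, m), 2.0)

  # dose linear in x over a mask symmetric about x = 10 -> value at x = 10
  xs <- axis_coords(g, 1)
  lin <- array(rep(0.5 * xs + 1, 100), dim = c(10, 10, 10))
  gl <- dose_grid(g$origin, g$spacing, g$shape, lin)
  expect_equal(mean_dose(gl, m), 0.5 * 10 + 1)

  set.seed(11)
  for (i in 1:20) {
    gm <- random_grid_and_mask(10)
    expect_equal(mean_dose(gm$grid, gm$mask), oracle_mean_dose(gm$grid, gm$mask))
  }

  empty <- structure(list(shape = g$shape,
                          included = array(FALSE, dim = g$shape)),
                     class = "voxel_mask")
  expect_error(mean_dose(g, empty), "empty mask")
})

test_that("mean dose is invariant under joint translation of grid and structure", {
  set.seed(12)
  g <- grid_10()
  s <- rt_structure("s", list(list(z = 7, vertices = square(2, 4, 10))))
  d0 <- mean_dose(g, rasterize_structure(s, g))
  shift <- c(13.7, -4.2, 6.5)
  g2 <- dose_grid(g$origin + shift, g$spacing, g$shape, g$values)
  s2 <- rt_structure("s", list(list(z = 7 + shift[3],
                                    vertices = sweep(square(2, 4, 10), 2, shift[1:2], "+"))))
  expect_equal(mean_dose(g2, rasterize_structure(s2, g2)), d0)
})

test_that("trilinear resampling is exact on identity, affine and constant fields", {
  g <- grid_10()
  r <- resample_dose(g, g$origin, g$spacing, g$shape)
  expect_identical(r$values, g$values)   # identity geometry, bitwise

  # affine field reproduced exactly at interior points
  co <- lapply(1:3, function(a) axis_coords(g, a))
  aff <- outer(outer(0.3 * co[[1]], 0.2 * co[[2]], "+"), 0.1 * co[[3]], "+") + 5
  ga <- dose_grid(g$origin, g$spacing, g$shape, aff)
  r2 <- resample_dose(ga, c(2.3, 3.1, 4.7), c(1.7, 2.9, 3.3), c(5, 5, 4))
  tc <- lapply(1:3, function(a) c(2.3, 3.1, 4.7)[a] +
                 (seq_len(c(5, 5, 4)[a]) - 1) * c(1.7, 2.9, 3.3)[a])
  want <- outer(outer(0.3 * tc[[1]], 0.2 * tc[[2]], "+"), 0.1 * tc[[3]], "+") + 5
  expect_equal(r2$values, want, tolerance = 1e-12)

  # constant field stays constant; exterior points become NA
  gc <- grid_10(rep(2, 1000))
  r3 <- resample_dose(gc, c(-3, 5, 5), c(4, 4, 4), c(8, 4, 4))
  expect_true(all(r3$values[!is.na(r3$values)] == 2))
  expect_true(anyNA(r3$values))       # the x < 1 mm columns are unsupported
  expect_error(resample_dose(gc, c(500, 500, 500), c(2, 2, 2), c(4, 4, 4)),
               "outside source support")
})

test_that("percent difference follows the reference-relative convention", {
  p <- make_summary_pair("A", c(brain = 2.0), c(brain = 2.2))
  cmp <- percent_difference(p$local, p$reference)
  expect_equal(cmp$pct_diff, 10.0)

  same <- make_summary_pair("A", c(brain = 2, PTV1 = 60), c(brain = 2, PTV1 = 60))
  cmp2 <- percent_difference(same$local, same$reference)
  expect_equal(cmp2$pct_diff, c(0, 0))

  # near-zero reference structures are skipped with a warning, not divided by
  low <- make_summary_pair("A", c(brain = 2, lens = 0.0), c(brain = 2.1, lens = 0.5))
  expect_warning(cmp3 <- percent_difference(low$local, low$reference), "floor")
  expect_equal(cmp3$structure, "brain")

  expect_error(percent_difference(
    plan_dose_summary("A", "local", c(x = 1)),
    plan_dose_summary("A", "reference", c(y = 1))), "no shared structures")
  expect_error(percent_difference(
    plan_dose_summary("A", "local", c(x = 1)),
    plan_dose_summary("B", "reference", c(x = 1))), "case mismatch")
})

test_that("role swap obeys the exact antisymmetry relation", {
  set.seed(13)
  for (i in 1:25) {
    ref <- runif(1, 1, 70)
    loc <- ref * runif(1, 0.8, 1.2)
    d <- percent_difference(plan_dose_summary("A", "local", c(s = loc)),
                            plan_dose_summary("A", "reference", c(s = ref)))$pct_diff
    d_sw <- percent_difference(plan_dose_summary("A", "local", c(s = ref)),
                               plan_dose_summary("A", "reference", c(s = loc)))$pct_diff
    expect_equal(d_sw, -100 * d / (100 + d), tolerance = 1e-10)
  }
})

test_that("summarize_plan composes per-structure mean doses and warns on misses", {
  g <- grid_10(rep(3, 1000))
  ss <- structure_set(list(
    rt_structure("A", list(list(z = 5, vertices = square(0, 0, 20)))),
    rt_structure("B", list(list(z = 9, vertices = square(4, 4, 8)))),
    rt_structure("outside", list(list(z = 5, vertices = square(200, 200, 5))))))
  expect_warning(summ <- summarize_plan(g, ss, "case1", "reference"), "outside")
  expect_setequal(names(summ$mean_dose_by_structure), c("A", "B"))
  expect_equal(unname(summ$mean_dose_by_structure), c(3, 3))
  # matches per-structure mean_dose called individually
  mA <- mean_dose(g, rasterize_structure(ss$structures$A, g))
  expect_equal(summ$mean_dose_by_structure[["A"]], mA)
  # frame mismatch refused
  ss2 <- structure_set(list(ss$structures$A), frame_id = "OTHER")
  expect_error(summarize_plan(g, ss2, "c", "local"), "frame mismatch")
})

test_that("comparison CSV round-trips", {
  spec <- cohort_spec(data.frame(name = c("a", "b"), offset_pct = c(0, 1),
                                 noise_pct = c(0.5, 0.5)),
                      n_cases = 5, seed = 3,
                      params = machine_parameters(0.2, 0.02, "AAA"))
  df <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  write_comparisons(df, path)
  back <- read_comparisons(path)
  expect_equal(back$pct_diff, df$pct_diff)
  expect_equal(back$dlg_cm, df$dlg_cm)
  expect_equal(back$algorithm, df$algorithm)
})
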