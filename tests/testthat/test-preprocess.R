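test_that("offset correction zeroes row means and is shift-invariant", {
  m <- rbind(c(5, 5, 5), c(1, 2, 3))
  out <- offset_correct(m)
  expect_equal(unname(out), rbind(c(0, 0, 0), c(-1, 0, 1)))
  expect_lt(max(abs(rowMeans(out))), 1e-12)

  set.seed(1)
  x <- matrix(rnorm(50), 5)
  expect_equal(offset_correct(x + 17.3), offset_correct(x))
})

test_that("linear baseline through anchors removes ramps, keeps peaks", {
  grid <- seq(650, 2000, by = 2)
  ramp <- 0.003 * grid + 1.2
  m <- rbind(ramp)
  out <- baseline_linear(m, grid, anchors = c(650, 2000))
  expect_lt(max(abs(out)), 1e-8)

  peak <- exp(-4 * log(2) * (grid - 1300)^2 / 20^2)
  out2 <- baseline_linear(rbind(peak + ramp), grid, anchors = c(700, 1900))
  expect_equal(drop(out2), peak, tolerance = 1e-8)

  expect_error(baseline_linear(m, grid, anchors = c(500, 2000)), "outside")
  expect_error(baseline_linear(m, grid, anchors = 800), "2 anchors")
})

test_that("Savitzky-Golay derivatives match analytic oracles in per-cm units", {
  for (h in c(1, 2, 4)) {
    grid <- seq(1000, 1000 + 40 * h, by = h)
    quad <- 2 + 0.5 * grid + 0.01 * grid^2
    m <- rbind(3 * grid, grid^2, quad)
    interior <- 5:(length(grid) - 4)

    smooth <- savgol(m, grid, window = 9, polyorder = 2, deriv = 0)
    expect_equal(smooth[3, interior], quad[interior], tolerance = 1e-10)

    d1 <- savgol(m, grid, window = 9, polyorder = 3, deriv = 1)
    expect_equal(d1[1, interior], rep(3, length(interior)), tolerance = 1e-8)

    d2 <- savgol(m, grid, window = 9, polyorder = 3, deriv = 2)
    expect_equal(d2[2, interior], rep(2, length(interior)), tolerance = 1e-8)
  }
})

test_that("savgol validates grid, window and flags edge columns", {
  grid <- seq(1000, 1080, by = 2)
  m <- rbind(sin(grid / 10))
  expect_error(savgol(m, grid^1.01), "uniform")
  expect_error(savgol(m, grid, window = 99), "exceeds")
  expect_error(savgol(m, grid, window = 8), "odd")
  expect_error(savgol(m, grid, polyorder = 1, deriv = 2), "polyorder")

  out <- savgol(m, grid, window = 9)
  expect_equal(attr(out, "edge_cols"), c(1:4, 38:41))
  expect_equal(dim(out), dim(m))
})

test_that("SNV standardizes rows and is affine-invariant", {
  expect_equal(unname(snv(rbind(c(1, 2, 3)))), rbind(c(-1, 0, 1)))

  set.seed(2)
  for (i in 1:100) {
    x <- matrix(rnorm(40), 2)
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 5)
    expect_equal(snv(a * x + b), snv(x), tolerance = 1e-10)
  }
  out <- snv(matrix(rnorm(60), 3))
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-12)

  m <- rbind(c(1, 2, 3), c(4, 4, 4))
  rownames(m) <- c("ok", "flat")
  expect_error(snv(m), "'flat'")
})

test_that("region selection keeps the inclusive union in original order", {
  grid <- seq(600, 2100, by = 2)
  m <- matrix(rnorm(2 * length(grid)), 2)
  sel <- select_regions(m, grid, list(c(2000, 650)))
  expect_true(all(sel$grid >= 650 & sel$grid <= 2000))
  expect_true(650 %in% sel$grid && 2000 %in% sel$grid)

  nested <- select_regions(m, grid, list(c(1500, 980), c(1500, 900)))
  alone <- select_regions(m, grid, list(c(1500, 900)))
  expect_identical(nested, alone)

  expect_error(select_regions(m, grid, list(c(500, 400))), "no grid points")

  # union column count against a brute-force point-by-point check
  set.seed(3)
  for (i in 1:20) {
    g <- sort(runif(60, 600, 2100))
    regs <- replicate(3, sort(runif(2, 600, 2100)), simplify = FALSE)
    regs <- lapply(regs, rev)
    ok <- vapply(regs, function(r) any(g >= min(r) & g <= max(r)), logical(1))
    if (!all(ok)) next
    manual <- sum(vapply(g, function(v)
      any(vapply(regs, function(r) v >= min(r) && v <= max(r), logical(1))),
      logical(1)))
    got <- select_regions(matrix(0, 1, 60), g, regs)
    expect_equal(ncol(got$matrix), manual)
  }
})

test_that("apply_recipe composes steps in order and is pure", {
  d <- small_design(seed = 5)
  dat <- generate_calibration_set(d)

  empty <- apply_recipe(dat$set, preprocess_recipe())
  expect_identical(empty$matrix, dat$set$matrix)

  once <- apply_recipe(dat$set, preprocess_recipe(step_offset()))
  twice <- apply_recipe(dat$set, preprocess_recipe(step_offset(), step_offset()))
  expect_equal(twice$matrix, once$matrix, tolerance = 1e-14)

  rec <- preprocess_recipe(step_savgol(9, 3, 1), step_snv(),
                           step_regions(list(c(1500, 900))),
                           drop_edges = FALSE)
  auto <- apply_recipe(dat$set, rec)
  manual <- savgol(dat$set$matrix, dat$set$grid, 9, 3, 1)
  attr(manual, "edge_cols") <- NULL
  manual <- snv(manual)
  manual <- select_regions(manual, dat$set$grid, list(c(1500, 900)))
  expect_equal(auto$matrix, manual$matrix)
  expect_equal(auto$grid, manual$grid)

  again <- apply_recipe(dat$set, rec)
  expect_identical(auto, again)
})

test_that("flagged savgol edges are dropped from the design by default", {
  d <- small_design(seed = 6, grid = seq(650, 800, by = 2))
  dat <- generate_calibration_set(d)
  rec <- preprocess_recipe(step_savgol(9, 3, 1))
  out <- apply_recipe(dat$set, rec)
  expect_equal(length(out$grid), length(dat$set$grid) - 8)
  expect_false(any(out$grid %in% c(head(dat$set$grid, 4), tail(dat$set$grid, 4))))
})

test_that("recipe validation rejects malformed steps", {
  expect_error(preprocess_recipe(list(op = "wavelet")), "unknown")
  expect_error(preprocess_recipe(step_savgol(8, 3, 1)), "odd")
  expect_error(preprocess_recipe(step_savgol(9, 1, 2)), "polyorder")
  expect_error(preprocess_recipe(step_regions(list())), "non-empty")
  expect_error(preprocess_recipe(step_regions(list(c(900, 1500)))), NA)
  expect_error(preprocess_recipe(step_regions(list(c(900, 900)))), "high > low")
})
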