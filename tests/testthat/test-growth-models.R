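# printed parameter triples used throughout
vb_model <- function() growth_model("von_bertalanffy", 174.607, 0.852, 0.006)
logi_model <- function() growth_model("logistic", 130.404, 24.613, 0.018)
gomp_model <- function() growth_model("gompertz", 153.244, 4.307, 0.009)

test_that("predict_weight evaluates each family and saturates at A", {
  m <- vb_model()
  expect_equal(predict_weight(m, 1e7), 174.607, tolerance = 1e-9)
  expect_equal(predict_weight(m, 0), 174.607 * (1 - 0.852)^3, tolerance = 1e-12)
  expect_equal(predict_weight(m, 0), 0.56607, tolerance = 1e-4)
  expect_equal(predict_weight(logi_model(), 0), 130.404 / 25.613,
               tolerance = 1e-12)
  expect_equal(predict_weight(logi_model(), 0), 5.0913, tolerance = 1e-4)
  expect_equal(predict_weight(gomp_model(), 1e7), 153.244, tolerance = 1e-9)
  # vectorized and bounded by A, increasing for vb with b < 1
  tt <- seq(0, 800, by = 10)
  y <- predict_weight(m, tt)
  expect_length(y, length(tt))
  expect_true(all(y > 0 & y <= m$A))
  expect_true(all(diff(y) > 0))
})

test_that("invalid parameters and negative ages are rejected", {
  expect_error(growth_model("logistic", NA, 1, 0.01), "non-finite")
  expect_error(growth_model("gompertz", 100, -1, 0.01), "must all be > 0")
  m <- vb_model()
  expect_error(predict_weight(m, -5), "age must be >= 0")
  expect_silent(predict_weight(m, -5, allow_negative_age = TRUE))
  expect_error(growth_rate(m, 10, order = 4), "unsupported")
})

test_that("analytic derivatives agree with central finite differences", {
  models <- list(vb_model(), logi_model(), gomp_model(),
                 growth_model("von_bertalanffy", 80, 0.6, 0.02))
  grid <- seq(5, 600, length.out = 40)
  h <- 1e-3
  for (m in models) {
    fd1 <- (predict_weight(m, grid + h) - predict_weight(m, grid - h)) / (2 * h)
    expect_equal(growth_rate(m, grid, 1L), fd1, tolerance = 1e-6)
    fd2 <- (growth_rate(m, grid + h, 1L) - growth_rate(m, grid - h, 1L)) / (2 * h)
    expect_equal(growth_rate(m, grid, 2L), fd2, tolerance = 1e-6)
    fd3 <- (growth_rate(m, grid + h, 2L) - growth_rate(m, grid - h, 2L)) / (2 * h)
    expect_equal(growth_rate(m, grid, 3L), fd3, tolerance = 1e-6)
    expect_true(all(growth_rate(m, grid, 1L) >= 0))
    expect_lt(growth_rate(m, 1e6, 1L), 1e-12)
  }
})

test_that("maximum growth rate matches the closed forms per family", {
  # published magnitude for the Von Bertalanffy triple
  rep_vb <- inflection_points(vb_model())
  expect_equal(growth_rate(vb_model(), rep_vb$t_MGI), 0.46562, tolerance = 5e-3)
  expect_equal(rep_vb$max_rate_g_per_day, 465.61, tolerance = 5e-3)
  # Gompertz max rate A*k/e at t = ln(b)/k
  expect_equal(growth_rate(gomp_model(), log(4.307) / 0.009),
               153.244 * 0.009 / exp(1), tolerance = 1e-12)
  expect_equal(growth_rate(gomp_model(), log(4.307) / 0.009), 0.50738,
               tolerance = 1e-4)
  # parameter-free closed forms, random models
  set.seed(42)
  for (i in 1:20) {
    A <- runif(1, 50, 300); b <- runif(1, 4, 30); k <- runif(1, 0.003, 0.05)
    closed <- c(logistic = A * k / 4, gompertz = A * k / exp(1),
                von_bertalanffy = 4 * A * k / 9)
    for (fam in names(closed)) {
      bb <- if (fam == "von_bertalanffy") min(b / 10, 0.99) else b
      m <- growth_model(fam, A, bb, k)
      r <- suppressWarnings(inflection_points(m))  # small-b GRI may pre-date birth
      expect_equal(growth_rate(m, r$t_MGI), closed[[fam]],
                   tolerance = 1e-10,
                   info = paste(fam, "closed-form max rate"))
    }
  }
})

test_that("inflection report reproduces the published staging numbers", {
  r <- inflection_points(vb_model())
  expect_equal(r$t_MGI, 156.40, tolerance = 5e-3)
  expect_equal(r$t_GRI, 23.82, tolerance = 5e-3)
  expect_equal(r$t_RSI, 288.97, tolerance = 5e-3)
  expect_equal(r$w_MGI, 51.73, tolerance = 5e-3)
  expect_equal(r$w_GRI, 3.14, tolerance = 1e-2)
  expect_equal(r$w_RSI, 107.03, tolerance = 5e-3)
})

test_that("inflection invariants hold: ordering, weight fractions, maximum", {
  models <- list(vb_model(), logi_model(), gomp_model())
  fracs <- c(logistic = 1 / 2, gompertz = exp(-1), von_bertalanffy = 8 / 27)
  for (m in models) {
    r <- inflection_points(m)
    expect_true(r$t_GRI < r$t_MGI && r$t_MGI < r$t_RSI)
    expect_true(r$w_GRI < r$w_MGI && r$w_MGI < r$w_RSI)
    expect_true(all(c(r$w_GRI, r$w_MGI, r$w_RSI) > 0 &
                      c(r$w_GRI, r$w_MGI, r$w_RSI) < m$A))
    expect_equal(r$w_MGI / m$A, fracs[[m$family]], tolerance = 1e-12)
    # first derivative is maximized at t_MGI over a dense grid
    grid <- seq(0, 3 * r$t_RSI, length.out = 2000)
    expect_true(all(growth_rate(m, grid) <=
                      growth_rate(m, r$t_MGI) + 1e-12))
  }
  # w_GRI/A and w_RSI/A are parameter-free constants per family
  set.seed(7)
  for (i in 1:10) {
    m1 <- growth_model("logistic", runif(1, 50, 200), runif(1, 2, 40),
                       runif(1, 0.005, 0.05))
    r1 <- inflection_points(m1)
    expect_equal(r1$w_GRI / m1$A, (3 - sqrt(3)) / 6, tolerance = 1e-12)
    expect_equal(r1$w_RSI / m1$A, (3 + sqrt(3)) / 6, tolerance = 1e-12)
  }
})

test_that("degenerate and pre-birth roots are flagged, symmetric logistic", {
  r <- suppressWarnings(inflection_points(growth_model("logistic", 100, 1, 0.02)))
  expect_equal(r$t_MGI, 0, tolerance = 1e-12)
  expect_equal(r$w_MGI, 50, tolerance = 1e-12)
  expect_warning(inflection_points(growth_model("logistic", 100, 0.5, 0.02)),
                 "negative age")
  expect_true(suppressWarnings(
    inflection_points(growth_model("logistic", 100, 0.5, 0.02)))$negative_age)
})

test_that("closed-form roots match bisection on the analytic derivatives", {
  set.seed(1)
  for (fam in c("logistic", "gompertz", "von_bertalanffy")) {
    for (i in 1:10) {
      b <- if (fam == "von_bertalanffy") runif(1, 0.5, 0.99) else runif(1, 4, 40)
      m <- growth_model(fam, runif(1, 50, 300), b, runif(1, 0.004, 0.04))
      r <- suppressWarnings(inflection_points(m))
      num <- numeric_inflections(m)
      expect_equal(r$t_MGI, num[["MGI"]], tolerance = 1e-6)
      expect_equal(r$t_GRI, num[["GRI"]], tolerance = 1e-6)
      expect_equal(r$t_RSI, num[["RSI"]], tolerance = 1e-6)
    }
  }
})

test_that("stage partition is exhaustive, non-overlapping, with MGI in RIS", {
  r <- inflection_points(vb_model())
  expect_equal(as.character(stage_of(r, 0)), "GIS")
  expect_equal(as.character(stage_of(r, r$t_MGI)), "RIS")
  expect_equal(as.character(stage_of(r, 300)), "SIS")
  expect_equal(as.character(stage_of(r, r$t_GRI)), "GIS")       # boundary in GIS
  expect_equal(as.character(stage_of(r, r$t_RSI)), "RIS")       # boundary in RIS
  grid <- seq(0, 500, by = 0.5)
  st <- stage_of(r, grid)
  expect_false(any(is.na(st)))
  expect_true(all(diff(as.integer(st)) >= 0))                   # monotone stages
  expect_error(stage_of(r, -1), "age must be >= 0")
})

test_that("growth reports round-trip through JSON", {
  r <- inflection_points(vb_model())
  path <- tempfile(fileext = ".json")
  write_growth_report(r, path)
  r2 <- read_growth_report(path)
  expect_equal(r2$t_MGI, r$t_MGI, tolerance = 1e-12)
  expect_equal(r2$max_rate_g_per_day, r$max_rate_g_per_day, tolerance = 1e-12)
  expect_equal(r2$model$family, "von_bertalanffy")
})
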