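test_that("stress matches direct evaluation of the normalized distance discrepancy", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(stress(X, X), 0)

  # distances {1, 1, sqrt(2)} against an equilateral triangle of side 1
  Yeq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  # numerator (sqrt(2) - 1)^2, denominator (6 - 4 sqrt(2)) / 3: exactly 3/2
  expect_equal(stress(X, Yeq), oracle_stress(X, Yeq), tolerance = 1e-12)
  expect_equal(stress(X, Yeq), 1.5, tolerance = 1e-12)

  # invariant to rigid motion of either configuration
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(stress(X, Yeq %*% R + 5), stress(X, Yeq), tolerance = 1e-12)

  # asymmetric: the denominator comes from the first configuration
  Y2 <- rbind(c(0, 0), c(2, 0), c(0, 1))
  expect_false(isTRUE(all.equal(stress(X, Y2), stress(Y2, X))))

  # random small configurations against the independent oracle
  withr::with_seed(101, {
    for (i in 1:20) {
      n <- sample(4:8, 1)
      A <- matrix(rnorm(2 * n), n, 2)
      B <- matrix(rnorm(2 * n), n, 2)
      expect_equal(stress(A, B), oracle_stress(A, B), tolerance = 1e-12)
    }
  })

  # equilateral reference: all d1 equal -> undefined
  expect_error(stress(Yeq, X), class = "attnspace_degenerate_error")
})

test_that("Procrustes alignment removes similarity transforms", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2))
  al0 <- procrustes_align(X, X)
  expect_equal(al0$stress, 0, tolerance = 1e-12)
  expect_equal(al0$scale, 1, tolerance = 1e-12)
  expect_equal(al0$Yaligned, X, tolerance = 1e-10)

  # rotated, reflected, scaled, shifted copy aligns to stress 0 with scaling
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) %*% rbind(c(1, 0), c(0, -1))
  Y <- 3 * X %*% R + 7
  al <- procrustes_align(X, Y, allow_scaling = TRUE)
  expect_equal(al$stress, 0, tolerance = 1e-12)
  expect_equal(al$scale, 1 / 3, tolerance = 1e-10)
  expect_true(det(al$rotation) < 0)  # reflection recovered

  # doubling without scaling: stress reflects the size difference
  X3 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  al2 <- procrustes_align(X3, 2 * X3, allow_scaling = FALSE)
  expect_equal(al2$scale, 1)
  expect_equal(al2$stress, oracle_stress(X3, 2 * X3), tolerance = 1e-12)
  expect_equal(al2$stress, 18 + 12 * sqrt(2), tolerance = 1e-12)
  # and with scaling on the magnification is absorbed
  al3 <- procrustes_align(X3, 2 * X3, allow_scaling = TRUE)
  expect_equal(al3$stress, 0, tolerance = 1e-12)
  expect_equal(al3$scale, 0.5, tolerance = 1e-12)

  expect_error(procrustes_align(X3, matrix(1, 3, 2)),
               class = "attnspace_degenerate_error")
})

test_that("alignment agrees with the vegan reference on scale-free fit", {
  skip_if_not_installed("vegan")
  withr::with_seed(61, {
    X <- matrix(rnorm(16), 8, 2)
    Y <- matrix(rnorm(16), 8, 2)
  })
  al <- procrustes_align(X, Y, allow_scaling = TRUE)
  ref <- vegan::procrustes(X, Y, scale = TRUE, symmetric = FALSE)
  # vegan's Yrot is in centered coordinates; add back the target centroid
  expect_equal(unname(al$Yaligned), unname(sweep(ref$Yrot, 2, ref$xmean, `+`)),
               tolerance = 1e-8)
  expect_equal(al$scale, ref$scale, tolerance = 1e-10)
  expect_equal(unname(al$rotation), unname(ref$rotation), tolerance = 1e-10)
  expect_equal(as.numeric(al$translation), as.numeric(ref$translation),
               tolerance = 1e-10)
})

test_that("alignment never increases stress for similarity-related pairs", {
  withr::with_seed(83, {
    for (i in 1:10) {
      X <- matrix(rnorm(16), 8, 2)
      th <- runif(1, 0, 2 * pi)
      R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      Y <- sweep(runif(1, 0.5, 2) * X %*% R, 2, rnorm(2), `+`)
      raw <- stress(X, Y)
      al <- procrustes_align(X, Y, allow_scaling = TRUE)
      expect_lte(al$stress, raw + 1e-12)
      expect_equal(al$stress, 0, tolerance = 1e-10)
    }
  })
})

test_that("convex hull summaries have the closed-form area and radius", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  h <- convex_hull_summary(sq)
  expect_equal(h$area, 1)
  expect_equal(h$mean_radius, sqrt(2) / 2)

  h2 <- convex_hull_summary(2 * sq)
  expect_equal(h2$area, 4)
  expect_equal(h2$mean_radius, sqrt(2))

  ang <- location_angles(8) * pi / 180
  oct <- convex_hull_summary(cbind(cos(ang), sin(ang)))
  expect_equal(oct$area, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(oct$mean_radius, 1, tolerance = 1e-12)

  expect_error(convex_hull_summary(cbind(1:4, 2 * (1:4))),
               class = "attnspace_degenerate_error")
})
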