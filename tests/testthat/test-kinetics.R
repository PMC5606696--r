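test_that("specific_rate matches the closed form and its limits", {
  p1 <- kinetic_params("Type I", 0.95, 0.48, 2000)
  p2 <- kinetic_params("Type II", 1.0, 0.5, 300)

  expect_identical(specific_rate(p1, 0), 0)
  # hand evaluation: 1.0*0.5 / ((0.5+0.5)*(1 + 0.5/300)) = 0.4991680532...
  expect_equal(specific_rate(p2, 0.5), 0.5 / (1 * (1 + 0.5 / 300)),
               tolerance = 1e-12)
  expect_equal(round(specific_rate(p2, 0.5), 4), 0.4992)

  # Michaelis-Menten limit as Ki -> infinity
  for (s in c(0.01, 0.5, 5, 50, 500)) {
    pmm <- kinetic_params("mm", 1.0, 0.5, 1e9)
    expect_lt(abs(specific_rate(pmm, s) - 1.0 * s / (0.5 + s)), 1e-6 * 1.0)
  }

  # rate is bounded above by vmax and zero only at s = 0
  s <- c(1e-6, 0.1, 1, 10, 1e4)
  expect_true(all(specific_rate(p1, s) < p1$vmax))
  expect_true(all(specific_rate(p1, s) > 0))

  expect_error(specific_rate(p1, -1), "negative")
  expect_error(kinetic_params("x", -1, 0.5, 300), "vmax")
  expect_error(kinetic_params("", 1, 0.5, 300), "label")
})

test_that("peak concentration is sqrt(Km*Ki) and matches a grid argmax", {
  expect_equal(peak_concentration(kinetic_params("a", 1, 1, 1)), 1)
  expect_equal(peak_concentration(kinetic_params("Type II", 1, 0.5, 300)),
               sqrt(0.5 * 300), tolerance = 1e-12)
  expect_equal(round(peak_concentration(kinetic_params("Type II", 1, 0.5,
                                                       300)), 3), 12.247)
  expect_equal(round(peak_concentration(kinetic_params("Type I", 0.95, 0.48,
                                                       2000)), 3), 30.984)

  set.seed(101)
  for (i in 1:5) {
    p <- random_params("p")
    grid <- seq(0.01, 3 * sqrt(p$km * p$ki), length.out = 1e4)
    argmax <- grid[which.max(specific_rate(p, grid))]
    expect_lt(abs(argmax - peak_concentration(p)), diff(grid[1:2]) * 1.5)
  }
})

test_that("rate curves are unimodal around the peak", {
  set.seed(202)
  for (i in 1:5) {
    p <- random_params("p")
    peak <- peak_concentration(p)
    up <- seq(peak / 1e3, peak, length.out = 1e4)
    down <- seq(peak, peak * 1e2, length.out = 1e4)
    expect_true(all(diff(specific_rate(p, up)) > 0))
    expect_true(all(diff(specific_rate(p, down)) < 0))
  }
})

test_that("rate_curve evaluates all populations on the grid", {
  pair <- published_pair()
  rc <- rate_curve(pair, grid = c(0.05, 0.5, 5, 50, 500))
  expect_named(rc, c("s", "Type I", "Type II"))
  expect_equal(rc[["Type I"]], haldane(0.95, 0.48, 2000, rc$s),
               tolerance = 1e-12)
  # Type II leads at 0.5 and 5, Type I at 50 and 500
  expect_true(all((rc[["Type II"]] > rc[["Type I"]])[rc$s %in% c(0.5, 5)]))
  expect_true(all((rc[["Type I"]] > rc[["Type II"]])[rc$s %in% c(50, 500)]))

  single <- rate_curve(pair[1], grid = 0)
  expect_equal(single[["Type I"]], 0)
  expect_error(rate_curve(pair, grid = numeric(0)), "non-empty")
  expect_error(rate_curve(list(pair[[1]], pair[[1]]), grid = 1), "duplicate")
  expect_error(rate_curve(pair, grid = c(2, 1)), "increasing")
})

test_that("dominance classification follows the higher rate, with ties", {
  pair <- published_pair()
  expect_identical(dominant_label(pair, 50), "Type I")
  expect_identical(dominant_label(pair, 5), "Type II")
  # identical parameter values -> tie regardless of s
  twin <- list(kinetic_params("a", 1, 0.5, 300),
               kinetic_params("b", 1, 0.5, 300))
  for (s in c(0.05, 1, 100)) expect_identical(dominant_label(twin, s), "tie")
  expect_identical(dominant_label(pair, 0), "tie")  # both rates zero
  expect_error(dominant_label(pair, -1), "negative")
  expect_error(dominant_label(pair[1], 5), "two populations")

  # antisymmetry: swapping the parameter sets swaps the winner
  set.seed(303)
  for (i in 1:20) {
    a <- random_params("A"); b <- random_params("B")
    s <- runif(1, 0.01, 500)
    lab <- dominant_label(list(a, b), s)
    swapped <- dominant_label(list(b, a), s)
    if (lab == "tie") expect_identical(swapped, "tie")
    else expect_identical(swapped, lab)
  }
})

test_that("crossover root-finding matches the closed-form quadratic", {
  pair <- published_pair()
  cx <- crossover_concentrations(pair)
  expect_length(cx, 1)
  # quadratic obtained by cross-multiplying the two rate laws:
  # 1600 S^2 - 29194 S - 3000 = 0, positive root:
  expected <- (29194 + sqrt(29194^2 + 4 * 1600 * 3000)) / (2 * 1600)
  expect_equal(cx, expected, tolerance = 1e-8)
  expect_gt(cx, 5); expect_lt(cx, 50)
})

test_that("crossover degenerate and no-root cases are reported cleanly", {
  same <- list(kinetic_params("a", 1, 0.5, 300),
               kinetic_params("b", 1, 0.5, 300))
  out <- crossover_concentrations(same)
  expect_length(out, 0)
  expect_true(attr(out, "degenerate"))

  # differing only in vmax: one curve strictly dominates, no root
  pair <- list(kinetic_params("a", 1.2, 0.5, 300),
               kinetic_params("b", 1.0, 0.5, 300))
  expect_length(crossover_concentrations(pair), 0)
})

test_that("crossover agrees with a brute-force sign-change scan", {
  set.seed(404)
  checked <- 0L
  for (i in 1:100) {
    a <- random_params("A"); b <- random_params("B")
    oracle <- scan_crossovers(a, b, s_max = 100, step = 1e-3)
    found <- crossover_concentrations(list(a, b), s_range = c(1e-4, 100))
    found <- found[found <= 100]
    expect_equal(length(found), length(oracle))
    if (length(oracle)) {
      expect_true(all(abs(found - oracle) < 1e-3))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20)  # the draw produces plenty of actual crossings
})

test_that("parameter fitting recovers truth", {
  truth <- kinetic_params("Type II", 1.0, 0.5, 300)
  s <- c(0.05, 0.2, 1, 5, 20, 80, 200, 500)
  obs <- data.frame(s = s, rate = specific_rate(truth, s))
  fit <- fit_params(obs, init = kinetic_params("Type II", 0.5, 1.5, 100))
  expect_true(fit$converged)
  est <- fit$params
  expect_lt(abs(est$vmax - 1.0) / 1.0, 1e-6)
  expect_lt(abs(est$km - 0.5) / 0.5, 1e-6)
  expect_lt(abs(est$ki - 300) / 300, 1e-6)

  # 1% multiplicative noise, n = 50, fixed seed
  noisy <- gen_rate_observations(synth_spec(seed = 42, noise_sd = 0.01),
                                 n = 50)
  o1 <- noisy[noisy$label == "Type I", ]
  f1 <- fit_params(o1, init = kinetic_params("Type I", 0.5, 1, 500))
  expect_true(f1$converged)
  expect_lt(abs(f1$params$vmax - 0.95) / 0.95, 0.05)
  expect_lt(abs(f1$params$km - 0.48) / 0.48, 0.05)
  expect_lt(abs(f1$params$ki - 2000) / 2000, 0.25)

  # log-residual loss also recovers noiseless truth
  flog <- fit_params(obs, init = kinetic_params("Type II", 0.5, 1.5, 100),
                     loss = "log")
  expect_lt(abs(flog$params$km - 0.5) / 0.5, 1e-6)

  expect_error(fit_params(obs[1:3, ], init = truth), "at least 4")
  degenerate <- data.frame(s = rep(5, 6), rate = rep(0.9, 6))
  expect_error(fit_params(degenerate, init = truth), "degenerate")
})

test_that("exhaustive search retains parameter pairs explaining dominance", {
  obs <- data.frame(s = c(0.5, 5, 50, 500),
                    dominant = c("Type II", "Type II", "Type I", "Type I"))
  grid <- list(vmax = c(0.95, 1.0), km = c(0.48, 0.5), ki = c(300, 2000))
  hits <- search_explaining_params(obs, grid)
  expect_gt(length(hits), 0)
  is_published <- vapply(hits, function(pair) {
    a <- pair[[1]]; b <- pair[[2]]
    a$vmax == 0.95 && a$km == 0.48 && a$ki == 2000 &&
      b$vmax == 1.0 && b$km == 0.5 && b$ki == 300
  }, logical(1))
  expect_true(any(is_published))
  # every retained pair actually reproduces all observations
  for (pair in hits) {
    for (k in seq_len(nrow(obs))) {
      expect_identical(dominant_label(pair, obs$s[k]), obs$dominant[k])
    }
  }

  contradictory <- data.frame(s = c(5, 5),
                              dominant = c("Type I", "Type II"))
  expect_length(search_explaining_params(contradictory, grid), 0)

  one <- data.frame(s = 50, dominant = "Type I")
  tiny <- list(vmax = 1, km = 0.5, ki = c(300, 2000))
  hits1 <- search_explaining_params(one, tiny)
  expect_gt(length(hits1), 0)
})
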