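test_that("noise-free dynamics converge to the root-finder's fixed point", {
  m <- grn_model(noise_sigma = 0)
  sched <- data.frame(time_label = c("a", "b"), mu = c(1.0, 0.9))
  ens <- simulate_ensemble(m, n_cells = 10, mu_schedule = sched, seed = 1,
                           stage_time = 50, burn_in = 5)
  st <- ens$states[["b"]]
  fps <- find_fixed_points(m, mu = 0.9)
  prog <- fps[fps$stable & abs(fps$x - fps$y) < 0.1, ]
  expect_lt(max(abs(st[, 1] - prog$x[1])), 1e-6)
  expect_lt(max(abs(st[, 2] - prog$y[1])), 1e-6)
  # terminal drift vanishes
  drift <- sctipping:::.master_drift(st[, 1:2], m, 0.9)
  expect_lt(max(abs(drift)), 1e-6)
})

test_that("ensembles are seed-deterministic and n_cells-invariant", {
  m <- grn_model()
  sched <- data.frame(time_label = "a", mu = 1.0)
  e1 <- simulate_ensemble(m, 12, sched, seed = 3, stage_time = 2,
                          burn_in = 2)
  e2 <- simulate_ensemble(m, 12, sched, seed = 3, stage_time = 2,
                          burn_in = 2)
  expect_identical(e1$snapshots[["a"]]$values, e2$snapshots[["a"]]$values)

  e3 <- simulate_ensemble(m, 20, sched, seed = 3, stage_time = 2,
                          burn_in = 2)
  expect_identical(e3$states[["a"]][1:12, ], e1$states[["a"]])

  e4 <- simulate_ensemble(m, 12, sched, seed = 4, stage_time = 2,
                          burn_in = 2)
  expect_false(identical(e4$states[["a"]], e1$states[["a"]]))
})

test_that("without noise or bias the symmetric invariant line is preserved", {
  m <- grn_model(noise_sigma = 0, bias = 0)
  st0 <- matrix(c(1, 1, rep(0.5, 10)), 1, 12)
  st <- sctipping:::.integrate_stage(st0, m, mu = 0.7, time = 10,
                                     dt = 0.01, seed = 1, stage = 1)
  expect_identical(st[1, 1], st[1, 2])
})

test_that("integration blow-up is reported, naming the step size", {
  m <- grn_model(noise_sigma = 0)
  st0 <- matrix(1, 2, 12)
  expect_error(sctipping:::.integrate_stage(st0, m, mu = 1, time = 1e4,
                                            dt = 50, seed = 1, stage = 1),
               "dt")
})

test_that("attractor classification labels basins and the instructive bias", {
  m <- grn_model(bias = 0.04)
  fps <- find_fixed_points(m, mu = 0.7)
  st <- fps[fps$stable, ]
  xbr <- st[which.max(st$x - st$y), ]
  ybr <- st[which.min(st$x - st$y), ]
  expect_equal(classify_attractor(c(xbr$x, xbr$y), m, mu = 0.7), "intended")
  expect_equal(classify_attractor(c(ybr$x, ybr$y), m, mu = 0.7),
               "rebellious")
  mid <- c((xbr$x + ybr$x) / 2, (xbr$y + ybr$y) / 2)
  expect_equal(classify_attractor(mid, m, mu = 0.7), "undecided")

  # pre-bifurcation the near-diagonal attractor is the progenitor
  fps1 <- find_fixed_points(m, mu = 1.0)
  prog <- fps1[fps1$stable & abs(fps1$x - fps1$y) < 0.2, ]
  expect_equal(classify_attractor(c(prog$x[1], prog$y[1]), m, mu = 1.0),
               "progenitor")
  # negative bias flips which branch is intended
  m2 <- grn_model(bias = -0.04)
  expect_equal(classify_attractor(c(ybr$x, ybr$y), m2, mu = 0.7),
               "intended")
})

test_that("fluctuation amplitude grows as mu approaches the bifurcation", {
  m <- grn_model(noise_sigma = 0.08)
  vars <- sapply(c(1.0, 0.9, 0.84), function(mu) {
    sched <- data.frame(time_label = "a", mu = mu)
    e <- simulate_ensemble(m, 150, sched, seed = 5, stage_time = 12,
                           burn_in = 12, dt = 0.02)
    st <- e$states[["a"]]
    lab <- e$labels[["a"]]
    keep <- lab == "progenitor"
    sum(apply(st[keep, 1:2], 2, var))
  })
  expect_true(all(diff(vars) > 0))
})

test_that("with zero bias the two branches are occupied symmetrically", {
  m <- grn_model(bias = 0, noise_sigma = 0.08)
  sched <- data.frame(time_label = c("a", "b"), mu = c(1.0, 0.7))
  e <- simulate_ensemble(m, 2000, sched, seed = 7, stage_time = 10,
                         burn_in = 10, dt = 0.02)
  lab <- e$labels[["b"]]
  n_int <- sum(lab == "intended")      # x-branch by convention at bias 0
  n_reb <- sum(lab == "rebellious")
  p <- binom.test(n_int, n_int + n_reb, p = 0.5)$p.value
  expect_gt(p, 0.01)
})

test_that("relaxation time matches linearization and handles edge cases", {
  m <- grn_model(noise_sigma = 0)
  t1 <- relaxation_time(m, mu = 0.95, threshold = 1)
  expect_equal(as.numeric(t1), 0)

  tm <- relaxation_time(m, mu = 0.95, noise_sigma = 0, dt = 0.002)
  pred <- predicted_relaxation_time(m, mu = 0.95)
  expect_lt(abs(as.numeric(tm) - pred) / pred, 0.2)
  expect_false(attr(tm, "censored"))

  # past the bifurcation there is no progenitor to relax to
  expect_error(relaxation_time(m, mu = 0.7), "progenitor")
  # a give-up horizon reports right-censoring, not an error
  tc <- relaxation_time(m, mu = 0.95, noise_sigma = 0, max_time = 0.2,
                        threshold = 1e-6)
  expect_true(is.infinite(as.numeric(tc)) && attr(tc, "censored"))
})

test_that("snapshots parse as valid expression matrices with labels", {
  ens <- cached_scenario(1)
  for (sn in ens$snapshots) {
    expect_s3_class(sn, "ExpressionMatrix")
    expect_true(all(sn$cell_meta$fraction %in%
                    c("progenitor", "intended", "rebellious", "undecided")))
    expect_true(all(is.finite(sn$values)) && all(sn$values >= 0))
  }
  X <- as_expression_matrix(ens)
  expect_equal(nrow(X$values), 4 * 500)
  expect_equal(ncol(X$values), 12)
})

test_that("schedule validation enforces monotone mu and ensemble size", {
  m <- grn_model()
  bad <- data.frame(time_label = c("a", "b", "c"), mu = c(1, 0.8, 0.9))
  expect_error(simulate_ensemble(m, 20, bad, seed = 1), "monotone")
  ok <- data.frame(time_label = "a", mu = 1)
  expect_error(simulate_ensemble(m, 5, ok, seed = 1), "n_cells")
})
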