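test_that("LHS stratifies each marginal into equal-probability bins", {
  r <- data.frame(parameter = "x", lower = 0, upper = 1)
  s <- lhs_sample(r, 4, seed = 11)$x
  expect_equal(sort(floor(s * 4)), 0:3)
  # reproducible under seed
  expect_identical(lhs_sample(default_ranges(), 50, seed = 3),
                   lhs_sample(default_ranges(), 50, seed = 3))
  # degenerate range gives a constant column
  r2 <- data.frame(parameter = c("a", "b"), lower = c(0.5, 0), upper = c(0.5, 1))
  s2 <- lhs_sample(r2, 10, seed = 1)
  expect_true(all(s2$a == 0.5))
})

test_that("LHS marginals have the uniform mean", {
  r <- data.frame(parameter = "k", lower = 0.1, upper = 1.0)
  s <- lhs_sample(r, 1e4, seed = 5)$k
  se <- sqrt((1 - 0.1)^2 / 12 / 1e4)
  expect_lt(abs(mean(s) - 0.55), 3 * se)
})

test_that("fixed-point enumeration recovers the logistic equilibria", {
  p1 <- glv_params(0.5, matrix(-0.022), species = "P")
  fps <- find_fixed_points(p1)
  ab <- sort(vapply(fps, function(f) f$abundance[[1]], 0))
  expect_equal(ab, c(0, 0.5 / 0.022), tolerance = 1e-12)
  stable <- vapply(fps, `[[`, TRUE, "stable")
  expect_equal(stable[order(vapply(fps, function(f) f$abundance[[1]], 0))],
               c(FALSE, TRUE))
})

test_that("mutual inhibition yields bistable boundary points, unstable interior", {
  k <- c(0.5, 0.5)
  A <- matrix(c(-0.02, -0.03, -0.03, -0.02), 2, 2)
  p <- glv_params(k, A, species = c("s1", "s2"))
  fps <- find_fixed_points(p)
  lab <- vapply(fps, function(f) paste(f$support, collapse = "+"), "")
  stable <- vapply(fps, `[[`, TRUE, "stable")
  expect_true(stable[lab == "s1"] && stable[lab == "s2"])
  expect_false(stable[lab == "s1+s2"])
  # confirm numerically: perturbed starts converge to a boundary point
  rp <- resident_params(bistable_draw)
  finals <- basin_attractors(rp, n_starts = 8, seed = 2)
  for (i in seq_len(nrow(finals)))
    expect_lt(min(finals[i, 1], finals[i, 2]) / max(finals[i, ]), 1e-4)
})

test_that("equilibrium-behavior labels summarise the stable set", {
  expect_equal(classify_equilibrium_behavior(resident_params(monostable_draw))$label,
               "1SS nAB")
  expect_equal(classify_equilibrium_behavior(resident_params(bistable_draw))$label,
               "2SS nAB/Li")
})

test_that("basin-sampled attractors agree with the analytic stable set", {
  # every attractor reached by simulation is (close to) an analytic stable
  # point, for a batch of random parameter draws
  draws <- lhs_sample(default_ranges(), 25, seed = 9)
  for (i in seq_len(nrow(draws))) {
    rp <- resident_params(draws[i, ])
    stable <- stable_fixed_points(rp)
    if (length(stable) == 0) next
    rel_pts <- lapply(stable, function(f) {
      x <- f$abundance
      if (sum(x) > 0) x / sum(x) else x
    })
    finals <- basin_attractors(rp, n_starts = 5, seed = i)
    for (j in seq_len(nrow(finals))) {
      x <- finals[j, ]
      if (sum(x) < 1e-8) next
      rel <- x / sum(x)
      dmin <- min(vapply(rel_pts, function(p) sqrt(sum((rel - p)^2)), 0))
      expect_lt(dmin, 0.05)
    }
  }
})

test_that("virtual patients are BV+ with a consistent initial state", {
  pat <- virtual_patient(monostable_draw, id = 1)
  expect_s3_class(pat, "virtual_patient")
  expect_equal(classify_cst(pat$initial_state), "nAB")
  expect_equal(pat$initial_state[["P"]], 0)
  # species absent from the equilibrium start at the detection floor
  fp <- Filter(function(p) identical(p$cst, "nAB"), pat$stable_points)[[1]]
  expect_equal(unname(pat$initial_state[1:3]),
               unname(pmax(fp$abundance, 0.01)))
  # untreated, the community relaxes back onto the analytic equilibrium
  params <- community_params(pat$params, make_strain("null"))
  tr <- simulate_glv(params, pat$initial_state, times = 200)
  expect_equal(as.numeric(tr[1, 2:4]), unname(fp$abundance),
               tolerance = 1e-4)
  # a community that can never be nAB-dominant is rejected
  no_bv <- monostable_draw
  no_bv["kgrow_nAB"] <- 0.1
  no_bv["alpha_nAB_to_nAB"] <- -0.04
  no_bv["alpha_Li_to_nAB"] <- -0.1
  no_bv["alpha_nAB_to_Li"] <- 0
  no_bv["alpha_nAB_to_oLB"] <- 0
  expect_null(virtual_patient(no_bv))
})

test_that("resampling hits the target strata counts exactly", {
  pool <- get_tiny_pop()$patients
  tf <- hmp_target_frequencies()
  pop <- resample_population(pool, tf, n = 50, seed = 1)
  labs <- table(vapply(pop$patients, `[[`, "", "behavior"))
  expect_equal(as.numeric(labs[names(tf)]), c(30, 16, 4))
  expect_equal(sum(labs), 50)
  # largest-remainder rounding: n = 7 with 60/31/9
  pop7 <- resample_population(pool, tf, n = 7, seed = 1)
  labs7 <- table(factor(vapply(pop7$patients, `[[`, "", "behavior"),
                        levels = names(tf)))
  expect_equal(as.numeric(labs7), c(4, 2, 1))
  # single-label target
  pop1 <- resample_population(pool, c("1SS nAB" = 1), n = 10, seed = 2)
  expect_true(all(vapply(pop1$patients, `[[`, "", "behavior") == "1SS nAB"))
  # missing stratum errors by name
  expect_error(resample_population(pool, c("1SS oLB" = 1), n = 5, seed = 1),
               "1SS oLB")
})

test_that("every stable point of generated patients has negative spectral abscissa", {
  pop <- get_tiny_pop()
  for (pat in pop$patients[1:20]) {
    for (fp in pat$stable_points) {
      A <- pat$params$alpha
      k <- pat$params$k_grow
      x <- fp$abundance
      J <- diag(as.numeric(k + A %*% x), 3) + diag(x, 3) %*% A
      expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
    }
  }
})
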