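# Monte-Carlo transport: free paths, scattering events, slab propagation,
# energy ledger and depolarization.

test_that("free paths are exponential with the requested rate", {
  set.seed(2)
  s <- sample_free_path(1, 2e5)
  expect_lt(abs(mean(s) - 1), 3 / sqrt(2e5))
  expect_lt(abs(mean(s <= 1) - (1 - exp(-1))), 3 * sqrt(0.25 / 2e5))
  expect_identical(sample_free_path(0, 5), rep(Inf, 5))
  expect_error(sample_free_path(-1), "mu must")
})

test_that("vacuum slab transmits every ray ballistically with unit weight", {
  rays <- local({
    set.seed(1)
    launch_collimated(500, c(1, 0), 0.5)
  })
  res <- propagate_through_medium(rays, medium_optics(0, 0), slab_geometry(10),
                                  seed = 1)
  expect_equal(nrow(res$exits), 500)
  expect_true(all(res$exits$status == "transmitted"))
  expect_equal(res$exits$weight, rep(1, 500))
  expect_equal(res$exits$events, rep(0L, 500))
  expect_equal(res$exits$uz, rep(1, 500))
  expect_equal(res$exits$path_length, rep(10, 500))
  expect_equal(ledger_closure(res), 0)
})

test_that("unscattered transmission follows the extinction law", {
  tb <- tables_for_alpha(1)
  mu_s <- 0.08; mu_a <- 0.02
  med <- medium_optics(mu_a, mu_s, spec_for_alpha(1), tables = tb)
  n <- 2e4
  for (od in c(0.5, 1, 2)) {
    D <- od / (mu_a + mu_s)
    rays <- local({
      set.seed(7)
      launch_collimated(n, c(1, 0), 0.488)
    })
    res <- propagate_through_medium(rays, med, slab_geometry(D), seed = 7)
    ex <- res$exits
    ballistic <- ex$status == "transmitted" & ex$events == 0L
    p <- exp(-mu_s * D)
    expect_lt(abs(sum(ballistic) / n - p), 3 * sqrt(p * (1 - p) / n))
    # ballistic weight includes the continuous absorption decay
    expect_equal(ex$weight[ballistic],
                 rep(exp(-mu_a * D), sum(ballistic)), tolerance = 1e-12)
    expect_lt(abs(ledger_closure(res)), 1e-9)
  }
})

test_that("energy ledger closes exactly, including absorbers and roulette", {
  tb <- tables_for_alpha(1)
  rod <- cylinder_absorber(c(0, 0, 10), c(0, 1, 0), 4, 0.3)
  med <- medium_optics(0.05, 0.1, spec_for_alpha(1), tables = tb)
  rays <- local({
    set.seed(3)
    launch_collimated(3000, c(1, 1i) / sqrt(2), 0.488)
  })
  res <- propagate_through_medium(rays, med, slab_geometry(20, list(rod)),
                                  seed = 3, weight_floor = 0.3,
                                  roulette_survival = 0.5)
  expect_lt(abs(ledger_closure(res)) / res$ledger["launched"], 1e-12)
  expect_gt(res$ledger["absorbed"], 0)
})

test_that("scattering preserves intensity and frame orthonormality", {
  med <- medium_optics(0, 0.1, spec_for_alpha(4), tables = tables_for_alpha(4))
  rays <- local({
    set.seed(5)
    launch_collimated(100, c(1, 0), 0.488)
  })
  set.seed(5)
  for (i in 1:1000) rays <- scatter_bundle(rays, med)
  expect_lt(max(abs(ray_weight(rays) - 1)), 1e-10)
  expect_lt(polmc:::frame_error(rays), 1e-10)
  expect_true(all(rays$events == 1000L))
})

test_that("event cap terminates long chains into the capped ledger", {
  med <- medium_optics(0, 1, spec_for_alpha(1), tables = tables_for_alpha(1))
  rays <- local({
    set.seed(11)
    launch_collimated(200, c(1, 0), 0.488)
  })
  res <- propagate_through_medium(rays, med, slab_geometry(1000), seed = 11,
                                  max_events = 50L)
  expect_gt(res$ledger["capped"], 0)
  expect_lt(abs(ledger_closure(res)), 1e-9)
  expect_true(all(res$exits$events <= 50L))
})

test_that("ensemble polarization decays monotonically with scattering order", {
  med <- medium_optics(0, 0.1, spec_for_alpha(1), tables = tables_for_alpha(1))
  dp <- depolarization_by_order(med, n_rays = 4000, n_orders = 8, seed = 3)
  expect_equal(dp$ensemble_L[1], 1, tolerance = 1e-12)
  expect_true(all(diff(dp$ensemble_L) <= 0))
  expect_lt(dp$ensemble_L[9], 0.2)
})

test_that("transport inside a closed mesh reports exits through its surface", {
  mesh <- polmc:::make_icosphere(20, 2)
  med <- medium_optics(0.01, 0, NULL)
  rays <- local({
    set.seed(2)
    launch_collimated(100, c(1, 0), 0.5, origin = c(0, 0, -19))
  })
  res <- propagate_through_medium(rays, med, mesh_geometry(mesh), seed = 2)
  expect_true(all(res$exits$status == "exited"))
  # exit point close to the sphere surface, weight decayed along the chord
  r_exit <- sqrt(res$exits$x^2 + res$exits$y^2 + res$exits$z^2)
  expect_lt(max(abs(r_exit - 20)), 0.5)
  expect_equal(res$exits$weight, exp(-0.01 * res$exits$path_length),
               tolerance = 1e-12)
})
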