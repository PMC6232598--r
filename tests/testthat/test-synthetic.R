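test_that("bag streams follow their regime schedule", {
  # degenerate regime emits only its certain symbol
  s <- generate_bag_stream(30, c(1, 0), seed = 1)
  expect_true(all(s$symbols == 0L))
  # long regime: empirical frequency concentrates on the truth
  s <- generate_bag_stream(1e4, c(0.9, 0.1), seed = 2)
  expect_equal(mean(s$symbols == 0L), 0.9, tolerance = 0.01)
  # truth labels switch exactly at the regime boundary
  s <- generate_bag_stream(c(40, 60), rbind(c(0.9, 0.1), c(0.2, 0.8)),
                           seed = 3)
  expect_equal(nrow(s$truth), 100L)
  expect_true(all(s$truth[1:40, 1] == 0.9))
  expect_true(all(s$truth[41:100, 1] == 0.2))
  # identical seeds give identical streams
  expect_identical(generate_bag_stream(c(50, 50), rbind(c(0.5, 0.5),
                                                        c(0.1, 0.9)),
                                       seed = 7)$symbols,
                   generate_bag_stream(c(50, 50), rbind(c(0.5, 0.5),
                                                        c(0.1, 0.9)),
                                       seed = 7)$symbols)
  expect_error(generate_bag_stream(c(10, 10), c(0.5, 0.5)), "one distribution")
  expect_error(generate_bag_stream(10, c(0.5, 0.6)), "probability")
})

test_that("phase trajectories show the programmed polarization contrast", {
  fx <- make_phase_fixture(seed = 5)
  expect_equal(length(fx$phase), nrow(fx$traj$x)) # one label per frame
  pol <- polarization(fx$traj)
  ph <- fx$phase[-length(fx$phase)]
  expect_gt(mean(pol$psi[ph == "coherent"]), 0.9)
  expect_lt(mean(pol$psi[ph == "dispersed"]), 0.3)
})

test_that("coherent phases are denser than dispersed phases", {
  fx <- make_phase_fixture(seed = 6)
  ds <- density_series(fx$traj, r = 10)
  expect_gt(mean(ds[fx$phase == "coherent", ]),
            mean(ds[fx$phase == "dispersed", ]))
})

test_that("the polarization series crosses 0.8 in both directions each cycle", {
  # end on a coherent phase so each dispersal is followed by re-formation
  fx <- make_phase_fixture(seed = 8, n_phases = 5)
  psi <- polarization(fx$traj)$psi
  down <- sum(psi[-1] < 0.8 & psi[-length(psi)] >= 0.8)
  up <- sum(psi[-1] >= 0.8 & psi[-length(psi)] < 0.8)
  expect_gte(down, 2L) # two coherent-to-dispersed switches programmed
  expect_gte(up, 2L)
})

test_that("phase trajectories are reproducible from their seed", {
  a <- make_phase_fixture(seed = 9, n_phases = 2, duration = 100, N = 8)
  b <- make_phase_fixture(seed = 9, n_phases = 2, duration = 100, N = 8)
  expect_identical(a$traj$x, b$traj$x)
  # zero angular noise in the coherent phase gives perfect alignment
  sched <- phase_schedule(50, "coherent")
  fx <- generate_phase_trajectories(sched, N = 10, coherent_sd = 0,
                                    cohesion = 0, seed = 10)
  expect_equal(polarization(fx$traj)$psi, rep(1, 49), tolerance = 1e-12)
})
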