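test_that("an empty scene renders pure noise with zero ground truth", {
  sc <- simulate_scene(scene_params(n_cells = 0L,
                                    volume_shape = c(4L, 32L, 32L),
                                    seed = 1))
  expect_equal(nrow(sc$cells), 0L)
  for (ro in CHANNEL_ROLES) expect_equal(ground_truth_count(sc, ro), 0L)
  st <- render_channel(sc, "nuclear")
  expect_equal(length(st$planes), 4L)
  expect_true(all(sapply(st$planes, max) < 200))  # background + noise only
})

test_that("a dead_ethd fraction of 1 marks every cell EtHd-positive", {
  sc <- simulate_scene(scene_params(n_cells = 50L,
                                    fractions = list(dead_ethd = 1),
                                    seed = 2))
  expect_true(all(sc$cells$fate == "ethd"))
})

test_that("fate draws replay the documented RNG sequence", {
  fr <- list(dead_ethd = 0.1, dead_apopxin = 0.1, dead_both = 0.05,
             s_phase = 0.3, gfp_lineage = 0)
  p <- scene_params(n_cells = 200L, volume_shape = c(24L, 384L, 384L),
                    fractions = fr, seed = 77)
  sc <- simulate_scene(p)
  # independent replay: positions (x, y, z), levels, then one multinomial
  # fate draw per cell, then S-phase and GFP uniforms
  set.seed(77)
  runif(200); runif(200); runif(200)    # x, y, z
  rlnorm(200)                           # levels
  fate <- sample(c("alive", "ethd", "apopxin", "both"), 200, replace = TRUE,
                 prob = c(0.75, 0.1, 0.1, 0.05))
  s_phase <- runif(200) < 0.3 & fate == "alive"
  expect_identical(sc$cells$fate, fate)
  expect_identical(sc$cells$s_phase, s_phase)
  expect_identical(as.vector(table(sc$cells$fate)),
                   as.vector(table(fate)))
})

test_that("fate counts conserve the cell total", {
  sc <- simulate_scene(scene_params(
    n_cells = 120L, volume_shape = c(24L, 384L, 384L),
    fractions = list(dead_ethd = 0.2, dead_apopxin = 0.1, dead_both = 0.1,
                     s_phase = 0.4), seed = 5))
  expect_equal(sum(table(sc$cells$fate)), 120L)
  expect_false(any(sc$cells$s_phase & sc$cells$fate != "alive"))
})

test_that("rendering is bit-identical under a fixed seed", {
  p <- scene_params(n_cells = 10L, volume_shape = c(6L, 64L, 64L),
                    nucleus_radius_px = 3,
                    fractions = list(dead_ethd = 0.3), seed = 11)
  a <- render_channel(simulate_scene(p), "nuclear")
  b <- render_channel(simulate_scene(p), "nuclear")
  expect_identical(a$planes, b$planes)
  e1 <- render_channel(simulate_scene(p), "dead_membrane")
  e2 <- render_channel(simulate_scene(p), "dead_membrane")
  expect_identical(e1$planes, e2$planes)
})

test_that("a written plate is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tiny_plate(d1, seed = 3L)
  write_tiny_plate(d2, seed = 3L)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  same <- vapply(f1, function(f)
    identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
              readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))),
    FALSE)
  expect_true(all(same))
})

test_that("one isolated cell matches the analytic cross-section areas", {
  p <- scene_params(n_cells = 1L, volume_shape = c(9L, 64L, 64L),
                    vignetting_strength = 0, z_confine = c(4, 4),
                    intensity = list(noise_sd = 0, cv = 0), seed = 8)
  sc <- simulate_scene(p)
  sc$cells$x <- 32.0; sc$cells$y <- 32.0; sc$cells$z <- 4.0
  sc$cells$level <- 8000
  truth <- ground_truth_mask(sc, "nuclear")
  r <- p$nucleus_radius_px
  for (k in seq_len(9)) {
    dz <- abs((k - 1) - 4) * p$z_step_px
    n_obs <- sum(truth[[k]])
    if (dz >= r) { expect_equal(n_obs, 0L); next }
    rad <- sqrt(r^2 - dz^2)
    # chord-dimmed cross-sections below half the nominal brightness leave
    # the ground truth (0.5 truth level)
    if ((rad / r)^p$chord_power * (1 + 0) < 0.5 && rad < 0.5) {
      expect_equal(n_obs, 0L)
    } else {
      # analytic disc area with a lattice-perimeter error bound
      expect_lt(abs(n_obs - pi * rad^2), 2 * (2 * pi * rad + 2))
    }
  }
})

test_that("the defocus halo is pinned to halo_scale at one radius", {
  p <- scene_params(n_cells = 1L, volume_shape = c(9L, 64L, 64L),
                    vignetting_strength = 0, z_confine = c(4, 4),
                    intensity = list(noise_sd = 0, cv = 0, core_boost = 0),
                    seed = 8)
  sc <- simulate_scene(p)
  sc$cells$x <- 32.0; sc$cells$y <- 32.0; sc$cells$z <- 4.0
  sc$cells$level <- 8000
  pure <- cellfate3d:::render_pure(sc, "nuclear")
  # slices at exactly dz = r (2 z-steps of r/2): peak = halo_scale * level
  expect_equal(max(pure[[3L]]), 0.3 * 8000, tolerance = 1e-9)
  expect_equal(max(pure[[7L]]), 0.3 * 8000, tolerance = 1e-9)
  expect_equal(max(pure[[5L]]), 8000 * (1 + p$intensity$core_boost),
               tolerance = 1e-6)
})

test_that("scenes with no dead cells leave the death channels signal-free", {
  sc <- default_scene(21, fractions = list(s_phase = 0.3))
  for (ro in c("dead_membrane", "dead_apoptotic")) {
    st <- render_channel(sc, ro)
    corrected <- lapply(st$planes, correct_illumination,
                        params = correction_params(50))
    expect_false(estimate_stack_threshold(corrected)$has_signal)
  }
})

test_that("the dose-response logistic plants the stated fractions", {
  base <- tiny_plate_params(1)
  pl <- simulate_plate(doses = c(0, 100, 1e6), base = base,
                       n_positions = 1L,
                       response = list(kill_max = 0.9, viability_ec50 = 100,
                                       viability_hill = 1.2, s_max = 0.4,
                                       s_min = 0.05, prolif_ec50 = 100,
                                       prolif_hill = 1.2),
                       roles = "nuclear", seed = 1)
  tr <- pl$truth
  expect_equal(tr$kill_fraction[tr$dose == 0], 0)          # baseline
  expect_equal(tr$s_phase_fraction[tr$dose == 0], 0.4)
  expect_equal(tr$kill_fraction[tr$dose == 100], 0.45)     # EC50: half effect
  expect_equal(tr$s_phase_fraction[tr$dose == 100], 0.225)
  expect_gt(tr$kill_fraction[tr$dose == 1e6], 0.89)        # near ceiling
  expect_error(simulate_plate(doses = c(1, 2), base = base),
               "doses == 0")
})

test_that("infeasible densities and inconsistent fractions are rejected", {
  expect_error(scene_params(n_cells = 5000L,
                            volume_shape = c(4L, 64L, 64L)),
               "density")
  expect_error(scene_params(fractions = list(dead_ethd = 0.8,
                                             dead_apopxin = 0.3)),
               "more than 1")
  expect_error(scene_params(fractions = list(s_phase = 1.2)), "s_phase")
})

test_that("GFP-tagged cells are protected from drug fates by default", {
  sc <- simulate_scene(scene_params(
    n_cells = 100L, volume_shape = c(24L, 384L, 384L),
    fractions = list(dead_ethd = 0.9, gfp_lineage = 0.5), seed = 31))
  expect_true(all(sc$cells$fate[sc$cells$gfp] == "alive"))
  expect_true(any(sc$cells$fate[!sc$cells$gfp] == "ethd"))
})
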