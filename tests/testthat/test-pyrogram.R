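test_that("noise-free pyrogram area recovers the requested S2 mass", {
  cases <- list(
    list(centers = 310, sigmas = 15, fr = 1, s2 = 100),
    list(centers = c(310, 370, 430, 500), sigmas = rep(15, 4),
         fr = rep(0.25, 4), s2 = 220),
    list(centers = c(330, 450), sigmas = c(10, 20), fr = c(0.3, 0.7), s2 = 37.5)
  )
  for (cs in cases) {
    p <- generate_pyrogram(thermal_composition(cs$centers, cs$sigmas, cs$fr),
                           total_s2 = cs$s2, noise_sd = 0)
    ramp <- p$pyrolysis[p$pyrolysis$phase == "ramp", ]
    area <- pracma::trapz(ramp$time_s, ramp$fid_signal)
    expect_equal(area, cs$s2, tolerance = 0.005)
  }
})

test_that("component mass lands in the correct node window (CDF oracle)", {
  # single labile component: nearly all mass in A1
  p1 <- generate_pyrogram(thermal_composition(310, 15, 1), total_s2 = 50,
                          noise_sd = 0)
  n1 <- integrate_s2_nodes(p1)
  o1 <- oracle_node_pct(310, 15, 1)
  expect_equal(unlist(n1), c(A1 = o1[1], A2 = o1[2], A3 = o1[3], A4 = o1[4]),
               tolerance = 1e-3)
  expect_gt(n1$A1, 97.5)

  # four equal components centred in each window: ~25% each
  p4 <- generate_pyrogram(
    thermal_composition(c(310, 370, 430, 500), rep(15, 4), rep(0.25, 4)),
    total_s2 = 80, noise_sd = 0)
  n4 <- integrate_s2_nodes(p4)
  o4 <- oracle_node_pct(c(310, 370, 430, 500), rep(15, 4), rep(0.25, 4))
  expect_equal(unlist(n4), c(A1 = o4[1], A2 = o4[2], A3 = o4[3], A4 = o4[4]),
               tolerance = 1e-3)
  expect_true(all(abs(unlist(n4) - 25) < 3))
})

test_that("zero total S2 gives a flat zero curve", {
  p <- generate_pyrogram(thermal_composition(310, 15, 1), total_s2 = 0,
                         noise_sd = 0)
  expect_true(all(p$pyrolysis$fid_signal == 0))
})

test_that("invalid compositions are rejected", {
  expect_error(generate_pyrogram(thermal_composition(numeric(0), numeric(0),
                                                     numeric(0)), 10),
               "at least one")
  expect_error(thermal_composition(700, 15, 1), "200, 650")
  expect_error(thermal_composition(150, 15, 1), "200, 650")
  expect_error(thermal_composition(c(310, 370), c(15, 15), c(0.5, 0.4)),
               "sum to 1")
  expect_error(thermal_composition(310, -1, 1), "width")
  expect_error(generate_pyrogram(thermal_composition(310, 15, 1), 10,
                                 noise_sd = -1))
})

test_that("pyrogram generation is deterministic under a fixed seed", {
  comp <- thermal_composition(c(310, 430), c(15, 15), c(0.6, 0.4))
  p1 <- generate_pyrogram(comp, 100, noise_sd = 0.01, seed = 7)
  p2 <- generate_pyrogram(comp, 100, noise_sd = 0.01, seed = 7)
  expect_identical(p1$pyrolysis, p2$pyrolysis)
})

test_that("pyrogram CSV round-trips", {
  comp <- thermal_composition(c(310, 430), c(15, 15), c(0.6, 0.4))
  p <- generate_pyrogram(comp, 100, noise_sd = 0.01, seed = 3,
                         sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_pyrogram(p, path)
  q <- read_pyrogram(path, sample_id = "s1")
  expect_equal(q$pyrolysis$fid_signal, p$pyrolysis$fid_signal,
               tolerance = 1e-12)
  expect_equal(q$oxidation, p$oxidation, tolerance = 1e-12)
  expect_equal(compute_parameters(q)$S2, compute_parameters(p)$S2,
               tolerance = 1e-9)
})

test_that("the thermal program grid follows the staged ramp", {
  p <- generate_pyrogram(thermal_composition(310, 15, 1), 10, noise_sd = 0)
  ramp <- p$pyrolysis[p$pyrolysis$phase == "ramp", ]
  expect_equal(range(ramp$temp_c), c(200, 650))
  # 25 degC/min: 1 degC every 2.4 s
  expect_equal(unique(round(diff(ramp$time_s), 9)), 2.4)
  hold <- p$pyrolysis[p$pyrolysis$phase == "hold", ]
  expect_true(all(hold$temp_c == 200))
  expect_equal(max(hold$time_s) + 2.4, 180, tolerance = 1e-9)
})
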