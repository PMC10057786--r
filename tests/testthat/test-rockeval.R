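test_that("node integration of a uniform signal matches window lengths", {
  # constant per-degC signal over 200-650: areas proportional to window
  # lengths 140:60:60:190
  df <- data.frame(temp_c = 200:650, fid_signal = 1)
  n <- integrate_s2_nodes(df)
  expect_equal(n$A1, 140 / 450 * 100, tolerance = 1e-6)
  expect_equal(n$A2, 60 / 450 * 100, tolerance = 1e-6)
  expect_equal(n$A3, 60 / 450 * 100, tolerance = 1e-6)
  expect_equal(n$A4, 190 / 450 * 100, tolerance = 1e-6)
})

test_that("node percentages always sum to 100", {
  set.seed(42)
  for (k in 1:20) {
    fr <- runif(4); fr <- fr / sum(fr)
    p <- generate_pyrogram(
      thermal_composition(c(310, 370, 430, 500), runif(4, 8, 25), fr),
      total_s2 = runif(1, 10, 300), noise_sd = 0.01, seed = k)
    n <- integrate_s2_nodes(p)
    expect_equal(n$A1 + n$A2 + n$A3 + n$A4, 100, tolerance = 1e-9)
  }
})

test_that("degenerate pyrograms are rejected", {
  expect_error(integrate_s2_nodes(data.frame(temp_c = 200:650,
                                             fid_signal = 0)),
               class = "peatsense_undefined_index")
  expect_error(integrate_s2_nodes(data.frame(temp_c = 200:400,
                                             fid_signal = 1)),
               "460")
})

test_that("R- and I-index follow their defining formulas", {
  n <- tibble::tibble(A1 = c(0, 100, 0, 20, 30, 5),
                      A2 = c(0, 0, 0, 20, 30, 5),
                      A3 = c(40, 0, 0, 40, 6, 80),
                      A4 = c(60, 0, 100, 20, 34, 10))
  expect_equal(r_index(n), c(1, 0, 1, 0.6, 0.4, 0.9))
  i <- suppressWarnings(i_index(n))
  expect_equal(i[4], 0)                      # (20+20)/40
  expect_equal(i[5], 1)                      # (30+30)/6 = 10
  expect_equal(i[6], log10(0.125), tolerance = 1e-12)  # ~ -0.903
})

test_that("undefined I-index is flagged, not dropped", {
  n <- tibble::tibble(A1 = c(50, 0), A2 = c(50, 0), A3 = c(0, 60),
                      A4 = c(0, 40))
  expect_warning(i <- i_index(n), "undefined")
  expect_true(is.na(i[1]))
  expect_true(is.na(i[2]))
  bad_sum <- tibble::tibble(A1 = 10, A2 = 10, A3 = 10, A4 = 10)
  expect_error(r_index(bad_sum), "sum to 100")
})

test_that("moving mass from labile to refractory windows raises R and lowers I", {
  set.seed(7)
  for (k in 1:15) {
    fr <- runif(4, 0.1, 1); fr <- fr / sum(fr)
    n0 <- tibble::tibble(A1 = 100 * fr[1], A2 = 100 * fr[2],
                         A3 = 100 * fr[3], A4 = 100 * fr[4])
    shift <- runif(1, 1, min(n0$A1, 20))
    n1 <- tibble::tibble(A1 = n0$A1 - shift, A2 = n0$A2,
                         A3 = n0$A3 + shift, A4 = n0$A4)
    expect_gt(r_index(n1), r_index(n0))
    expect_lt(i_index(n1), i_index(n0))
  }
})

test_that("S2 is invariant to temperature-grid refinement", {
  comp <- thermal_composition(c(310, 430), c(15, 15), c(0.6, 0.4))
  p1 <- generate_pyrogram(comp, 100, noise_sd = 0,
                          program = temp_program(ramp_step_c = 1))
  p2 <- generate_pyrogram(comp, 100, noise_sd = 0,
                          program = temp_program(ramp_step_c = 0.5))
  s2_1 <- compute_parameters(p1)$S2
  s2_2 <- compute_parameters(p2)$S2
  expect_lt(abs(s2_1 - s2_2) / s2_1, 0.001)
})

test_that("compute_parameters assembles the standard parameter set", {
  comp <- thermal_composition(c(310, 370, 430, 500), rep(12, 4),
                              c(0.26, 0.24, 0.32, 0.18))
  p <- generate_pyrogram(comp, total_s2 = 220, noise_sd = 0)
  res <- compute_parameters(p)
  expect_equal(res$S2, 220, tolerance = 0.005)
  expect_equal(res$S1, 0.02 * 220, tolerance = 1e-6)
  # generator defaults put TOC near 55 wt% and HI inside the 300-475 band
  expect_gt(res$TOC, 45); expect_lt(res$TOC, 65)
  expect_gt(res$HI, 300); expect_lt(res$HI, 475)
  expect_equal(res$HI, 100 * res$S2 / res$TOC, tolerance = 1e-9)
  expect_equal(res$OI, 100 * res$S3_CO2 / res$TOC, tolerance = 1e-9)
  expect_true(res$TpkS2 >= 200 && res$TpkS2 <= 650)
})

test_that("TpkS2 is the ramp temperature of maximum yield", {
  p <- generate_pyrogram(thermal_composition(420, 15, 1), 50, noise_sd = 0)
  expect_equal(compute_parameters(p)$TpkS2, 420)
})

test_that("pre-integrated parameter rows skip pyrogram processing", {
  rows <- tibble::tibble(
    sample_id = c("a", "b"),
    S1 = c(1, 2), S2 = c(40, 100), S3_CO = c(5, 10), S3_CO2 = c(0, 50),
    TOC = c(10, 50), TpkS2 = c(420, 430),
    A1 = c(40, 30), A2 = c(20, 20), A3 = c(20, 30), A4 = c(20, 20))
  res <- rockeval_from_parameters(rows)
  expect_equal(res$HI, c(400, 200))  # S2=40, TOC=10 -> HI 400
  expect_equal(res$OI, c(0, 100))    # zero CO2 yield -> OI 0
  expect_equal(res$r_index, c(0.4, 0.5))
  expect_equal(res$i_index, log10(c(60 / 20, 50 / 30)))
  expect_error(rockeval_from_parameters(rows[, -3]), "Missing")
})

test_that("depth layers follow the shallowest-applicable-rule convention", {
  expect_equal(classify_depth_layer(0, 10, 40, 300), "upper50")
  expect_equal(classify_depth_layer(250, 260, 40, 300), "deep")
  expect_equal(classify_depth_layer(60, 70, 40, 300), "below_water_table")
  expect_equal(classify_depth_layer(120, 130, 40, 300), "other")
  # upper50 wins over below_water_table at the 40-50 cm overlap
  expect_equal(classify_depth_layer(40, 50, 40, 300), "upper50")
  # shallow core: everything within 50 cm of the clay is also upper50
  expect_equal(classify_depth_layer(c(0, 40), c(10, 50), 40, 50),
               c("upper50", "upper50"))
  expect_error(classify_depth_layer(10, 5, 40, 300), "top_cm")
  expect_error(classify_depth_layer(280, 310, 40, 300), "clay")
})
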