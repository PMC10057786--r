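test_that("core depth fixes the segment count", {
  core <- generate_core(site_scenario("CentralForest", peat_depth = 0.5))
  expect_equal(nrow(core$segments), 5)
  expect_equal(core$segments$bottom_cm - core$segments$top_cm, rep(10, 5))
  deep <- generate_core(site_scenario("CentralForest", peat_depth = 3.5))
  expect_equal(nrow(deep$segments), 35)
  expect_error(site_scenario("CentralForest", peat_depth = 0), "> 0")
})

test_that("segment dry masses centre bulk density on 0.10 g cm^-3", {
  core <- generate_core(site_scenario("CentralForest", peat_depth = 3.5,
                                      seed = 4))
  bd <- bulk_density(core$segments$dry_g)
  expect_lt(abs(mean(bd) - 0.10), 0.01)
  expect_true(all(core$segments$dry_g <= core$segments$wet_g))
})

test_that("pristine cores decompose with depth: I falls, R rises", {
  core <- generate_core(site_scenario("CentralForest", peat_depth = 3,
                                      seed = 2))
  expect_gt(core_index_mean(core, "i_index", "upper"),
            core_index_mean(core, "i_index", "deep"))
  expect_lt(core_index_mean(core, "r_index", "upper"),
            core_index_mean(core, "r_index", "deep"))
})

test_that("upper-50 cm depletion thermally stabilises the surface peat", {
  # paired seeds: identical base randomness, depletion the only difference
  for (s in c(3, 17, 23)) {
    pristine <- generate_core(site_scenario(
      "CentralForest", peat_depth = 2, upper_labile_depletion = 0, seed = s))
    disturbed <- generate_core(site_scenario(
      "DisturbedForest", peat_depth = 2, upper_labile_depletion = 0.6,
      seed = s))
    expect_lt(core_index_mean(disturbed, "i_index", "upper"),
              core_index_mean(pristine, "i_index", "upper"))
    expect_gt(core_index_mean(disturbed, "r_index", "upper"),
              core_index_mean(pristine, "r_index", "upper"))
  }
})

test_that("depletion removes labile mass rather than reshuffling it", {
  pristine <- generate_core(site_scenario(
    "CentralForest", peat_depth = 1, upper_labile_depletion = 0, seed = 5))
  disturbed <- generate_core(site_scenario(
    "FireAffected", peat_depth = 1, upper_labile_depletion = 0.5, seed = 5))
  up_p <- pristine$segments$s2_mg_g[pristine$segments$bottom_cm <= 50]
  up_d <- disturbed$segments$s2_mg_g[disturbed$segments$bottom_cm <= 50]
  expect_true(all(up_d < up_p))
})

test_that("the default study has the field-design shape", {
  study <- generate_study(seed = 1)
  expect_equal(length(study$cores), 11)
  expect_equal(as.integer(table(study$sites$class)[c(
    "CentralForest", "ManagedRecovery", "DisturbedForest", "FireAffected")]),
    c(3L, 2L, 4L, 2L))
  expect_equal(length(study$stack$years), 5)
  expect_equal(study$stack$years, c(1989L, 1995L, 2001L, 2010L, 2019L))
  expect_true(all(study$sites$peat_depth_m >= 0.5 &
                    study$sites$peat_depth_m <= 3.5))
  for (m in c(study$stack$nir, study$stack$swir2)) {
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("disturbed-site pixels have elevated NBR variability and lower baseline", {
  study <- generate_study(seed = 6)
  pr <- stack_stats(study$stack)
  cov <- extract_at_sites(pr, study$sites)
  cf <- cov$class == "CentralForest"
  expect_gt(mean(cov$nbr_sd[!cf]), mean(cov$nbr_sd[cf]))
  expect_lt(mean(cov$nbr_mean[!cf]), mean(cov$nbr_mean[cf]))
})

test_that("a fixed seed reproduces the study byte-for-byte", {
  s1 <- generate_study(seed = 9)
  s2 <- generate_study(seed = 9)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$stack$nir, s2$stack$nir)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in c("cores.csv", "sites.csv", "nir_1989.asc", "river.geojson")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  p1 <- list.files(file.path(d1, "pyrograms"))
  expect_gt(length(p1), 0)
  expect_identical(readLines(file.path(d1, "pyrograms", p1[1])),
                   readLines(file.path(d2, "pyrograms", p1[1])))
})

test_that("study configuration is validated", {
  expect_error(study_config(years = 1989), "two years")
  expect_error(study_config(n_sites = c(CentralForest = 0)), "one site")
})

test_that("written pyrograms reproduce the in-memory Rock-Eval results", {
  cfg <- study_config(n_sites = c(CentralForest = 1), grid_nrow = 8,
                      grid_ncol = 8)
  study <- generate_study(cfg, seed = 3)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  core <- study$cores[[1]]
  id <- names(core$pyrograms)[1]
  q <- read_pyrogram(file.path(dir, "pyrograms", paste0(id, ".csv")))
  expect_equal(compute_parameters(q)[, c("S1", "S2", "TOC", "r_index")],
               compute_parameters(core$pyrograms[[id]])[, c("S1", "S2", "TOC",
                                                            "r_index")],
               tolerance = 1e-9)
})
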