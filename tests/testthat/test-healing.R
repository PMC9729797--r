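# frequency statistics, healing-stage sweep and design criteria

test_that("frequency analysis reproduces the hand-counted example", {
  e <- frequency_bins()$stress_edges
  expect_equal(frequency_analysis(c(10, 60, 60, 400), e),
               c(25, 50, 0, 0, 0, 0, 0, 25))
  expect_equal(frequency_analysis(rep(120, 7), e),
               c(0, 0, 100, 0, 0, 0, 0, 0))
  # half-open membership: a value on an edge belongs to the upper bin
  expect_equal(frequency_analysis(c(50), e)[2], 100)
  expect_error(frequency_analysis(numeric(0), e), "empty")
  expect_error(frequency_analysis(1, c(3, 2)), "increasing")
})

test_that("percentages always sum to 100 and match binomial expectations", {
  e <- frequency_bins()$stress_edges
  set.seed(1234)
  for (i in 1:5) {
    x <- runif(1000, 0, 500)
    expect_equal(sum(frequency_analysis(x, e)), 100, tolerance = 1e-6)
  }
  # 10,000 uniform draws on [0, 400]: per-bin share within 3 sigma of the
  # binomial expectation
  n <- 10000
  x <- runif(n, 0, 400)
  p_expect <- c(50, rep(50, 6), 50) / 400  # each 50-wide bin, last = >350
  pct <- frequency_analysis(x, e)
  for (b in seq_along(p_expect)) {
    sd3 <- 3 * sqrt(p_expect[b] * (1 - p_expect[b]) / n) * 100
    expect_lt(abs(pct[b] - 100 * p_expect[b]), sd3 + 1e-9)
  }
})

test_that("frequency report wires adaptation fraction to the first strain bin", {
  r <- frequency_report("G-T", implant_stress = c(10, 200, 360),
                        graft_strain = c(100, 2000, 4000, 12000))
  expect_equal(r$adaptation_fraction, r$strain_percentages[1])
  expect_equal(r$adaptation_fraction, 50)
  expect_equal(r$max_stress, 360)
  expect_equal(r$max_strain, 12000)
  expect_equal(sum(r$stress_percentages), 100, tolerance = 1e-6)
})

test_that("identical graft material across stages yields identical reports", {
  des <- small_design()
  same <- healing_stages(c("IM-B", "IM-B", "IM-B"))
  reps <- run_stage_sweep(des, same)
  expect_equal(reps[[1]]$stress_percentages, reps[[2]]$stress_percentages)
  expect_equal(reps[[2]]$max_strain, reps[[3]]$max_strain)
})

test_that("stage sweep: implant stress and graft strain maxima are
           non-increasing as the graft matures", {
  reps <- small_sweep()
  mx <- vapply(reps, function(r) r$max_stress, numeric(1))
  ms <- vapply(reps, function(r) r$max_strain, numeric(1))
  expect_true(all(diff(mx) <= 0))   # G-T >= IM-B >= M-B
  expect_true(all(diff(ms) <= 0))
  # adaptation fraction improves as the graft stiffens
  ad <- vapply(reps, function(r) r$adaptation_fraction, numeric(1))
  expect_true(all(diff(ad) >= 0))
})

test_that("adaptation fraction is non-increasing in the bite force", {
  des <- small_design()
  gt <- healing_stages("G-T")
  r800 <- run_stage_sweep(des, gt)[[1]]$adaptation_fraction
  des2 <- defect_model(des$fixture, des$lattice, voxel_mm = des$voxel_mm,
                       load = load_case(bite_force = 1600))
  r1600 <- run_stage_sweep(des2, gt)[[1]]$adaptation_fraction
  expect_lte(r1600, r800)
})

test_that("criteria evaluation: inclusive yield comparison per stage", {
  mk <- function(mx) frequency_report("G-T", implant_stress = c(1, mx),
                                      graft_strain = c(100, 500))
  crit <- criteria_config()
  # the optimized design's printed maxima pass ...
  s1 <- evaluate_criteria(list(mk(697.35), mk(398.36), mk(293.40)), crit)
  expect_true(s1$stress_pass)
  # ... the original design's fail at the G-T stage
  s2 <- evaluate_criteria(list(mk(1036.30), mk(739.22), mk(594.05)), crit)
  expect_false(s2$stress_pass)
  expect_false(s2$stress_pass_by_stage[1])
  # boundary: exactly at yield passes ("cannot exceed" is inclusive)
  s3 <- evaluate_criteria(list(mk(897)), crit)
  expect_true(s3$stress_pass)
})

test_that("a failing stage aborts the sweep naming the stage", {
  des <- small_design()
  bad <- list(list(label = "X-X", graft_material = NULL))
  expect_error(run_stage_sweep(des, bad), "X-X")
})
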