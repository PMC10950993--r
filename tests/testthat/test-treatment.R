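test_that("constant-window efficacy matches the piecewise form", {
  p <- moran_params(f_c = 1.1)
  sch <- treatment_schedule(
    treatment_course(eff_c = 0.8, t_start = 100, t_length = 50))
  ef <- effective_fitness(p, sch, t = c(99, 100, 125, 150, 151))
  expect_equal(ef$f_c, c(1.1, 0.22, 0.22, 0.22, 1.1))
  expect_equal(ef$f_h, rep(1, 5))   # healthy cells are never targeted
  expect_equal(ef$f_m, rep(1.1, 5)) # eff_m = 0 here
})

test_that("waning efficacy halves per half-life", {
  p <- moran_params(f_c = 1.1)
  sch <- treatment_schedule(
    treatment_course(eff_c = 0.8, t_start = 200, mode = "waning",
                     t_half = 300))
  ef <- effective_fitness(p, sch, t = c(0, 200, 500, 800))
  expect_equal(ef$f_c, c(1.1,
                         1.1 * (1 - 0.8),
                         1.1 * (1 - 0.4),
                         1.1 * (1 - 0.2)))
})

test_that("complete efficacy zeroes the targeted clone's fitness", {
  p <- moran_params(f_c = 2, f_m = 3)
  sch <- treatment_schedule(
    treatment_course(eff_c = 1, eff_m = 1, t_start = 0, t_length = 10))
  ef <- effective_fitness(p, sch, t = 5)
  expect_equal(ef$f_c, 0)
  expect_equal(ef$f_m, 0)
  expect_equal(ef$f_h, 1)
})

test_that("negative times and invalid courses are rejected", {
  sch <- preset_schedule("mtd")
  expect_error(schedule_efficacy(sch, -1), "non-negative")
  expect_error(treatment_course(eff_c = 1.2), "efficacies")
  expect_error(treatment_course(eff_c = 0.5, t_length = NA), "t_length")
  expect_error(treatment_course(eff_c = 0.5, mode = "waning"), "t_half")
})

test_that("a constant course is the infinite-half-life limit of a waning one", {
  p <- moran_params(f_c = 1.7)
  cons <- treatment_schedule(
    treatment_course(eff_c = 0.6, t_start = 50, t_length = 400))
  wane <- treatment_schedule(
    treatment_course(eff_c = 0.6, t_start = 50, mode = "waning",
                     t_half = 1e12))
  ts <- seq(50, 450, by = 25)  # inside the window
  expect_equal(effective_fitness(p, wane, ts)$f_c,
               effective_fitness(p, cons, ts)$f_c, tolerance = 1e-9)
})

test_that("raising an efficacy never raises the targeted clone's fitness", {
  p <- moran_params(f_c = 1.5, f_m = 2)
  ts <- seq(0, 1000, by = 50)
  effs <- seq(0, 1, by = 0.1)
  prev <- rep(Inf, length(ts))
  for (e in effs) {
    sch <- treatment_schedule(
      treatment_course(eff_c = e, t_start = 100, t_length = 500),
      treatment_course(eff_c = e / 2, t_start = 400, mode = "waning",
                       t_half = 200))
    cur <- effective_fitness(p, sch, ts)$f_c
    expect_true(all(cur <= prev + 1e-12))
    expect_true(all(cur >= 0 & cur <= p$f_c))
    prev <- cur
  }
})

test_that("superposed doses add and saturate at efficacy 1", {
  # two simultaneous 0.6 doses cap at 1
  two <- treatment_schedule(
    treatment_course(eff_c = 0.6, t_start = 0, mode = "waning", t_half = 100),
    treatment_course(eff_c = 0.6, t_start = 0, mode = "waning", t_half = 100))
  expect_equal(schedule_efficacy(two, 0)$eff_c, 1)
  # a single dose reduces to the plain decaying exponential
  one <- treatment_schedule(
    treatment_course(eff_c = 0.6, t_start = 0, mode = "waning", t_half = 100))
  expect_equal(schedule_efficacy(one, c(0, 100, 300))$eff_c,
               0.6 * 2^(-c(0, 100, 300) / 100))
})

test_that("weekly dose regimen superposes with the 5.8-day half-life", {
  N <- 1000
  reg <- dose_regimen(N, eff_c = 0.3, n_doses = 4)
  expect_equal(nrow(reg), 4)
  expect_equal(reg$t_start, days_to_divisions(c(0, 7, 14, 21), N))
  expect_equal(unique(reg$t_half), days_to_divisions(5.8, N))
  # just before dose 2 only dose 1 contributes; at dose 2 the fresh dose adds
  t2 <- days_to_divisions(7, N)
  carry <- 0.3 * 2^(-7 / 5.8)
  expect_equal(schedule_efficacy(reg, t2 - 1e-9)$eff_c, carry,
               tolerance = 1e-6)
  expect_equal(schedule_efficacy(reg, t2)$eff_c, carry + 0.3)
})

test_that("presets build the five named strategies", {
  mtd <- preset_schedule("mtd", t_start = 5000, t_length = 3000,
                         eff_c = 0.8, eff_m = 0.4)
  expect_equal(nrow(mtd), 1)
  expect_equal(mtd$mode, "constant")
  expect_equal(mtd[, c("t_start", "t_length", "eff_c", "eff_m")],
               tibble::tibble(t_start = 5000, t_length = 3000,
                              eff_c = 0.8, eff_m = 0.4),
               ignore_attr = TRUE)

  early <- preset_schedule("early_mtd", early_start = 500)
  expect_equal(early$t_start, 500)

  dual <- preset_schedule("dual", t_start = 4000, t_length = 4000)
  expect_equal(nrow(dual), 2)
  expect_true(dual$eff_m[1] > 0 && dual$eff_c[1] == 0)  # mutant targeted first
  expect_true(dual$eff_c[2] > 0 && dual$eff_m[2] == 0)
  expect_equal(dual$t_start, c(4000, 6000))

  sus <- preset_schedule("sustained", eff_scale = 1 / 3, length_scale = 5)
  expect_equal(sus$eff_c, 0.8 / 3)
  expect_equal(sus$t_length, 25000)

  wan <- preset_schedule("waning")
  expect_equal(wan$mode, "waning")
  expect_equal(wan$t_half, 5000)

  expect_error(preset_schedule("bolus"))
})

test_that("an empty schedule leaves fitness untouched", {
  p <- moran_params(f_c = 1.9, f_m = 2.2)
  ef <- effective_fitness(p, treatment_schedule(), t = c(0, 10, 1e6))
  expect_equal(ef$f_c, rep(1.9, 3))
  expect_equal(ef$f_m, rep(2.2, 3))
})

test_that("clock-time conversion is reciprocal and uses N/8 divisions per hour", {
  expect_equal(days_to_divisions(1, 1000), 3000)
  expect_equal(divisions_to_days(days_to_divisions(5.8, 250), 250), 5.8)
})
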