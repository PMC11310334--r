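test_that("scenario configs validate their grids and time settings", {
  expect_error(scenario_config(n_steps = 1), class = "fracdrink_invalid_config")
  expect_error(scenario_config(t_end = 0), class = "fracdrink_invalid_config")
  expect_error(scenario_config(multipliers = c(1, 1.2)))
  cfg <- scenario_config(vartheta = c(0.9, 1), zeta = c(0.8, 1))
  expect_equal(nrow(cfg$orders), 4L)
})

test_that("packaged scenario configurations load and describe the studies", {
  dir <- system.file("extdata", "scenarios", package = "fracdrink")
  files <- list.files(dir, full.names = TRUE)
  expect_length(files, 5L)
  for (f in files) {
    cfg <- read_scenario_config(f)
    expect_s3_class(cfg, "scenario_config")
    expect_gte(nrow(cfg$orders), 1L)
  }
  endemic <- read_scenario_config(file.path(dir, "figs4-5.yaml"))
  expect_equal(endemic$params$beta1, 0.6)
  expect_gt(reproduction_number(endemic$params), 1)
})

test_that("subcritical and supercritical runs classify their attractors", {
  sub <- scenario_config(vartheta = c(0.95, 1), zeta = 1,
                         t_end = 400, n_steps = 1500)
  res_sub <- run_scenario(sub)
  expect_true(all(res_sub$attractor == "AFE"))
  expect_true(all(res_sub$R0 < 1))

  p <- tbl1; p$beta1 <- 0.6
  sup <- scenario_config(params = p, vartheta = c(0.9, 1), zeta = 1,
                         t_end = 400, n_steps = 1500)
  res_sup <- run_scenario(sup)
  expect_true(all(res_sup$attractor == "EE"))
  expect_true(all(res_sup$R0 > 1))
})

test_that("the classified attractor flips where R0 crosses one", {
  p <- tbl1; p$beta1 <- 0.6  # R0 ~ 1.306; halving beta1 pushes R0 below 1
  cfg <- scenario_config(params = p, vartheta = 1, zeta = 1,
                         multipliers = c(1, 0.5), apply_to = "beta1",
                         t_end = 400, n_steps = 1500)
  res <- run_scenario(cfg)
  res <- res[order(res$multiplier), ]
  expect_equal(res$attractor, c("AFE", "EE"))
  expect_true(res$R0[1] < 1 && res$R0[2] > 1)
  # attractor labels never contradict the threshold theory
  expect_true(all(res$attractor != "EE" | res$R0 > 1))
  expect_true(all(res$attractor != "AFE" | res$R0 < 1))
})

test_that("scenario reports are byte-identical across reruns", {
  cfg <- scenario_config(vartheta = 1, zeta = 1, t_end = 50, n_steps = 200)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_scenario(cfg, out_dir = d1)
  run_scenario(cfg, out_dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})

test_that("cumulative burden falls as contact rates are reduced", {
  sw <- contact_rate_sweep(t_end = 60, n_steps = 400)
  expect_equal(nrow(sw), 4 * 2 * 4)  # multipliers x orders x compartments
  expect_equal(sum(sw$compartment == "H"), 8L)
  wide <- tidyr::pivot_wider(sw, names_from = "multiplier",
                             values_from = "burden",
                             id_cols = c("vartheta", "compartment"))
  expect_true(all(wide[["0.25"]] < wide[["1"]]))
  # burden is monotone along the full reduction path for every cell
  for (v in unique(sw$vartheta)) for (cc in unique(sw$compartment)) {
    b <- sw$burden[sw$vartheta == v & sw$compartment == cc]
    m <- sw$multiplier[sw$vartheta == v & sw$compartment == cc]
    expect_true(all(diff(b[order(m)]) >= 0))
  }
})

test_that("contact-rate recovery is exact on noise-free observations", {
  truth <- solve_caputo(tbl1, ic_default, 0.9, t_end = 40, n_steps = 400)
  obs <- truth[seq(5, 401, by = 4), ]
  fit <- fit_contact_rate(obs, tbl1, vartheta = 0.9, bounds = c(0.05, 1.2),
                          n_steps = 400, n_scan = 5)
  expect_lt(abs(fit$estimate - 0.4), 1e-4)
  expect_false(fit$at_bound)
  td <- tidy(fit)
  expect_equal(td$term, "beta1")
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("a bracket excluding the truth pins the estimate at the bound", {
  truth <- solve_caputo(tbl1, ic_default, 0.9, t_end = 40, n_steps = 200)
  obs <- truth[seq(5, 201, by = 4), ]
  expect_warning(
    fit <- fit_contact_rate(obs, tbl1, vartheta = 0.9, bounds = c(0.5, 1.0),
                            n_steps = 200, n_scan = 5),
    "bound"
  )
  expect_true(fit$at_bound)
  expect_equal(fit$estimate, 0.5, tolerance = 1e-3)
})
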