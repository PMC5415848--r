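test_that("isotherm simulation matches the bisection oracle", {
  sched <- default_schedule()
  got <- simulate_titration(51, 1.35, -5.8, sched, 100, 1500)
  want <- oracle_titration_heats(51, 1.35, -5.8, sched, 100, 1500)
  expect_equal(got, want, tolerance = 1e-9)

  # a second geometry (weak binder, fewer injections)
  got2 <- simulate_titration(400, 1, -3.2, rep(2, 15), 80, 2400, 200)
  want2 <- oracle_titration_heats(400, 1, -3.2, rep(2, 15), 80, 2400, 200)
  expect_equal(got2, want2, tolerance = 1e-9)

  expect_equal(simulate_titration(51, 1, 0, sched, 100, 1500), rep(0, 20))
  expect_error(simulate_titration(-5, 1, -5, sched, 100, 1500), "K_D")
})

test_that("tight-binding limit releases dH per mole injected until saturation", {
  sched <- default_schedule()
  h <- simulate_titration(1e-4, 1, -5.8, sched, 100, 1500, 200)
  mol_inj <- 1500 * sched * 1e-12                 # mol ligand per injection
  expected <- -5.8e3 * mol_inj * 1e6              # ucal
  # pre-equivalence injections (cumulative ligand << N M V0)
  expect_equal(h[2:5], expected[2:5], tolerance = 1e-3)
  # post-equivalence injections are essentially heat-free
  expect_lt(abs(h[20]), abs(expected[20]) * 1e-3)
})

test_that("cumulative heat approaches N M V0 dH at strong saturation", {
  # tight binder, syringe load ~50x the site count, small injections so the
  # discrete perfusion correction stays accurate
  h <- simulate_titration(0.051, 1, -5.8, rep(0.5, 20), 100, 2e6, 200)
  total <- 1 * 100 * 200 * -5.8 * 1e-3
  expect_lt(abs(sum(h) - total) / abs(total), 0.005)
})

test_that("per-mole heat is non-increasing in magnitude after equivalence", {
  h <- simulate_titration(51, 1.35, -5.8, rep(2, 20), 100, 1500, 200)
  per_mole <- abs(h) / (1500 * 2e-12)
  # equivalence at ~ N M V0 / (X dV) = 9 injections
  post <- per_mole[10:20]
  expect_true(all(diff(post) <= 1e-9))
})

test_that("blank subtraction requires matching schedules", {
  tit <- make_titration(51, 1.35, -5.8, noise_sd = 0)
  zero <- titration(default_schedule(), rep(0, 20), 200, 100, 1500)
  expect_equal(subtract_blank(tit, zero)$heats, tit$heats)

  const <- titration(default_schedule(), rep(0.3, 20), 200, 100, 1500)
  expect_equal(subtract_blank(tit, const)$heats, tit$heats - 0.3)

  short <- titration(rep(2, 10), rep(0, 10), 200, 100, 1500)
  expect_error(subtract_blank(tit, short), "schedule")
})

test_that("noiseless fit recovers the generating parameters to < 0.1%", {
  tit <- make_titration(51, 1.35, -5.8, noise_sd = 0)
  fit <- fit_single_site(tit)
  expect_true(fit$converged)
  expect_lt(abs(fit$k_d / 51 - 1), 1e-3)
  expect_lt(abs(fit$n / 1.35 - 1), 1e-3)
  expect_lt(abs(fit$delta_h / -5.8 - 1), 1e-3)
  expect_gt(fit$c_value, 1)

  expect_error(fit_single_site(make_titration(51, 1.35, 0, noise_sd = 0)),
               "zero")
})

test_that("fixing N pins the stoichiometry and re-fits the rest", {
  tit <- make_titration(51, 1.35, -5.8, noise_sd = 0.2, seed = 3)
  fit <- fit_single_site(tit, fix_n = 1)
  expect_identical(fit$n, 1)
  expect_identical(fit$n_err, 0)
  expect_true(fit$n_fixed)
  expect_true(fit$converged)
})

test_that("weak binders are reported as a K_D lower bound", {
  # K_D far above the cell concentration: c << 1
  tit <- make_titration(5000, 1, -5, cell_conc = 100, syringe_conc = 3000,
                        noise_sd = 0.05, seed = 2)
  fit <- fit_single_site(tit, fix_n = 1)
  expect_lt(fit$c_value, 1)
  if (fit$kd_is_bound) expect_match(fit$kd_report, "^>")
})

test_that("derived thermodynamics reproduce the printed exemplar rows", {
  wt <- derive_thermo(51, 2, -5.8, 0.1)
  f <- format_thermo_row(wt)
  expect_equal(unname(f["dg"]), -5.86)
  expect_equal(unname(f["dg_err"]), 0.02)
  expect_equal(unname(f["tds"]), 0.1)
  expect_equal(unname(f["tds_err"]), 0.1)

  gg <- format_thermo_row(derive_thermo(143, 7, -7.4, 0.3))
  expect_equal(unname(gg["dg"]), -5.25)
  expect_equal(unname(gg["tds"]), -2.2)

  # ln 1 = 0 at K_D of 1 M
  molar <- derive_thermo(1e6, delta_h = -5)
  expect_equal(molar$dg, 0)
  expect_equal(molar$tds, -5)

  # identity dG = dH - TdS holds exactly before rounding
  r <- derive_thermo(37.2, 1.5, -6.44, 0.21)
  expect_equal(r$dg, r$delta_h - r$tds)

  expect_error(derive_thermo(-1, delta_h = 0), "K_D")
})

test_that("fold changes match the reported affinity ratios", {
  expect_equal(fold_change(51, 210)$ratio, 4.1)
  expect_equal(fold_change(48, 810)$ratio, 16.9)
  expect_equal(fold_change(48, 810)$fold_label, "~17-fold")
  expect_equal(fold_change(48, 48)$ratio, 1.0)
  expect_error(fold_change(0, 48), "> 0")
})

test_that("packaged thermodynamic tables are internally consistent", {
  for (tab in c("table2_thermo.csv", "table3_thermo.csv")) {
    rep <- validate_table(helixread_extdata(tab))
    numeric_rows <- rep$status != "skipped"
    expect_true(all(rep$status[numeric_rows] == "ok"), label = tab)
    expect_true(all(abs(rep$dg_dev[numeric_rows]) <= 0.03), label = tab)
    expect_true(all(abs(rep$tds_dev[numeric_rows]) <= 0.1), label = tab)
  }
  # lower-bound rows are skipped with a note
  t2 <- validate_table(helixread_extdata("table2_thermo.csv"))
  expect_true(all(t2$status[grepl(">", t2$kd_raw)] == "skipped"))

  # an injected corruption is flagged
  tab <- read_thermo_table(helixread_extdata("table2_thermo.csv"))
  tab$dg[4] <- tab$dg[4] + 1
  rep <- validate_table(tab)
  expect_equal(rep$status[4], "inconsistent")
})

test_that("titrations round-trip through CSV", {
  tit <- make_titration(51, 1.35, -5.8, noise_sd = 0.2, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration(tit, path)
  back <- read_titration(path)
  expect_equal(back$volumes, tit$volumes)
  expect_equal(back$heats, tit$heats, tolerance = 1e-6)
  expect_equal(back$cell_conc, tit$cell_conc)
  expect_equal(back$temperature, tit$temperature)
})
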