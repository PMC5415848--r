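R_KCAL <- 1.9872e-3   # gas constant, kcal / (mol K)
ITC_TEMP <- 298.15    # default experiment temperature (25 C), K

#' Construct a titration object
#'
#' @param volumes Injection volumes (ul), in order.
#' @param heats Measured (or simulated) injection heats (ucal).
#' @param cell_vol Calorimeter cell volume (ul).
#' @param cell_conc Macromolecule concentration in the cell (uM).
#' @param syringe_conc Ligand concentration in the syringe (uM).
#' @param temperature Temperature (K).
#' @return Object of class `titration`.
#' @export
titration <- function(volumes, heats, cell_vol = 200, cell_conc,
                      syringe_conc, temperature = ITC_TEMP) {
  if (!length(volumes)) stop("empty injection schedule")
  if (length(volumes) != length(heats))
    stop("volumes and heats differ in length")
  if (any(volumes <= 0)) stop("injection volumes must be > 0")
  if (cell_vol <= 0 || cell_conc <= 0 || syringe_conc <= 0)
    stop("volumes and concentrations must be > 0")
  structure(list(volumes = as.numeric(volumes), heats = as.numeric(heats),
                 cell_vol = cell_vol, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, temperature = temperature,
                 meta = list()),
            class = "titration")
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf(
    "titration: %d injections, cell %.0f ul at %.1f uM, syringe %.0f uM, %.2f K\n",
    length(x$volumes), x$cell_vol, x$cell_conc, x$syringe_conc,
    x$temperature))
  invisible(x)
}

#' Default injection schedule
#'
#' One first injection of 0.4 ul followed by 19 injections of 2 ul.
#' @return Numeric vector of injection volumes (ul).
#' @export
default_schedule <- function() c(0.4, rep(2, 19))

# running cell concentrations after cumulative injected volume v (ul),
# using the standard perfusion (displaced volume) correction
cell_concentrations <- function(cell_conc, syringe_conc, cell_vol, v) {
  list(M = cell_conc * (1 - v / (2 * cell_vol)) / (1 + v / (2 * cell_vol)),
       X = syringe_conc * (v / cell_vol) / (1 + v / (2 * cell_vol)))
}

# fraction of sites occupied: smaller root of
# theta^2 - theta (1 + X/(N M) + Kd/(N M)) + X/(N M) = 0
site_occupancy <- function(k_d, n_sites, M, X) {
  s <- n_sites * M
  b <- 1 + X / s + k_d / s
  c0 <- X / s
  disc <- b^2 - 4 * c0
  if (any(disc < 0)) stop("negative discriminant in binding quadratic")
  theta <- (b - sqrt(disc)) / 2
  if (any(theta < -1e-12 | theta > 1 + 1e-12))
    stop("nonphysical occupancy root")
  pmin(pmax(theta, 0), 1)
}

#' Simulate a single-site (Wiseman) binding isotherm
#'
#' Computes per-injection heats for a 1:N single-binding-site model with
#' the standard displaced-volume (perfusion) correction. After injection i
#' the running cell concentrations are
#' `M_i = M0 (1 - v/2V0)/(1 + v/2V0)` and
#' `X_i = X_syr (v/V0)/(1 + v/2V0)` with `v` the cumulative injected
#' volume; the bound-site fraction theta is the smaller root of the
#' single-site quadratic, and the heat of injection i is
#' `dQ_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i + Q_{i-1})/2` with heat content
#' `Q_i = N theta_i M_i V0 dH`.
#'
#' @param k_d Dissociation constant (uM, > 0).
#' @param n_sites Binding stoichiometry N.
#' @param delta_h Binding enthalpy (kcal/mol).
#' @param schedule Injection volumes (ul).
#' @param cell_conc,syringe_conc Concentrations (uM).
#' @param cell_vol Cell volume (ul).
#' @return Numeric vector of injection heats (ucal).
#' @export
simulate_titration <- function(k_d, n_sites, delta_h,
                               schedule = default_schedule(),
                               cell_conc, syringe_conc, cell_vol = 200) {
  if (k_d <= 0) stop("K_D must be > 0")
  if (n_sites <= 0) stop("n_sites must be > 0")
  if (!length(schedule)) stop("empty injection schedule")
  if (any(schedule <= 0)) stop("injection volumes must be > 0")
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_vol <= 0)
    stop("concentrations and volumes must be > 0")
  v <- cumsum(schedule)
  if (max(v) >= cell_vol)
    stop("cumulative injected volume exceeds cell volume; ",
         "the perfusion correction is invalid there")
  conc <- cell_concentrations(cell_conc, syringe_conc, cell_vol, v)
  theta <- site_occupancy(k_d, n_sites, conc$M, conc$X)
  # heat content in ucal: conc uM (=1e-6 mol/L), volume ul (=1e-6 L),
  # dH kcal/mol (=1e3 cal/mol)  =>  uM * ul * kcal/mol = 1e-9 cal = 1e-3 ucal
  Q <- n_sites * theta * conc$M * cell_vol * delta_h * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (schedule / cell_vol) * (Q + Qprev) / 2
}

#' Generate a synthetic titration with seeded Gaussian noise
#'
#' @inheritParams simulate_titration
#' @param noise_sd Gaussian heat noise s.d. (ucal, >= 0).
#' @param seed Integer seed.
#' @param temperature Temperature (K).
#' @return A [titration()].
#' @export
make_titration <- function(k_d, n_sites, delta_h,
                           schedule = default_schedule(),
                           cell_conc = 100, syringe_conc = 1500,
                           cell_vol = 200, noise_sd = 0, seed = 1L,
                           temperature = ITC_TEMP) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  heats <- simulate_titration(k_d, n_sites, delta_h, schedule,
                              cell_conc, syringe_conc, cell_vol)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    heats <- heats + rng$rnorm(length(heats), 0, noise_sd)
  }
  tit <- titration(schedule, heats, cell_vol, cell_conc, syringe_conc,
                   temperature)
  tit$meta$truth <- list(k_d = k_d, n_sites = n_sites, delta_h = delta_h,
                         noise_sd = noise_sd, seed = seed)
  tit
}

#' Subtract a blank (heat-of-dilution) titration
#'
#' @param sample,blank [titration()] objects with identical injection
#'   schedules.
#' @return The sample titration with per-injection heats differenced;
#'   `meta$blank_subtracted` records the operation.
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "titration"), inherits(blank, "titration"))
  if (length(sample$volumes) != length(blank$volumes) ||
      any(abs(sample$volumes - blank$volumes) > 1e-9))
    stop("injection schedules differ between sample and blank")
  sample$heats <- sample$heats - blank$heats
  sample$meta$blank_subtracted <- TRUE
  sample
}

#' Fit a single-binding-site model to a titration
#'
#' Nonlinear least squares in (ln K_A, dH, N, baseline): the model heats
#' come from [simulate_titration()] plus a constant per-injection baseline
#' offset. The first injection is discarded from the residuals by default
#' (small pre-injection convention) but still drives the running
#' concentrations. Parameter errors are taken from the covariance matrix at
#' the optimum. The Wiseman c-value `N M0 / K_D` is reported; for c < 1
#' with a K_D estimate beyond `kd_ceiling` the K_D is flagged as a lower
#' bound (reported as e.g. ">1000").
#'
#' @param tit A [titration()].
#' @param discard_first Drop the first injection from the fit (default
#'   TRUE).
#' @param fix_n Optional fixed stoichiometry (e.g. 1); its error is then 0.
#' @param kd_ceiling Reporting ceiling for weak binders (uM).
#' @return Object of class `binding_fit`: list with `k_d`, `k_d_err` (uM),
#'   `n`, `n_err`, `delta_h`, `delta_h_err` (kcal/mol), `baseline` (ucal),
#'   `c_value`, `residual_norm`, `converged`, `n_fixed`, `kd_is_bound`,
#'   `kd_report`.
#' @export
fit_single_site <- function(tit, discard_first = TRUE, fix_n = NULL,
                            kd_ceiling = 1000) {
  stopifnot(inherits(tit, "titration"))
  use <- seq_along(tit$heats)
  if (discard_first) use <- use[-1]
  if (length(use) < 3) stop("need >= 3 usable injections")
  if (all(abs(tit$heats[use]) < 1e-12))
    stop("all heats are zero; nothing to fit")

  model_heats <- function(lnka, dh, n) {
    simulate_titration(exp(-lnka) * 1e6, n, dh, tit$volumes,
                       tit$cell_conc, tit$syringe_conc, tit$cell_vol)
  }
  resid_fun <- function(par) {
    n <- if (is.null(fix_n)) par[3] else fix_n
    base <- par[length(par)]
    h <- tryCatch(model_heats(par[1], par[2], abs(n)),
                  error = function(e) rep(1e6, length(tit$heats)))
    (h[use] + base) - tit$heats[use]
  }

  # multistart over K_D guesses; dH guess from total heat at N = 1
  m0_mol <- tit$cell_conc * tit$cell_vol * 1e-12          # mol in cell
  dh0 <- sum(tit$heats[use]) * 1e-6 / (m0_mol * 1e3)      # kcal/mol
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  kd_guesses <- tit$cell_conc * c(0.01, 0.1, 1, 10)       # uM
  best <- NULL
  for (kd0 in kd_guesses) {
    par0 <- c(log(1 / (kd0 * 1e-6)), dh0,
              if (is.null(fix_n)) 1 else NULL, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("single-site fit failed to converge")

  par <- best$par
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par)))
  lnka <- par[1]
  kd <- exp(-lnka) * 1e6                      # uM
  kd_err <- if (is.finite(se[1])) kd * se[1] else NA_real_
  dh <- par[2]
  dh_err <- se[2]
  if (is.null(fix_n)) {
    n <- abs(par[3]); n_err <- se[3]
  } else {
    n <- fix_n; n_err <- 0
  }
  baseline <- par[length(par)]
  c_value <- n * tit$cell_conc / kd
  kd_is_bound <- c_value < 1 && kd > kd_ceiling
  structure(list(
    k_d = kd, k_d_err = kd_err, n = n, n_err = n_err,
    delta_h = dh, delta_h_err = dh_err, baseline = baseline,
    c_value = c_value, residual_norm = sqrt(best$deviance),
    converged = best$info %in% 1:4, n_fixed = !is.null(fix_n),
    kd_is_bound = kd_is_bound,
    kd_report = if (kd_is_bound) paste0(">", format(kd_ceiling)) else
      format(signif(kd, 3)),
    low_c_warning = c_value < 1,
    temperature = tit$temperature),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "single-site fit: K_D = %s uM (+/- %.3g), N = %.3f (+/- %.3g), dH = %.3f kcal/mol (+/- %.3g), c = %.1f%s\n",
    x$kd_report, x$k_d_err, x$n, x$n_err, x$delta_h, x$delta_h_err,
    x$c_value, if (x$low_c_warning) " [low c: parameters poorly identified]" else ""))
  invisible(x)
}

#' Derive binding thermodynamics with propagated errors
#'
#' `dG = R T ln(K_D in M)`, `T dS = dH - dG`, with
#' `d(dG) = R T dK_D / K_D` and `d(T dS) = sqrt(d(dH)^2 + d(dG)^2)`.
#' Values are returned at full precision; the printed-table convention
#' (dG to two decimals, T dS to one) is available via [format_thermo_row()].
#'
#' @param k_d,k_d_err Dissociation constant and its error (uM).
#' @param delta_h,delta_h_err Binding enthalpy and its error (kcal/mol).
#' @param temperature Temperature (K).
#' @return Object of class `thermo_row`: list with `k_d`, `k_d_err`, `n`,
#'   `n_err` (optional, NA by default), `delta_h`, `delta_h_err`, `dg`,
#'   `dg_err`, `tds`, `tds_err`, `temperature`.
#' @export
derive_thermo <- function(k_d, k_d_err = NA_real_, delta_h,
                          delta_h_err = NA_real_, temperature = ITC_TEMP) {
  if (k_d <= 0) stop("K_D must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  rt <- R_KCAL * temperature
  dg <- rt * log(k_d * 1e-6)
  dg_err <- if (is.finite(k_d_err)) rt * k_d_err / k_d else NA_real_
  tds <- delta_h - dg
  tds_err <- if (is.finite(delta_h_err) && is.finite(dg_err))
    sqrt(delta_h_err^2 + dg_err^2) else NA_real_
  structure(list(k_d = k_d, k_d_err = k_d_err,
                 delta_h = delta_h, delta_h_err = delta_h_err,
                 dg = dg, dg_err = dg_err, tds = tds, tds_err = tds_err,
                 temperature = temperature),
            class = "thermo_row")
}

#' Format a thermodynamics row at printed-table precision
#'
#' dG (and its error) to two decimals, T dS (and its error) to one decimal.
#'
#' @param row A `thermo_row` from [derive_thermo()].
#' @return Named numeric vector `c(dg, dg_err, tds, tds_err)`, rounded.
#' @export
format_thermo_row <- function(row) {
  stopifnot(inherits(row, "thermo_row"))
  c(dg = round(row$dg, 2), dg_err = round(row$dg_err, 2),
    tds = round(row$tds, 1), tds_err = round(row$tds_err, 1))
}

#' @export
print.thermo_row <- function(x, ...) {
  f <- format_thermo_row(x)
  cat(sprintf(
    "K_D = %.3g uM, dH = %.2f kcal/mol, dG = %.2f +/- %.2f, TdS = %.1f +/- %.1f kcal/mol (%.2f K)\n",
    x$k_d, x$delta_h, f["dg"], f["dg_err"], f["tds"], f["tds_err"],
    x$temperature))
  invisible(x)
}

#' Affinity fold change between two dissociation constants
#'
#' @param k_d_reference Reference K_D (uM).
#' @param k_d_other Comparison K_D (uM).
#' @return List with `ratio` (`k_d_other / k_d_reference`, one decimal),
#'   `ratio_exact`, and `fold_label` (nearest-integer "~N-fold" rendering).
#' @export
fold_change <- function(k_d_reference, k_d_other) {
  if (k_d_reference <= 0 || k_d_other <= 0) stop("K_D values must be > 0")
  r <- k_d_other / k_d_reference
  list(ratio = round(r, 1), ratio_exact = r,
       fold_label = paste0("~", round(r), "-fold"))
}

#' Read a printed thermodynamic-parameter table
#'
#' Parses a CSV with columns `peptide, protein, kd_uM, kd_err, n, n_err,
#' dh, dh_err, tds, tds_err, dg, dg_err, note`. Non-numeric K_D entries
#' (lower bounds such as ">1000", "N.D." or "No binding" rows) are kept
#' with `kd_uM = NA` and the raw entry in `kd_raw`. Unicode minus signs
#' are normalized.
#'
#' @param path CSV file (see `inst/extdata/table2_thermo.csv`).
#' @return data.frame.
#' @export
read_thermo_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  num <- function(x) {
    x <- gsub("−", "-", x)        # Unicode minus
    suppressWarnings(as.numeric(x))
  }
  out <- data.frame(peptide = df$peptide, protein = df$protein,
                    kd_raw = df$kd_uM, kd_uM = num(df$kd_uM),
                    kd_err = num(df$kd_err), n = num(df$n),
                    n_err = num(df$n_err), dh = num(df$dh),
                    dh_err = num(df$dh_err), tds = num(df$tds),
                    tds_err = num(df$tds_err), dg = num(df$dg),
                    dg_err = num(df$dg_err),
                    note = if ("note" %in% names(df)) df$note else "",
                    stringsAsFactors = FALSE)
  out
}

#' Validate a printed thermodynamics table for internal consistency
#'
#' For every numeric row, dG is recomputed from the printed K_D and T dS
#' from printed dH minus recomputed dG; deviations from the printed values
#' are reported. Rows whose K_D is a bound (e.g. ">1000") or not determined
#' are skipped with a note.
#'
#' @param table data.frame from [read_thermo_table()] (or a path to one).
#' @param temperature Temperature (K).
#' @param dg_tol,tds_tol Flagging tolerances (kcal/mol); defaults absorb
#'   the printed rounding of K_D.
#' @return data.frame with recomputed values, deviations and a `status`
#'   column (`ok`, `inconsistent`, `skipped`).
#' @export
validate_table <- function(table, temperature = ITC_TEMP,
                           dg_tol = 0.03, tds_tol = 0.1) {
  if (is.character(table)) table <- read_thermo_table(table)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (!is.finite(r$kd_uM) || !is.finite(r$dg) || !is.finite(r$dh)) {
      return(data.frame(r, dg_recomputed = NA_real_, tds_recomputed = NA_real_,
                        dg_dev = NA_real_, tds_dev = NA_real_,
                        status = "skipped", stringsAsFactors = FALSE))
    }
    th <- derive_thermo(r$kd_uM, r$kd_err, r$dh, r$dh_err, temperature)
    dg_dev <- th$dg - r$dg
    tds_dev <- th$tds - r$tds
    ok <- abs(dg_dev) <= dg_tol && abs(tds_dev) <= tds_tol
    data.frame(r, dg_recomputed = th$dg, tds_recomputed = th$tds,
               dg_dev = dg_dev, tds_dev = tds_dev,
               status = if (ok) "ok" else "inconsistent",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write titration CSV files
#'
#' Format: comment header lines `# key=value` for `temp_K`, `cell_ul`,
#' `cell_uM`, `syringe_uM`, then columns `volume_ul, heat_ucal`.
#'
#' @param path CSV file.
#' @return A [titration()].
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "="))
  meta <- stats::setNames(as.numeric(kv[, 2]), trimws(kv[, 1]))
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  titration(df$volume_ul, df$heat_ucal, cell_vol = meta[["cell_ul"]],
            cell_conc = meta[["cell_uM"]], syringe_conc = meta[["syringe_uM"]],
            temperature = meta[["temp_K"]])
}

#' @rdname read_titration
#' @param tit A [titration()].
#' @export
write_titration <- function(tit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%.6g",
                     c("temp_K", "cell_ul", "cell_uM", "syringe_uM"),
                     c(tit$temperature, tit$cell_vol, tit$cell_conc,
                       tit$syringe_conc)), con)
  writeLines("volume_ul,heat_ucal", con)
  writeLines(sprintf("%.6g,%.8g", tit$volumes, tit$heats), con)
  invisible(path)
}
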