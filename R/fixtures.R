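#' Path to a packaged data file
#'
#' @param name File name under the package's `extdata/` (e.g.
#'   `"table2_thermo.csv"`).
#' @return Absolute path.
#' @export
helixread_extdata <- function(name) {
  system.file("extdata", name, package = "helixread", mustWork = TRUE)
}

#' Regenerate all synthetic inputs and packaged table copies
#'
#' Writes, under `dir`: a multi-model PDB ensemble with a planted helicity
#' fraction, free/bound HSQC peak-list CSVs with planted shifted residues,
#' a noisy synthetic titration CSV, a planted acidic-wall alignment in
#' aligned FASTA, and verbatim copies of the packaged thermodynamic-table
#' CSVs. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ensemble = file.path(dir, "synthetic_ensemble.pdb"),
    free = file.path(dir, "synthetic_hsqc_free.csv"),
    bound = file.path(dir, "synthetic_hsqc_bound.csv"),
    titration = file.path(dir, "synthetic_titration.csv"),
    msa = file.path(dir, "synthetic_msa.fasta"),
    table2 = file.path(dir, "table2_thermo.csv"),
    table3 = file.path(dir, "table3_thermo.csv")
  )
  ens <- make_ensemble("ARTKQTARKS", 0.4, n_frames = 40, seed = seed,
                       n_replicas = 4)
  write_structures(ens, paths["ensemble"])
  pk <- make_peak_lists(30, shifted = list("7" = c(0.10, 0.50),
                                           "12" = c(0.05, 0.20)),
                        jitter = 0.002, seed = seed, n_sidechain = 2)
  write_peak_list(pk$free, paths["free"])
  write_peak_list(pk$bound, paths["bound"])
  tit <- make_titration(51, 1.35, -5.8, noise_sd = 0.2, seed = seed)
  write_titration(tit, paths["titration"])
  msa <- make_msa(10, wall_set = 1:4, trp_set = 5:7, double_patch_set = 1,
                  length = 60, seed = seed)
  write_alignment(msa, paths["msa"])
  file.copy(helixread_extdata("table2_thermo.csv"), paths["table2"],
            overwrite = TRUE)
  file.copy(helixread_extdata("table3_thermo.csv"), paths["table3"],
            overwrite = TRUE)
  invisible(paths)
}
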