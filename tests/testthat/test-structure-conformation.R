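test_that("hydrogen-bond detection matches brute-force oracle on short chains", {
  cases <- list(
    helix = make_ideal_chain(h3_wt, -57, -47),
    extended = make_ideal_chain(h3_wt, -139, 135),
    mixed = make_ideal_chain("ARTKQTARKSQP",
                             phi = c(-139, -139, -57, -57, -57, -57, -57,
                                     -139, -139, -57, -57, -57),
                             psi = c(135, 135, -47, -47, -47, -47, -47,
                                     135, 135, -47, -47, -47)),
    short = make_ideal_chain("ART", -57, -47)
  )
  for (nm in names(cases)) {
    got <- detect_hbonds(cases[[nm]])
    got <- got[order(got$donor, got$acceptor), c("donor", "acceptor", "energy")]
    want <- oracle_hbonds(cases[[nm]])
    expect_equal(got$donor, want$donor, label = nm)
    expect_equal(got$acceptor, want$acceptor, label = nm)
    expect_equal(got$energy, want$energy, tolerance = 1e-12, label = nm)
  }
})

test_that("ideal alpha-helix shows the canonical i to i+4 ladder", {
  hb <- detect_hbonds(make_ideal_chain(h3_wt, -57, -47))
  expect_equal(hb$acceptor, 1:6)
  expect_equal(hb$donor, 5:10)
  expect_true(all(hb$energy < -0.5))
  # T3 -> A7 and K4 -> R8 style bonds are the donor 7 <- acceptor 3 and
  # donor 8 <- acceptor 4 entries of the ladder
  expect_true(all(c(7, 8) %in% hb$donor[hb$acceptor %in% c(3, 4)]))
})

test_that("sidechain-to-backbone bonds are found by the distance criterion", {
  ch <- make_ideal_chain(h3_wt, -57, -47)
  amide_n <- as.numeric(
    ch$atoms[ch$atoms$resno == 6 & ch$atoms$elety == "N", c("x", "y", "z")])
  ch <- add_sidechain_atom(ch, 3, "OG1", amide_n + c(3.0, 0, 0))
  hb <- detect_hbonds(ch, include_sidechain = TRUE)
  sc <- hb[hb$kind == "sidechain-backbone", ]
  expect_true(any(sc$donor == 3 & sc$acceptor == 6 & sc$donor_atom == "OG1"))
  expect_equal(sc$distance[sc$acceptor == 6 & sc$donor_atom == "OG1"][1], 3.0,
               tolerance = 1e-9)
})

test_that("detection is invariant under rigid-body motion", {
  ch <- make_ideal_chain(h3_wt, -57, -47)
  rot <- random_rotation(42)
  moved <- helixread:::transform_chain(ch, rot, c(11.3, -4.2, 250))
  a <- detect_hbonds(ch)
  b <- detect_hbonds(moved)
  expect_equal(a$donor, b$donor)
  expect_equal(a$acceptor, b$acceptor)
  expect_equal(a$energy, b$energy, tolerance = 1e-9)
  expect_equal(assign_helicity(ch), assign_helicity(moved))
})

test_that("helicity assignment covers the minimal-helix rule", {
  expect_equal(which(assign_helicity(make_ideal_chain(h3_wt, -57, -47))), 2:9)
  expect_false(any(assign_helicity(make_ideal_chain(h3_wt, -139, 135))))
  expect_false(any(assign_helicity(make_ideal_chain("ART", -57, -47))))
})

test_that("multi-model PDB round-trips through write/read", {
  ens <- make_ensemble(h3_wt, 0.5, 8, seed = 2, n_replicas = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structures(ens, path)
  back <- read_structures(path, replica = rep(1:2, each = 4))
  expect_equal(length(back$frames), 8)
  expect_equal(back$replica, rep(1:2, each = 4))
  for (m in c(1, 5)) {
    expect_equal(back$frames[[m]]$atoms$x, ens$frames[[m]]$atoms$x,
                 tolerance = 1e-3)  # PDB stores 3 decimals
    expect_identical(back$frames[[m]]$resname, ens$frames[[m]]$resname)
  }
  single <- withr::local_tempfile(fileext = ".pdb")
  write_structures(make_ideal_chain(h3_wt, -57, -47), single)
  one <- read_structures(single)
  expect_equal(length(one$frames), 1)
  expect_equal(length(one$frames[[1]]), 10)
})

test_that("roster mismatches and incomplete residues are caught", {
  p1 <- withr::local_tempfile(fileext = ".pdb")
  lines1 <- readLines(write_structures(
    conformer_ensemble(list(make_ideal_chain("ARTKQ", -57, -47),
                            make_ideal_chain("ARTKQ", -57, -47))), p1))
  # corrupt model 2's residue name
  i <- grep("^ATOM", lines1)
  j <- i[i > grep("^MODEL", lines1)[2]][1]
  substr(lines1[j], 18, 20) <- "GLY"
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines1, bad)
  expect_error(read_structures(bad), "roster")

  # drop one backbone atom: residue flagged incomplete with a warning
  lines2 <- readLines(write_structures(make_ideal_chain("ARTKQ", -57, -47),
                                       withr::local_tempfile(fileext = ".pdb")))
  drop <- grep("^ATOM.* O   THR", lines2)[1]
  incomplete <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines2[-drop], incomplete)
  expect_warning(ens <- read_structures(incomplete), "incomplete")
  expect_false(all(ens$frames[[1]]$complete))
})

test_that("conformation classifier separates helical, bent and extended", {
  # crystal-like H3: extended anchor 1-4, helix from 4 onwards
  crystal <- make_ideal_chain(h3_wt,
                              phi = c(rep(-139, 3), rep(-57, 7)),
                              psi = c(rep(135, 3), rep(-47, 7)))
  cls <- classify_conformation(crystal, segment = 4:10, anchor = 1:3)
  expect_equal(cls$class, "helical")
  expect_gte(cls$evidence$longest_helical_run, 3)

  ext <- classify_conformation(make_ideal_chain(h3_wt, -139, 135),
                               segment = 4:10, anchor = 1:3)
  expect_equal(ext$class, "extended")
  expect_gte(ext$evidence$end_to_end_ratio, 0.8)

  # kinked chain: no helical bonds, compact end-to-end ratio
  kink <- make_ideal_chain(h3_wt,
                           phi = c(rep(-139, 4), 80, 80, rep(-139, 4)),
                           psi = c(rep(135, 4), -60, -60, rep(135, 4)))
  bent <- classify_conformation(kink, segment = 1:10)
  expect_equal(bent$class, "bent")
  expect_equal(bent$evidence$segment_hbonds, 0)
  expect_lt(bent$evidence$end_to_end_ratio, 0.8)

  expect_error(classify_conformation(crystal, segment = 4:6), "4 residues")
  expect_error(classify_conformation(crystal, segment = 4:10, anchor = 4:5),
               "disjoint")
})
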