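# DSSP electrostatic hydrogen-bond model constants
HB_COUPLING <- 27.888   # kcal/mol * Angstrom (q1*q2*f)
HB_CUTOFF <- -0.5       # kcal/mol; bond iff E < cutoff
HB_NH <- 1.00           # Angstrom, reconstructed amide H distance from N

# reconstruct amide H positions: H sits 1.0 A from N, with the N-H vector
# anti-parallel to the preceding residue's C=O vector. Residue 1 (no
# preceding carbonyl) and prolines (no amide H) get NA and are ineligible
# donors.
amide_hydrogens <- function(chain) {
  N <- coords(chain, "N")
  C <- coords(chain, "C")
  O <- coords(chain, "O")
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  if (n < 2) return(H)
  for (i in 2:n) {
    if (chain$resname[i] == "PRO") next
    co <- O[i - 1, ] - C[i - 1, ]
    if (anyNA(co) || anyNA(N[i, ])) next
    H[i, ] <- N[i, ] - HB_NH * co / sqrt(sum(co^2))
  }
  H
}

# DSSP electrostatic energy (kcal/mol) of the donor NH (residue j) ->
# acceptor C=O (residue i) interaction
dssp_energy <- function(N_j, H_j, C_i, O_i) {
  r_on <- sqrt(sum((O_i - N_j)^2))
  r_ch <- sqrt(sum((C_i - H_j)^2))
  r_oh <- sqrt(sum((O_i - H_j)^2))
  r_cn <- sqrt(sum((C_i - N_j)^2))
  HB_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Detect intrapeptide hydrogen bonds
#'
#' Backbone-backbone hydrogen bonds are called with the DSSP electrostatic
#' criterion: the amide H is reconstructed geometrically (1.00 Angstrom from
#' N, anti-parallel to the preceding carbonyl C=O vector) and the
#' interaction energy E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)
#' kcal/mol is computed for every donor NH / acceptor C=O pair; a bond is
#' reported when E < -0.5 kcal/mol. Residue 1 and prolines cannot donate.
#' Optionally, sidechain-to-backbone bonds are called with a geometric
#' criterion: donor-acceptor heavy-atom distance and donor angle.
#'
#' @param chain A [peptide_chain()].
#' @param include_sidechain Also search sidechain donor/acceptor heavy atoms
#'   (OG, OG1, OH, NE, NH1, NH2, ND1, NE2, NZ, ND2, SG) against backbone
#'   N/O partners.
#' @param sc_dist_max Heavy-atom distance cutoff (Angstrom) for
#'   sidechain-backbone bonds.
#' @param sc_angle_min Minimum donor angle (degrees), measured at the donor
#'   heavy atom between its bonded parent atom and the acceptor, when the
#'   parent is resolvable; pairs without a resolvable parent are accepted on
#'   distance alone.
#' @return data.frame with columns `donor`, `acceptor` (residue indices),
#'   `donor_atom`, `acceptor_atom`, `energy` (kcal/mol, backbone bonds),
#'   `distance` (Angstrom), `kind`.
#' @export
detect_hbonds <- function(chain, include_sidechain = FALSE,
                          sc_dist_max = 3.5, sc_angle_min = 120) {
  stopifnot(inherits(chain, "peptide_chain"))
  n <- length(chain$resno)
  usable <- which(chain$complete)
  if (length(usable) < 2)
    stop("need at least 2 complete residues")
  N <- coords(chain, "N")
  C <- coords(chain, "C")
  O <- coords(chain, "O")
  H <- amide_hydrogens(chain)

  out <- list()
  for (j in usable) {          # donor residue (NH)
    if (anyNA(H[j, ])) next    # residue 1 / proline / incomplete neighbour
    for (i in usable) {        # acceptor residue (C=O)
      if (i == j || i == j - 1) next  # exclude self and the covalent C-N link
      e <- dssp_energy(N[j, ], H[j, ], C[i, ], O[i, ])
      if (e < HB_CUTOFF) {
        out[[length(out) + 1L]] <- data.frame(
          donor = j, acceptor = i, donor_atom = "N", acceptor_atom = "O",
          energy = e, distance = sqrt(sum((O[i, ] - N[j, ])^2)),
          kind = "backbone-backbone", stringsAsFactors = FALSE)
      }
    }
  }

  if (include_sidechain) {
    sc_donors <- c("OG", "OG1", "OH", "NE", "NH1", "NH2", "ND1", "NE2",
                   "NZ", "ND2", "SG")
    sc <- chain$atoms[chain$atoms$elety %in% sc_donors, , drop = FALSE]
    for (k in seq_len(nrow(sc))) {
      dxyz <- as.numeric(sc[k, c("x", "y", "z")])
      for (i in usable) {
        for (acc in c("O", "N")) {
          axyz <- if (acc == "O") O[i, ] else N[i, ]
          if (anyNA(axyz)) next
          if (sc$resno[k] == i) next
          d <- sqrt(sum((axyz - dxyz)^2))
          if (d > sc_dist_max) next
          # donor angle parent-donor-acceptor, parent = CB when present
          cb <- chain$atoms[chain$atoms$resno == sc$resno[k] &
                              chain$atoms$elety == "CB", , drop = FALSE]
          ok_angle <- TRUE
          if (nrow(cb) == 1) {
            v1 <- as.numeric(cb[1, c("x", "y", "z")]) - dxyz
            v2 <- axyz - dxyz
            ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
            ok_angle <- ang >= sc_angle_min
          }
          if (ok_angle) {
            out[[length(out) + 1L]] <- data.frame(
              donor = sc$resno[k], acceptor = i, donor_atom = sc$elety[k],
              acceptor_atom = acc, energy = NA_real_, distance = d,
              kind = "sidechain-backbone", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  if (!length(out)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      donor_atom = character(), acceptor_atom = character(),
                      energy = numeric(), distance = numeric(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assign per-residue helicity
#'
#' A residue is helical iff it lies inside a minimal helix of turn length
#' n in {3, 4, 5} (3-10, alpha and pi helices): two consecutive n-turns,
#' i.e. backbone hydrogen bonds O(i) -> NH(i+n) present at both i and i+1,
#' mark residues i+1 ... i+n as helical.
#'
#' @param frame A [peptide_chain()].
#' @return Logical vector, one element per residue.
#' @export
assign_helicity <- function(frame) {
  stopifnot(inherits(frame, "peptide_chain"))
  n <- length(frame$resno)
  hel <- rep(FALSE, n)
  if (n < 4 || sum(frame$complete) < 2) return(hel)
  hb <- detect_hbonds(frame)
  hb <- hb[hb$kind == "backbone-backbone", , drop = FALSE]
  for (turn in c(3L, 4L, 5L)) {
    # n-turn at i: acceptor i, donor i+turn
    turn_at <- rep(FALSE, n)
    idx <- hb$donor - hb$acceptor == turn
    turn_at[hb$acceptor[idx]] <- TRUE
    for (i in seq_len(n - 1)) {
      if (turn_at[i] && turn_at[i + 1] && i + turn <= n)
        hel[(i + 1):(i + turn)] <- TRUE
    }
  }
  hel
}
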