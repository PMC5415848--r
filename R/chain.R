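# one-letter -> three-letter residue codes (standard 20)
AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
AA3TO1 <- stats::setNames(names(AA1TO3), AA1TO3)

# ideal backbone geometry (lengths in Angstrom, angles in degrees)
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

#' Construct a peptide chain object
#'
#' A `peptide_chain` holds the backbone (N, CA, C, O) coordinates of one
#' peptide conformation, plus any optional sidechain donor/acceptor atoms.
#' Residue indices are 1-based and contiguous.
#'
#' @param atoms data.frame with columns `resno` (integer), `resname`
#'   (3-letter code), `elety` (atom name), `x`, `y`, `z` (Angstrom).
#' @return An object of class `peptide_chain`.
#' @export
peptide_chain <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resname", "elety", "x", "y", "z") %in% names(atoms)))
  atoms$resno <- as.integer(atoms$resno)
  resno <- sort(unique(atoms$resno))
  if (length(resno) < 1L)
    stop("chain has no residues")
  if (!all(diff(resno) == 1L))
    stop("residue indices must be contiguous")
  if (resno[1] != 1L) {
    # renumber to 1-based contiguity; original numbering is not retained
    atoms$resno <- atoms$resno - resno[1] + 1L
    resno <- resno - resno[1] + 1L
  }
  bb <- c("N", "CA", "C", "O")
  complete <- vapply(resno, function(r) {
    all(bb %in% atoms$elety[atoms$resno == r])
  }, logical(1))
  seq3 <- vapply(resno, function(r) atoms$resname[atoms$resno == r][1], character(1))
  obj <- structure(list(atoms = atoms,
                        resno = resno,
                        resname = seq3,
                        complete = complete),
                   class = "peptide_chain")
  ca <- coords(obj, "CA")
  dca <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
  ok <- stats::complete.cases(ca[-1, , drop = FALSE]) &
    stats::complete.cases(ca[-nrow(ca), , drop = FALSE])
  if (any(ok) && any(dca[ok] < 2.8 | dca[ok] > 4.2))
    warning("bonded CA-CA distance outside [2.8, 4.2] Angstrom")
  obj
}

#' @export
print.peptide_chain <- function(x, ...) {
  cat("peptide_chain:", length(x$resno), "residues (",
    paste(AA3TO1[x$resname], collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' @export
length.peptide_chain <- function(x) length(x$resno)

#' One-letter sequence of a peptide chain
#' @param chain A `peptide_chain`.
#' @return Character scalar.
#' @export
chain_sequence <- function(chain) {
  paste(unname(AA3TO1[chain$resname]), collapse = "")
}

# matrix (n_res x 3) of coordinates for one backbone atom type; NA when absent
coords <- function(chain, elety) {
  out <- matrix(NA_real_, nrow = length(chain$resno), ncol = 3)
  sub <- chain$atoms[chain$atoms$elety == elety, , drop = FALSE]
  out[match(sub$resno, chain$resno), ] <- as.matrix(sub[, c("x", "y", "z")])
  out
}

# place a new atom D from positions A, B, C with bond |CD|, angle B-C-D and
# dihedral A-B-C-D (NeRF construction; angles in degrees)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal-geometry peptide backbone
#'
#' Constructs backbone N/CA/C/O coordinates for a peptide with ideal bond
#' lengths and angles, trans peptide bonds (omega = 180 degrees) and the
#' given backbone dihedrals. With `phi = -57, psi = -47` the result is an
#' ideal alpha-helix; with `phi = -139, psi = 135` an extended (beta) strand.
#'
#' @param sequence One-letter amino-acid string (length >= 2, standard
#'   residues only).
#' @param phi,psi Backbone dihedrals in degrees; scalars are recycled, or
#'   per-residue vectors of the sequence length. `phi[1]` and `psi[n]` affect
#'   only terminal atom placement.
#' @return A [peptide_chain()].
#' @examples
#' helix <- make_ideal_chain("ARTKQTARKS", -57, -47)
#' strand <- make_ideal_chain("ARTKQTARKS", -139, 135)
#' @export
make_ideal_chain <- function(sequence, phi = -57, psi = -47) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n < 2)
    stop("sequence must have at least 2 residues")
  bad <- setdiff(aa, names(AA1TO3))
  if (length(bad))
    stop("unknown residue letter: ", paste(unique(bad), collapse = ", "))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  g <- IDEAL_GEOM

  N <- matrix(NA_real_, n, 3)
  CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  O <- matrix(NA_real_, n, 3)

  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                             g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                              g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                             g$b_ca_c, g$a_n_ca_c, phi[i + 1])
  }
  # carbonyl O: anti to the next amide N (dihedral N-CA-C-O = psi + 180)
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }

  atoms <- data.frame(
    resno = rep(seq_len(n), each = 4L),
    resname = rep(unname(AA1TO3[aa]), each = 4L),
    elety = rep(c("N", "CA", "C", "O"), n),
    x = as.vector(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1]))),
    y = as.vector(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2]))),
    z = as.vector(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3]))),
    stringsAsFactors = FALSE
  )
  peptide_chain(atoms)
}

#' Add a sidechain atom to a chain
#'
#' Utility for constructing test geometries with sidechain hydrogen-bond
#' donors/acceptors (e.g. a Thr OG1 near a downstream amide nitrogen).
#'
#' @param chain A [peptide_chain()].
#' @param resno Residue index carrying the atom.
#' @param elety Atom name (e.g. `"OG1"`).
#' @param xyz Numeric length-3 coordinates (Angstrom).
#' @return The modified `peptide_chain`.
#' @export
add_sidechain_atom <- function(chain, resno, elety, xyz) {
  stopifnot(inherits(chain, "peptide_chain"), length(xyz) == 3)
  row <- data.frame(resno = as.integer(resno),
                    resname = chain$resname[match(resno, chain$resno)],
                    elety = elety, x = xyz[1], y = xyz[2], z = xyz[3],
                    stringsAsFactors = FALSE)
  chain$atoms <- rbind(chain$atoms, row)
  chain
}

# apply a rigid-body transform (3x3 rotation + translation) to all atoms
transform_chain <- function(chain, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  chain$atoms[, c("x", "y", "z")] <- xyz
  chain
}
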