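#' Construct a conformer ensemble
#'
#' @param frames List of [peptide_chain()] objects sharing an identical
#'   residue roster (indices and residue names).
#' @param replica Integer replica id per frame (default all 1).
#' @return Object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(frames, replica = rep(1L, length(frames))) {
  if (!length(frames))
    stop("ensemble needs at least one frame")
  if (length(replica) != length(frames))
    stop("replica ids must match number of frames")
  roster <- lapply(frames, function(f) paste(f$resno, f$resname))
  if (!all(vapply(roster, identical, logical(1), roster[[1]])))
    stop("residue roster differs across frames")
  structure(list(frames = frames, replica = as.integer(replica)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer_ensemble:", length(x$frames), "frames,",
      length(unique(x$replica)), "replica(s),",
      length(x$frames[[1]]$resno), "residues\n")
  invisible(x)
}

# verify that every MODEL block carries the identical atom identity
# (residue number, residue name, atom name) roster
check_model_rosters <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) < 2) return(invisible(TRUE))
  model_of <- findInterval(seq_along(lines), model_starts)
  atom <- grepl("^ATOM|^HETATM", lines)
  ident <- paste(substr(lines, 13, 27))
  rosters <- split(ident[atom], model_of[atom])
  if (!all(vapply(rosters, identical, logical(1), rosters[[1]])))
    stop("residue/atom roster differs across models")
  invisible(TRUE)
}

#' Read peptide structures from a (multi-model) PDB file
#'
#' MODEL records define frames; a file without MODEL records yields a
#' single-frame ensemble. Alternate locations are resolved to the highest
#' occupancy; insertion codes are rejected; residues missing any backbone
#' atom are flagged incomplete (with a warning) and excluded from the
#' hydrogen-bond search.
#'
#' @param path PDB file.
#' @param chain_id Chain identifier to select (default: first chain found).
#' @param replica Optional integer replica id per frame (recycled); defaults
#'   to a single replica.
#' @return A [conformer_ensemble()].
#' @export
read_structures <- function(path, chain_id = NULL, replica = NULL) {
  check_model_rosters(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain_id)) chain_id <- at$chain[1]
  sel <- at$chain == chain_id & at$type == "ATOM"
  if (!any(sel)) stop("no ATOM records for chain ", chain_id)
  if (any(nzchar(trimws(at$insert[sel])) & !is.na(at$insert[sel])))
    stop("insertion codes are not supported")
  # resolve altlocs: keep highest occupancy per (resno, elety)
  sub <- at[sel, , drop = FALSE]
  key <- paste(sub$resno, sub$elety)
  keep <- unlist(lapply(split(seq_len(nrow(sub)), key), function(idx) {
    idx[which.max(sub$o[idx])]
  }), use.names = FALSE)
  keep <- sort(keep)
  sub <- sub[keep, , drop = FALSE]

  nframes <- nrow(pdb$xyz)
  rows <- which(sel)[keep]          # atom rows in full table
  frames <- vector("list", nframes)
  for (m in seq_len(nframes)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(resno = sub$resno, resname = sub$resid,
                        elety = sub$elety,
                        x = xyz[rows, 1], y = xyz[rows, 2], z = xyz[rows, 3],
                        stringsAsFactors = FALSE)
    ch <- peptide_chain(atoms)
    if (!all(ch$complete))
      warning("frame ", m, ": residues with missing backbone atoms flagged ",
              "incomplete: ", paste(which(!ch$complete), collapse = ", "))
    frames[[m]] <- ch
  }
  roster <- lapply(frames, function(f) paste(f$resno, f$resname))
  if (!all(vapply(roster, identical, logical(1), roster[[1]])))
    stop("residue roster differs across models")
  if (is.null(replica)) replica <- rep(1L, nframes)
  conformer_ensemble(frames, rep_len(as.integer(replica), nframes))
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL record per frame, chain A, standard ATOM formatting.
#'
#' @param ensemble A [conformer_ensemble()] (or a single [peptide_chain()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structures <- function(ensemble, path) {
  if (inherits(ensemble, "peptide_chain"))
    ensemble <- conformer_ensemble(list(ensemble))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    at <- ensemble$frames[[m]]$atoms
    serial <- seq_len(nrow(at))
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
      serial,
      ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
      at$resname, "A", at$resno, at$x, at$y, at$z, 1.00, 0.00,
      substr(at$elety, 1, 1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Generate a conformer ensemble with planted per-residue helicity
#'
#' Frames are built from ideal geometry: a frame is either the ideal
#' alpha-helix conformation or the extended (coil stand-in) conformation
#' over each contiguous block of residues sharing the same planted
#' fraction. Frame counts are rounded deterministically
#' (`floor(fraction * n_frames + 0.5)`), not sampled, so zero-noise
#' recovery of the planted fraction is exact; `seed` only drives optional
#' coordinate jitter.
#'
#' @param sequence One-letter peptide sequence.
#' @param helix_fraction Per-residue helical fractions in `[0, 1]` (scalar
#'   recycled to the sequence length).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed for the coordinate jitter stream.
#' @param n_replicas Number of equally sized replicas the frames are split
#'   into (frame order is helical-first within each replica).
#' @param jitter Gaussian coordinate jitter s.d. in Angstrom (>= 0).
#' @return A [conformer_ensemble()].
#' @export
make_ensemble <- function(sequence, helix_fraction, n_frames, seed = 1L,
                          n_replicas = 1L, jitter = 0) {
  nres <- nchar(sequence)
  frac <- rep_len(helix_fraction, nres)
  if (any(frac < 0 | frac > 1))
    stop("helix_fraction must lie in [0, 1]")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (jitter < 0) stop("jitter must be >= 0")
  if (n_frames %% n_replicas != 0)
    stop("n_frames must be divisible by n_replicas")
  per_rep <- n_frames %/% n_replicas

  # contiguous blocks of equal planted fraction
  block <- cumsum(c(TRUE, diff(frac) != 0))
  blocks <- split(seq_len(nres), block)
  helix_phi <- -57; helix_psi <- -47
  ext_phi <- -139; ext_psi <- 135

  rng <- local_rng(seed)
  frames <- vector("list", n_frames)
  replica <- integer(n_frames)
  k <- 0L
  for (r in seq_len(n_replicas)) {
    n_hel_block <- vapply(blocks, function(ix) {
      as.integer(floor(frac[ix[1]] * per_rep + 0.5))
    }, integer(1))
    for (t in seq_len(per_rep)) {
      phi <- rep(ext_phi, nres); psi <- rep(ext_psi, nres)
      for (b in seq_along(blocks)) {
        if (t <= n_hel_block[b]) {
          phi[blocks[[b]]] <- helix_phi
          psi[blocks[[b]]] <- helix_psi
        }
      }
      ch <- make_ideal_chain(sequence, phi, psi)
      if (jitter > 0) {
        nat <- nrow(ch$atoms)
        ch$atoms$x <- ch$atoms$x + rng$rnorm(nat, 0, jitter)
        ch$atoms$y <- ch$atoms$y + rng$rnorm(nat, 0, jitter)
        ch$atoms$z <- ch$atoms$z + rng$rnorm(nat, 0, jitter)
      }
      k <- k + 1L
      frames[[k]] <- ch
      replica[k] <- r
    }
  }
  conformer_ensemble(frames, replica)
}
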