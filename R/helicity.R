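# frame indices retained after discarding the first burn_in_fraction of
# each replica's frames
retained_frames <- function(ensemble, burn_in_fraction) {
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must lie in [0, 1)")
  idx_all <- integer(0)
  for (r in sort(unique(ensemble$replica))) {
    idx <- which(ensemble$replica == r)
    drop <- floor(burn_in_fraction * length(idx))
    idx <- idx[seq_len(length(idx)) > drop]
    if (!length(idx))
      stop("burn-in leaves no frames in replica ", r)
    idx_all <- c(idx_all, idx)
  }
  idx_all
}

#' Per-residue helicity profile of a conformer ensemble
#'
#' For each replica, the first `burn_in_fraction` of frames is discarded
#' (mirroring analysis of only the late part of each trajectory) and the
#' per-residue fraction of retained frames assigned helical
#' ([assign_helicity()]) is computed. The pooled fraction is the
#' frame-weighted mean over all retained frames; the median and
#' interquartile range are taken across per-replica fractions.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param burn_in_fraction Fraction of initial frames discarded per replica
#'   (default 0.25, i.e. keep the last three quarters).
#' @return Object of class `helicity_profile`: a data.frame with columns
#'   `resno`, `fraction` (pooled), `median`, `iqr`, plus a `per_replica`
#'   attribute (replica x residue matrix of fractions).
#' @export
helicity_profile <- function(ensemble, burn_in_fraction = 0.25) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must lie in [0, 1)")
  reps <- sort(unique(ensemble$replica))
  nres <- length(ensemble$frames[[1]]$resno)
  keep_idx <- integer(0)
  per_rep <- matrix(NA_real_, length(reps), nres,
                    dimnames = list(paste0("replica", reps), NULL))
  pooled_counts <- rep(0, nres)
  pooled_n <- 0L
  for (r in seq_along(reps)) {
    idx <- which(ensemble$replica == reps[r])
    drop <- floor(burn_in_fraction * length(idx))
    idx <- idx[seq_len(length(idx)) > drop]
    if (!length(idx))
      stop("burn-in leaves no frames in replica ", reps[r])
    hel <- vapply(ensemble$frames[idx], assign_helicity, logical(nres))
    per_rep[r, ] <- rowMeans(hel)
    pooled_counts <- pooled_counts + rowSums(hel)
    pooled_n <- pooled_n + length(idx)
    keep_idx <- c(keep_idx, idx)
  }
  out <- data.frame(
    resno = ensemble$frames[[1]]$resno,
    fraction = pooled_counts / pooled_n,
    median = apply(per_rep, 2, stats::median),
    iqr = apply(per_rep, 2, stats::IQR)
  )
  attr(out, "per_replica") <- per_rep
  attr(out, "retained_frames") <- keep_idx
  class(out) <- c("helicity_profile", "data.frame")
  out
}

#' Compare per-residue helicity between two groups of replicas
#'
#' Two-tailed Mann-Whitney U test per residue: exact when both groups have
#' at most 8 replicas and there are no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param a,b Numeric matrices (replica x residue) of per-replica helical
#'   fractions, e.g. the `per_replica` attribute of [helicity_profile()],
#'   or plain vectors for a single residue.
#' @return data.frame with columns `resno`, `U` (statistic for group `a`)
#'   and `p_value`.
#' @export
compare_helicity <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 replicas per group")
  if (ncol(a) != ncol(b))
    stop("groups must cover the same residues")
  res <- lapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    exact <- min(length(x), length(y)) <= 8 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    data.frame(resno = j, U = unname(wt$statistic), p_value = wt$p.value)
  })
  do.call(rbind, res)
}

#' Hydrogen-bond contact occupancy map of an ensemble
#'
#' For every donor/acceptor residue pair, the fraction of retained frames
#' (after per-replica burn-in) in which a backbone-backbone hydrogen bond
#' is present.
#'
#' @inheritParams helicity_profile
#' @return data.frame with columns `donor`, `acceptor`, `occupancy`,
#'   containing only pairs observed at least once; also carries an
#'   `n_frames` attribute.
#' @export
hbond_contact_map <- function(ensemble, burn_in_fraction = 0.25) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  idx <- retained_frames(ensemble, burn_in_fraction)
  counts <- new.env(parent = emptyenv())
  for (m in idx) {
    hb <- detect_hbonds(ensemble$frames[[m]])
    hb <- hb[hb$kind == "backbone-backbone", , drop = FALSE]
    for (k in seq_len(nrow(hb))) {
      key <- paste(hb$donor[k], hb$acceptor[k])
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    out <- data.frame(donor = integer(), acceptor = integer(),
                      occupancy = numeric())
  } else {
    parts <- do.call(rbind, strsplit(keys, " "))
    out <- data.frame(donor = as.integer(parts[, 1]),
                      acceptor = as.integer(parts[, 2]),
                      occupancy = vapply(keys, function(k) counts[[k]],
                                         numeric(1)) / length(idx))
    out <- out[order(out$donor, out$acceptor), ]
    rownames(out) <- NULL
  }
  attr(out, "n_frames") <- length(idx)
  out
}

#' Classify the conformation of a bound peptide segment
#'
#' Assigns one of three classes to a peptide segment (typically the part of
#' the histone H3 tail after the anchoring N-terminal residues): `helical`
#' if at least three consecutive segment residues are assigned helical (one
#' complete turn), `extended` if the segment has no backbone hydrogen bonds
#' with sequence separation >= 3 and its end-to-end / contour-length ratio
#' is >= 0.8, and `bent` otherwise.
#'
#' @param chain A [peptide_chain()].
#' @param segment Integer residue range to classify (length >= 4).
#' @param anchor Integer residue range of the anchoring region; must be
#'   disjoint from `segment` (recorded as evidence only).
#' @return Object of class `conformation_class`: list with `class` and an
#'   `evidence` list (helical residue count, longest helical run,
#'   intrapeptide backbone H-bond count in the segment, end-to-end /
#'   contour ratio).
#' @export
classify_conformation <- function(chain, segment, anchor = integer(0)) {
  stopifnot(inherits(chain, "peptide_chain"))
  segment <- sort(as.integer(segment))
  if (length(segment) < 4)
    stop("segment must contain at least 4 residues")
  if (!all(segment %in% chain$resno))
    stop("segment outside chain")
  if (length(intersect(segment, anchor)))
    stop("anchor must be disjoint from segment")

  hel <- assign_helicity(chain)[segment]
  runs <- rle(hel)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  hb <- detect_hbonds(chain)
  hb <- hb[hb$kind == "backbone-backbone" &
             hb$donor %in% segment & hb$acceptor %in% segment &
             abs(hb$donor - hb$acceptor) >= 3, , drop = FALSE]
  ca <- coords(chain, "CA")[segment, , drop = FALSE]
  e2e <- sqrt(sum((ca[nrow(ca), ] - ca[1, ])^2))
  contour <- sum(sqrt(rowSums((ca[-1, , drop = FALSE] -
                                 ca[-nrow(ca), , drop = FALSE])^2)))
  ratio <- e2e / contour

  cls <- if (longest >= 3) "helical"
  else if (nrow(hb) == 0 && ratio >= 0.8) "extended"
  else "bent"
  structure(list(class = cls,
                 evidence = list(helical_residues = sum(hel),
                                 longest_helical_run = longest,
                                 segment_hbonds = nrow(hb),
                                 end_to_end_ratio = ratio)),
            class = "conformation_class")
}

#' @export
print.conformation_class <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf(
    "conformation: %s (helical residues %d, longest run %d, segment H-bonds %d, e2e/contour %.2f)\n",
    x$class, ev$helical_residues, ev$longest_helical_run,
    ev$segment_hbonds, ev$end_to_end_ratio))
  invisible(x)
}
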