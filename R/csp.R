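CSP_N_WEIGHT <- 0.14  # 15N scaling factor relative to 1H shift range

#' Construct an NMR peak list
#'
#' @param residue Integer residue ids (unique among assigned backbone
#'   entries).
#' @param dH,dN Amide 1H and 15N chemical shifts (ppm).
#' @param label Optional residue labels.
#' @param sidechain Logical: member of a sidechain NH2 pair (excluded from
#'   CSP statistics).
#' @param assigned Logical: peak assigned to a residue.
#' @return data.frame of class `peak_list`.
#' @export
peak_list <- function(residue, dH, dN, label = NA_character_,
                      sidechain = FALSE, assigned = TRUE) {
  out <- data.frame(residue = as.integer(residue), label = label,
                    dH = as.numeric(dH), dN = as.numeric(dN),
                    sidechain = sidechain, assigned = assigned,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$dH)) || any(!is.finite(out$dN)))
    stop("non-finite chemical shift")
  dup <- duplicated(out$residue[out$assigned & !out$sidechain])
  if (any(dup))
    stop("duplicate assigned residue id: ",
         out$residue[out$assigned & !out$sidechain][dup][1])
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Weighted chemical shift difference
#'
#' `|dH| + 0.14 * |dN|` where 0.14 rescales the wider 15N shift range on to
#' the amide-proton range.
#'
#' @param delta_h,delta_n Shift differences (ppm).
#' @return Weighted shift difference (ppm).
#' @export
weighted_shift <- function(delta_h, delta_n) {
  abs(delta_h) + CSP_N_WEIGHT * abs(delta_n)
}

#' Chemical-shift-perturbation table from assigned free/bound peak lists
#'
#' Matches peaks by residue id over the union of residues in both lists and
#' computes per-residue shift differences and the weighted combined shift.
#' Sidechain NH2 entries are excluded from statistics; residues present in
#' only one list carry a missing status.
#'
#' @param free,bound [peak_list()] objects.
#' @return data.frame of class `csp_table` with columns `residue`,
#'   `delta_h`, `delta_n`, `delta_weighted`, `status` (one of `measured`,
#'   `missing-in-free`, `missing-in-bound`, `excluded-sidechain`).
#' @export
weighted_csp <- function(free, bound) {
  if (!nrow(free) || !nrow(bound)) stop("empty peak list")
  fb <- free[free$assigned & !free$sidechain, , drop = FALSE]
  bb <- bound[bound$assigned & !bound$sidechain, , drop = FALSE]
  if (anyDuplicated(fb$residue)) stop("duplicate assigned residue id in free list")
  if (anyDuplicated(bb$residue)) stop("duplicate assigned residue id in bound list")
  residues <- sort(union(fb$residue, bb$residue))
  fi <- match(residues, fb$residue)
  bi <- match(residues, bb$residue)
  dh <- bb$dH[bi] - fb$dH[fi]
  dn <- bb$dN[bi] - fb$dN[fi]
  status <- ifelse(is.na(fi), "missing-in-free",
                   ifelse(is.na(bi), "missing-in-bound", "measured"))
  out <- data.frame(residue = residues, delta_h = dh, delta_n = dn,
                    delta_weighted = weighted_shift(dh, dn),
                    status = status, stringsAsFactors = FALSE)
  sc <- sort(unique(c(free$residue[free$sidechain], bound$residue[bound$sidechain])))
  sc <- setdiff(sc, residues)
  if (length(sc)) {
    out <- rbind(out, data.frame(residue = sc, delta_h = NA_real_,
                                 delta_n = NA_real_, delta_weighted = NA_real_,
                                 status = "excluded-sidechain",
                                 stringsAsFactors = FALSE))
    out <- out[order(out$residue), ]
    rownames(out) <- NULL
  }
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Classify CSPs into none/weak/medium/strong
#'
#' Thresholds are the mean, mean + 1 s.d. and mean + 2 s.d. of the weighted
#' shifts over measured residues (sample standard deviation, n - 1).
#' Comparisons are inclusive ("equal or above"): weak >= mu,
#' medium >= mu + sigma, strong >= mu + 2 sigma.
#'
#' @param table A `csp_table` from [weighted_csp()] or [minimal_shift()].
#' @return Object of class `csp_classification`: the table with a `class`
#'   column added, plus `thresholds` attribute `c(mu, mu_sigma, mu_2sigma)`.
#' @export
classify_csp <- function(table) {
  measured <- table$status == "measured"
  vals <- table$delta_weighted[measured]
  if (length(vals) < 2)
    stop("need >= 2 measured residues to form thresholds")
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  thr <- c(mu = mu, mu_sigma = mu + sdv, mu_2sigma = mu + 2 * sdv)
  cls <- rep(NA_character_, nrow(table))
  v <- table$delta_weighted
  cls[measured] <- ifelse(v[measured] >= thr[3], "strong",
                          ifelse(v[measured] >= thr[2], "medium",
                                 ifelse(v[measured] >= thr[1], "weak", "none")))
  out <- table
  out$class <- cls
  attr(out, "thresholds") <- thr
  attr(out, "sd_type") <- "sample (n-1)"
  class(out) <- c("csp_classification", class(table))
  out
}

#' Minimal-shift CSP estimate from an unassigned bound spectrum
#'
#' For slow-exchange titrations where bound-state assignments are not
#' transferable, each assigned free-state peak is paired with the nearest
#' bound-state peak under the weighted metric
#' `sqrt(delta_h^2 + (0.14 * delta_n)^2)`; the resulting shift differences
#' are combined as in [weighted_csp()]. Many free peaks may map to one
#' bound peak. Ties are broken towards the smaller bound dH, then smaller
#' dN, and flagged.
#'
#' @param free Assigned [peak_list()].
#' @param bound_peaks Unassigned bound-state peak set: data.frame with
#'   columns `dH`, `dN` (a `peak_list` works; assignments are ignored).
#' @return `csp_table` with additional columns `matched_dH`, `matched_dN`,
#'   `tie`.
#' @export
minimal_shift <- function(free, bound_peaks) {
  if (!nrow(bound_peaks)) stop("empty bound peak set")
  fb <- free[free$assigned & !free$sidechain, , drop = FALSE]
  if (!nrow(fb)) stop("no assigned free peaks")
  res <- lapply(seq_len(nrow(fb)), function(i) {
    dh <- bound_peaks$dH - fb$dH[i]
    dn <- bound_peaks$dN - fb$dN[i]
    d <- sqrt(dh^2 + (CSP_N_WEIGHT * dn)^2)
    hit <- which(d <= min(d) + 1e-9)   # tolerance absorbs ppm round-off
    tie <- length(hit) > 1
    if (tie)  # deterministic: smaller bound dH, then smaller bound dN
      hit <- hit[order(bound_peaks$dH[hit], bound_peaks$dN[hit])]
    j <- hit[1]
    data.frame(residue = fb$residue[i], delta_h = dh[j], delta_n = dn[j],
               delta_weighted = weighted_shift(dh[j], dn[j]),
               status = "measured", matched_dH = bound_peaks$dH[j],
               matched_dN = bound_peaks$dN[j], tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Export a per-residue CSP color map
#'
#' Writes (and returns) a residue/class/color table suitable for driving a
#' molecular-graphics colorer: none = white, weak = yellow, medium =
#' orange, strong = red.
#'
#' @param classification A `csp_classification`.
#' @param roster Integer residue ids present in the structure; classified
#'   residues absent from it trigger a warning (rows are still emitted).
#' @param path Optional CSV output path.
#' @return data.frame with columns `residue`, `class`, `color`.
#' @export
export_csp_map <- function(classification, roster, path = NULL) {
  colmap <- c(none = "white", weak = "yellow", medium = "orange",
              strong = "red")
  cl <- classification[classification$status == "measured", , drop = FALSE]
  missing <- setdiff(cl$residue, roster)
  if (length(missing))
    warning("classified residues absent from roster: ",
            paste(missing, collapse = ", "))
  out <- data.frame(residue = cl$residue, class = cl$class,
                    color = unname(colmap[cl$class]),
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Generate synthetic free/bound HSQC peak lists with planted shifts
#'
#' Free-state peaks are laid out deterministically across typical amide
#' ranges (1H 7.5-9.5 ppm, 15N 105-130 ppm); the bound list is the free
#' list plus the planted per-residue offsets plus seeded Gaussian jitter.
#'
#' @param n_residues Number of backbone residues.
#' @param shifted Named list mapping residue id (as character) to
#'   `c(delta_h, delta_n)` offsets in ppm, e.g.
#'   `list("7" = c(0.10, 0.50))`.
#' @param jitter Gaussian jitter s.d. (ppm) applied to bound peak positions
#'   (same value on both axes; >= 0).
#' @param seed Integer seed.
#' @param n_sidechain Number of sidechain NH2 pairs appended (flagged).
#' @return List with elements `free` and `bound` ([peak_list()] objects).
#' @export
make_peak_lists <- function(n_residues, shifted = list(), jitter = 0,
                            seed = 1L, n_sidechain = 0L) {
  if (jitter < 0) stop("jitter must be >= 0")
  ids <- suppressWarnings(as.integer(names(shifted)))
  if (length(shifted)) {
    if (anyNA(ids)) stop("shifted names must be residue ids")
    if (anyDuplicated(ids)) stop("duplicate residue id in shifted set")
    if (any(ids < 1 | ids > n_residues)) stop("shifted ids outside residues")
  }
  rng <- local_rng(seed)
  res <- seq_len(n_residues)
  # deterministic comb layout over the amide region
  dH <- 7.5 + 2.0 * ((res * 7L) %% n_residues) / max(n_residues - 1L, 1L)
  dN <- 105 + 25 * ((res * 3L) %% n_residues) / max(n_residues - 1L, 1L)
  free <- peak_list(res, round(dH, 3), round(dN, 3))
  bdH <- free$dH
  bdN <- free$dN
  for (k in seq_along(shifted)) {
    i <- match(ids[k], res)
    bdH[i] <- bdH[i] + shifted[[k]][1]
    bdN[i] <- bdN[i] + shifted[[k]][2]
  }
  if (jitter > 0) {
    bdH <- bdH + rng$rnorm(n_residues, 0, jitter)
    bdN <- bdN + rng$rnorm(n_residues, 0, jitter)
  }
  bound <- peak_list(res, bdH, bdN)
  if (n_sidechain > 0) {
    scres <- n_residues + seq_len(n_sidechain)
    sc <- function() peak_list(rep(scres, each = 2),
                                   rep(6.8 + 0.1 * seq_len(n_sidechain), each = 2) +
                                     c(0, 0.4),
                                   rep(112 + seq_len(n_sidechain), each = 2),
                                   sidechain = TRUE)
    free <- rbind(free, sc()); class(free) <- c("peak_list", "data.frame")
    bound <- rbind(bound, sc()); class(bound) <- c("peak_list", "data.frame")
  }
  list(free = free, bound = bound)
}

#' Read / write peak-list CSV files
#'
#' Columns: `residue, label, dH_ppm, dN_ppm, sidechain, assigned`; ppm
#' values stored to 3 decimals.
#'
#' @param path CSV file.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  peak_list(df$residue, df$dH_ppm, df$dN_ppm, label = df$label,
            sidechain = as.logical(df$sidechain),
            assigned = as.logical(df$assigned))
}

#' @rdname read_peak_list
#' @param peaks A [peak_list()].
#' @export
write_peak_list <- function(peaks, path) {
  df <- data.frame(residue = peaks$residue, label = peaks$label,
                   dH_ppm = sprintf("%.3f", peaks$dH),
                   dN_ppm = sprintf("%.3f", peaks$dN),
                   sidechain = peaks$sidechain, assigned = peaks$assigned)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
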