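#' Load a helix-propensity scale
#'
#' Reads a flat `residue<TAB>value` config file of per-residue helix
#' propensities (ddG in kcal/mol relative to alanine; lower = more
#' helix-favoring). The packaged default is the experimental consensus
#' scale of Pace & Scholtz (Biophys J 1998), on which Ala is the 0
#' reference and Gly (1.0) is the least helix-favoring residue after Pro.
#'
#' @param path Scale file; default: the packaged scale.
#' @return Named numeric vector over the 20 standard residues, with a
#'   `scale_name` attribute.
#' @export
load_propensity_scale <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "helix_propensity_pace_scholtz.tsv",
                        package = "helixread", mustWork = TRUE)
  lines <- readLines(path)
  name <- sub("^#\\s*", "", grep("^#", lines, value = TRUE)[1])
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- do.call(rbind, strsplit(lines, "\t"))
  scale <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  missing <- setdiff(names(AA1TO3), names(scale))
  if (length(missing))
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  if (scale[["A"]] != 0) stop("scale must use Ala = 0 reference")
  if (scale[["G"]] <= 0) stop("scale must have Gly > 0")
  attr(scale, "scale_name") <- name
  scale
}

#' Helix-propensity score of a peptide window
#'
#' Sum of per-residue scale values over the window; lower totals indicate a
#' more helix-favoring sequence. This is an ordinal score, not a
#' helix-content prediction.
#'
#' @param sequence One-letter peptide sequence.
#' @param window Integer positions to score (default: residues 3-8, the
#'   observed helical segment of the H3 10-mer).
#' @param scale Propensity scale from [load_propensity_scale()].
#' @return Total ddG (kcal/mol).
#' @export
score_peptide <- function(sequence, window = 3:8,
                          scale = load_propensity_scale()) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (any(window < 1 | window > length(aa)))
    stop("window outside sequence")
  sub <- aa[window]
  bad <- setdiff(sub, names(scale))
  if (length(bad))
    stop("residue not in scale: ", paste(unique(bad), collapse = ", "))
  sum(scale[sub])
}

#' Rank peptide variants by helix propensity
#'
#' @param sequences Character vector (optionally named) of peptide
#'   variants.
#' @param window Integer positions to score on each sequence.
#' @param scale Propensity scale.
#' @return data.frame ordered by ascending score (most helix-favoring
#'   first) with columns `sequence`, `score`, `rank`, `tie`.
#' @export
rank_variants <- function(sequences, window = 3:8,
                          scale = load_propensity_scale()) {
  if (!length(sequences)) stop("no sequences to rank")
  scores <- vapply(sequences, score_peptide, numeric(1),
                   window = window, scale = scale)
  ord <- order(scores)
  out <- data.frame(sequence = unname(sequences[ord]),
                    score = unname(scores[ord]),
                    rank = rank(scores)[ord],
                    stringsAsFactors = FALSE)
  out$tie <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
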