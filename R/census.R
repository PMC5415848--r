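MSA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of unique row ids.
#' @param seqs Character vector of aligned sequences (equal length, symbols
#'   restricted to the 20 amino acids and the gap `-`).
#' @return Object of class `phd_msa`.
#' @export
phd_msa <- function(ids, seqs) {
  ids <- unname(ids)
  seqs <- toupper(unname(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(ids) != length(seqs)) stop("ids and sequences differ in length")
  if (anyDuplicated(ids)) stop("duplicate row ids")
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("rows of unequal length (ragged alignment)")
  for (i in seq_along(seqs)) {
    sym <- strsplit(seqs[i], "")[[1]]
    bad <- which(!sym %in% MSA_ALPHABET)
    if (length(bad))
      stop("illegal symbol '", sym[bad[1]], "' in row ", ids[i],
           " column ", bad[1])
  }
  structure(list(ids = as.character(ids), seqs = seqs, width = w),
            class = "phd_msa")
}

#' @export
print.phd_msa <- function(x, ...) {
  cat("phd_msa:", length(x$ids), "sequences, alignment length", x$width, "\n")
  invisible(x)
}

#' Read a multiple sequence alignment (aligned FASTA or Clustal)
#'
#' The format is sniffed from the file content: a `CLUSTAL` header selects
#' the Clustal dialect, otherwise aligned FASTA is assumed. Lowercase is
#' normalized to uppercase and `.` gaps to `-`.
#'
#' @param path Alignment file.
#' @return A [phd_msa()].
#' @export
read_alignment <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    aln <- as.character(Biostrings::readAAMultipleAlignment(path,
                                                            format = "clustal"))
    phd_msa(names(aln), aln)
  } else {
    ss <- Biostrings::readBStringSet(path)
    phd_msa(sub("\\s.*$", "", names(ss)), as.character(ss))
  }
}

#' Write an alignment as aligned FASTA
#' @param msa A [phd_msa()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "phd_msa"))
  writeLines(as.vector(rbind(paste0(">", msa$ids), msa$seqs)), path)
  invisible(path)
}

#' Map a reference residue number to an alignment column
#'
#' Resolves, e.g., "the position corresponding to E1689 of BAZ2A" to a
#' 1-based alignment column: the column in which the reference row's
#' ungapped residue with that construct number sits.
#'
#' @param msa A [phd_msa()].
#' @param ref_id Id of the reference row.
#' @param target Residue number (construct numbering) to resolve.
#' @param ref_start Construct number of the reference row's first residue.
#' @return List with `column` (1-based) and `residue` (the reference row's
#'   residue there, for a sanity check).
#' @export
map_reference_position <- function(msa, ref_id, target, ref_start = 1L) {
  stopifnot(inherits(msa, "phd_msa"))
  row <- match(ref_id, msa$ids)
  if (is.na(row)) stop("reference row '", ref_id, "' not in alignment")
  sym <- strsplit(msa$seqs[row], "")[[1]]
  res_cols <- which(sym != "-")
  if (!length(res_cols)) stop("reference row is gap-only")
  pos <- target - ref_start + 1L
  if (pos < 1L || pos > length(res_cols))
    stop("target residue ", target, " outside reference construct range ",
         ref_start, "-", ref_start + length(res_cols) - 1L)
  col <- res_cols[pos]
  list(column = col, residue = sym[col])
}

#' Detect a double acidic patch around the acidic-wall position
#'
#' TRUE iff the residue at the wall position is Asp/Glu and at least one of
#' its sequence neighbours (ungapped positions wall - 1, wall + 1) is also
#' Asp/Glu; adjacency is sequence adjacency, not alignment adjacency.
#'
#' @param sequence Ungapped one-letter sequence.
#' @param wall_position 1-based position of the acidic wall in `sequence`.
#' @return Logical scalar.
#' @export
detect_double_patch <- function(sequence, wall_position) {
  sym <- strsplit(toupper(sequence), "")[[1]]
  if (wall_position < 1 || wall_position > length(sym))
    stop("wall position outside sequence")
  acidic <- c("D", "E")
  if (!sym[wall_position] %in% acidic) return(FALSE)
  nb <- c(wall_position - 1L, wall_position + 1L)
  nb <- nb[nb >= 1L & nb <= length(sym)]
  any(sym[nb] %in% acidic)
}

#' Classify alignment rows by acidic wall, reader Trp and double patch
#'
#' For each row: `has_acidic_wall` iff the residue in the wall column is
#' Asp/Glu; `has_trp` iff the residue in the Trp column is Trp; a gap in a
#' diagnostic column scores as absent. `has_double_patch` applies
#' [detect_double_patch()] on the ungapped sequence at the wall position.
#'
#' @param msa A [phd_msa()].
#' @param wall_col,trp_col 1-based alignment columns (distinct).
#' @return data.frame with columns `id`, `wall_residue`, `trp_residue`,
#'   `has_acidic_wall`, `has_trp`, `has_double_patch` and `category`
#'   (one of `wall-only`, `trp-only`, `both`, `neither`).
#' @export
classify_rows <- function(msa, wall_col, trp_col) {
  stopifnot(inherits(msa, "phd_msa"))
  if (wall_col == trp_col) stop("wall and Trp columns must differ")
  if (wall_col < 1 || wall_col > msa$width || trp_col < 1 || trp_col > msa$width)
    stop("diagnostic column outside alignment")
  out <- lapply(seq_along(msa$ids), function(i) {
    sym <- strsplit(msa$seqs[i], "")[[1]]
    wall <- sym[wall_col]
    trp <- sym[trp_col]
    has_wall <- wall %in% c("D", "E")
    has_trp <- trp == "W"
    dp <- FALSE
    if (has_wall) {
      ungapped <- sym[sym != "-"]
      wall_pos <- sum(sym[seq_len(wall_col)] != "-")
      dp <- detect_double_patch(paste(ungapped, collapse = ""), wall_pos)
    }
    data.frame(id = msa$ids[i], wall_residue = wall, trp_residue = trp,
               has_acidic_wall = has_wall, has_trp = has_trp,
               has_double_patch = dp,
               category = if (has_wall && has_trp) "both"
               else if (has_wall) "wall-only"
               else if (has_trp) "trp-only" else "neither",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize an acidic-wall census
#'
#' @param classifications Output of [classify_rows()].
#' @return Object of class `census_summary`: list with counts `n_total`,
#'   `n_acidic_wall`, `n_trp`, `n_both`, `n_double_patch` and a 2x2
#'   `table` of wall x Trp membership.
#' @export
census_summary <- function(classifications) {
  if (!nrow(classifications)) stop("no classifications")
  cl <- classifications
  tab <- table(wall = factor(cl$has_acidic_wall, c(FALSE, TRUE)),
               trp = factor(cl$has_trp, c(FALSE, TRUE)))
  structure(list(n_total = nrow(cl),
                 n_acidic_wall = sum(cl$has_acidic_wall),
                 n_trp = sum(cl$has_trp),
                 n_both = sum(cl$has_acidic_wall & cl$has_trp),
                 n_double_patch = sum(cl$has_double_patch),
                 table = tab),
            class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  cat(sprintf(
    "census: %d sequences | acidic wall %d | reader Trp %d | both %d | double patch %d\n",
    x$n_total, x$n_acidic_wall, x$n_trp, x$n_both, x$n_double_patch))
  print(x$table)
  invisible(x)
}

#' Generate a synthetic alignment with planted census structure
#'
#' Produces an ungapped alignment in which designated rows carry an acidic
#' residue at the wall column, a Trp at the Trp column, and (for the
#' double-patch rows, which must be wall rows) an acidic residue at the
#' column just before the wall. All remaining cells are random residues
#' drawn from the 17 letters that are not D/E/W, so planted counts are
#' recovered exactly. A reference row (id `"BAZ2A_ref"`, construct
#' numbering from `ref_start`) carrying the acidic wall is always appended,
#' emulating the numbering anchor used to resolve the wall column.
#'
#' @param n_sequences Number of (non-reference) rows.
#' @param wall_set,trp_set,double_patch_set Integer sets of row indices in
#'   `1:n_sequences`; `double_patch_set` must be a subset of `wall_set`.
#' @param length Alignment length (>= 3).
#' @param seed Integer seed.
#' @param wall_col,trp_col Designated diagnostic columns (distinct, within
#'   `length`, `wall_col >= 2`).
#' @param ref_start Construct number of the reference row's first residue.
#' @return A [phd_msa()] with attributes `wall_col`, `trp_col`, `ref_id`,
#'   `ref_start`.
#' @export
make_msa <- function(n_sequences, wall_set = integer(0), trp_set = integer(0),
                     double_patch_set = integer(0), length = 60L, seed = 1L,
                     wall_col = 10L, trp_col = 25L, ref_start = 1680L) {
  if (length < 3) stop("alignment length must be >= 3")
  if (wall_col == trp_col) stop("wall and Trp columns must differ")
  if (wall_col < 2 || wall_col > length || trp_col < 1 || trp_col > length)
    stop("diagnostic columns outside alignment")
  sets <- list(wall_set, trp_set, double_patch_set)
  if (any(unlist(sets) < 1 | unlist(sets) > n_sequences))
    stop("planted sets must be subsets of 1:n_sequences")
  if (!all(double_patch_set %in% wall_set))
    stop("double_patch_set must be a subset of wall_set")
  rng <- local_rng(seed)
  filler <- setdiff(names(AA1TO3), c("D", "E", "W"))
  rows <- vapply(seq_len(n_sequences), function(i) {
    sym <- rng$sample(filler, length, replace = TRUE)
    if (i %in% wall_set)
      sym[wall_col] <- rng$sample(c("D", "E"), 1)
    if (i %in% trp_set)
      sym[trp_col] <- "W"
    if (i %in% double_patch_set)
      sym[wall_col - 1L] <- rng$sample(c("D", "E"), 1)
    paste(sym, collapse = "")
  }, character(1))
  ref <- rng$sample(filler, length, replace = TRUE)
  ref[wall_col] <- "E"
  ref[wall_col - 1L] <- "D"   # reference carries the double patch
  msa <- phd_msa(c(paste0("seq", seq_len(n_sequences)), "BAZ2A_ref"),
                 c(rows, paste(ref, collapse = "")))
  attr(msa, "wall_col") <- wall_col
  attr(msa, "trp_col") <- trp_col
  attr(msa, "ref_id") <- "BAZ2A_ref"
  attr(msa, "ref_start") <- ref_start
  msa
}
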