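# Per-column conservation profiles and wildcard motif discovery.
#
# A motif such as FGxGT is called from an alignment as a run of columns in
# which the modal residue is (nearly) fixed, with at most a configured
# number of variable ("wildcard", rendered 'x') columns. Candidate motifs
# are then filtered against excluded structural spans (CDR1/2/3, aCPM).

#' Per-column conservation profile of an alignment
#'
#' For every alignment column: the residue frequency table over non-gap
#' symbols (summing to 1), the modal residue (lexicographically smallest
#' among ties, for determinism), its frequency, and the gap fraction
#' (computed over all rows). All-gap columns are flagged and carry an
#' undefined (`NA`) modal residue with gap fraction 1.
#'
#' @param aln An `aligned_set` from [align_sequences()].
#' @return A `conservation_profile`: data.frame with 0-based `column`,
#'   `modal_residue`, `modal_freq`, `gap_fraction`, `all_gap`; the full
#'   residue frequency matrix (residues x columns) is in
#'   `attr(, "frequencies")`.
#' @export
conservation_profile <- function(aln) {
  M <- alignment_matrix(aln)
  if (nrow(M) == 0L) stop("empty alignment", call. = FALSE)
  res <- setdiff(AA_ALPHABET, "X")
  res <- c(res, "X")
  freq <- matrix(0, length(res), ncol(M), dimnames = list(res, NULL))
  modal <- character(ncol(M)); mfreq <- numeric(ncol(M))
  gapf <- numeric(ncol(M)); allgap <- logical(ncol(M))
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    gapf[j] <- mean(col == "-")
    col <- col[col != "-"]
    if (length(col) == 0L) {
      allgap[j] <- TRUE; modal[j] <- NA_character_; mfreq[j] <- NA_real_
      next
    }
    tab <- tabulate(match(col, res), length(res)) / length(col)
    freq[, j] <- tab
    top <- which(tab == max(tab))
    modal[j] <- res[top[1L]]  # residues sorted, so first tie wins
    mfreq[j] <- tab[top[1L]]
  }
  out <- data.frame(column = seq_len(ncol(M)) - 1L, modal_residue = modal,
                    modal_freq = mfreq, gap_fraction = gapf,
                    all_gap = allgap, stringsAsFactors = FALSE)
  attr(out, "frequencies") <- freq
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Export a conservation profile as TSV
#' @param profile A `conservation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Discover conserved wildcard motifs
#'
#' Slides a window of length `k` across the alignment columns. A column is
#' *conserved* when its modal frequency is at least `min_conservation` and
#' its gap fraction is at most `max_gap_fraction`; a column with tolerable
#' gaps but modal frequency below threshold is a *wildcard*. A window
#' qualifies when every column is gap-tolerable and at most
#' `max_wildcards` columns are wildcards. Overlapping qualifying windows
#' are merged into maximal runs; leading and trailing wildcards are
#' trimmed from the merged pattern.
#'
#' @param profile A [conservation_profile()].
#' @param k Window length (default 5, the FGxGT / WYxQ shape).
#' @param min_conservation Modal-frequency threshold for a conserved
#'   column (default 0.85).
#' @param max_wildcards Maximum wildcard columns per window (default 1).
#' @param max_gap_fraction Columns with a larger gap fraction disqualify
#'   any window containing them (default 0.5: the motif must exist in most
#'   germlines).
#' @return List of `motif_pattern` objects: `pattern` (string with `x`
#'   wildcards), `start_column` (0-based alignment column),
#'   `conservation` (per-position modal frequency), `wildcards`
#'   (0-based positions within the pattern).
#' @export
find_conserved_motifs <- function(profile, k = 5, min_conservation = 0.85,
                                  max_wildcards = 1,
                                  max_gap_fraction = 0.5) {
  ncols <- nrow(profile)
  if (k > ncols) stop("window length k exceeds alignment length",
                      call. = FALSE)
  ok_gap <- !profile$all_gap & profile$gap_fraction <= max_gap_fraction
  conserved <- ok_gap & profile$modal_freq >= min_conservation
  wildcard <- ok_gap & !conserved
  qual <- logical(ncols - k + 1L)
  for (s in seq_len(ncols - k + 1L)) {
    idx <- s:(s + k - 1L)
    qual[s] <- all(ok_gap[idx]) && sum(wildcard[idx]) <= max_wildcards
  }
  if (!any(qual)) return(list())
  # merge overlapping qualifying windows into maximal runs of columns
  covered <- logical(ncols)
  for (s in which(qual)) covered[s:(s + k - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- list()
  for (ri in runs) {
    idx <- starts[ri]:ends[ri]
    # trim leading/trailing wildcards
    while (length(idx) && wildcard[idx[1L]]) idx <- idx[-1L]
    while (length(idx) && wildcard[idx[length(idx)]])
      idx <- idx[-length(idx)]
    if (length(idx) < 3L) next
    pat <- ifelse(conserved[idx], profile$modal_residue[idx], "x")
    out[[length(out) + 1L]] <- structure(
      list(pattern = paste(pat, collapse = ""),
           start_column = profile$column[idx[1L]],
           conservation = profile$modal_freq[idx],
           wildcards = which(pat == "x") - 1L,
           criteria = c(conserved = TRUE)),
      class = "motif_pattern")
  }
  out
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s @ column %d (min conservation %.2f)\n",
              x$pattern, x$start_column, min(x$conservation)))
  invisible(x)
}

#' Filter motifs against excluded structural spans
#'
#' Implements the decoupling-candidate criteria for a motif: it must lie
#' outside the complementarity-determining regions (CDR1/2/3) and outside
#' the alpha-chain connecting peptide motif (aCPM) in every gene of the
#' alignment. Motif alignment columns are mapped through each row's
#' `column_map` to ungapped coordinates before overlap testing.
#'
#' @param motifs List of `motif_pattern` objects.
#' @param aln The `aligned_set` the motifs were found in; its genes must
#'   carry annotations for the excluded labels.
#' @param excluded_labels Span labels that a motif must not overlap.
#' @return The surviving motifs; each records per-label pass flags in its
#'   `criteria` field.
#' @export
filter_candidate_motifs <- function(motifs, aln,
                                    excluded_labels = c("CDR1", "CDR2",
                                                        "CDR3", "aCPM")) {
  genes <- aln$genes
  for (g in genes) {
    if (is.null(g$annotations)) {
      stop("gene '", g$name, "' has no annotations; cannot apply ",
           "exclusion criteria", call. = FALSE)
    }
  }
  keep <- list()
  for (m in motifs) {
    cols <- (m$start_column + 1L):(m$start_column + nchar(m$pattern))
    overlap <- stats::setNames(rep(FALSE, length(excluded_labels)),
                               excluded_labels)
    for (i in seq_along(genes)) {
      pos <- aln$column_map[[i]][cols]
      pos <- pos[!is.na(pos)]
      if (!length(pos)) next
      ann <- genes[[i]]$annotations
      ann <- ann[ann$label %in% excluded_labels, , drop = FALSE]
      for (r in seq_len(nrow(ann))) {
        if (any(pos >= ann$start[r] & pos < ann$end[r])) {
          overlap[[ann$label[r]]] <- TRUE
        }
      }
    }
    if (any(overlap)) next
    m$criteria <- c(m$criteria,
                    stats::setNames(!overlap,
                                    paste0("outside_", excluded_labels)))
    keep[[length(keep) + 1L]] <- m
  }
  keep
}

#' Motif report as a data.frame
#' @param motifs List of `motif_pattern` objects.
#' @return data.frame with pattern, start column, minimum conservation,
#'   wildcard count.
#' @export
motif_report <- function(motifs) {
  if (!length(motifs)) {
    return(data.frame(pattern = character(), start_column = integer(),
                      min_conservation = numeric(),
                      n_wildcards = integer()))
  }
  data.frame(
    pattern = vapply(motifs, `[[`, character(1), "pattern"),
    start_column = vapply(motifs, `[[`, integer(1), "start_column"),
    min_conservation = vapply(motifs, function(m)
      min(m$conservation), numeric(1)),
    n_wildcards = vapply(motifs, function(m)
      length(m$wildcards), integer(1)),
    stringsAsFactors = FALSE)
}
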