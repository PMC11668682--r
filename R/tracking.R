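# Anchored amplicon parsing, the variation-only cleaning rule, and
# frequency/rank tracking across sorted populations.

FAIL_REASONS <- c("anchor_mismatch", "frame", "low_quality",
                  "ambiguous_base", "off_target_mutation", "stop_codon")

# Hamming distance between equal-length strings and a reference, computed
# once per unique string (reads are near-duplicates of the template).
.mm_by_unique <- function(obs, ref) {
  u <- unique(obs)
  rr <- charToRaw(ref)
  mm <- vapply(u, function(s) {
    rs <- charToRaw(s)
    if (length(rs) != length(rr)) return(NA_integer_)
    sum(rs != rr)
  }, integer(1))
  unname(mm[match(obs, u)])
}

#' Parse amplicon reads into motif variant calls
#'
#' Each read is located by matching the fixed template flanks (anchors)
#' around the motif span, then the motif codons are extracted in frame
#' and classified under the cleaning rule: a read passes only when the
#' anchors match (within `max_anchor_mismatches`), the spacing preserves
#' the reading frame, motif bases meet the quality floor and are
#' unambiguous, *no* variation occurs outside the targeted codons, and no
#' targeted codon is a stop. Failures carry exactly one primary reason,
#' the first failing check in the fixed order anchor, frame, quality,
#' ambiguity, off-target, stop.
#'
#' @param fastq Path to a Phred-33 FASTQ file, or a
#'   `Biostrings::DNAStringSet` (then quality checks are skipped), or a
#'   character vector of read sequences.
#' @param template Amplicon template list (see
#'   [default_amplicon_template()]).
#' @param anchor_length Anchor length on each side of the motif span.
#' @param max_anchor_mismatches Tolerated mismatches per anchor.
#' @param min_base_quality Minimum Phred score at motif bases (set to 0
#'   to disable).
#' @return data.frame of class `variant_calls`: `read_id`, `pass`,
#'   `reason`, per-position `aa_<i>` columns, `motif`, `codons`.
#' @export
parse_reads <- function(fastq, template = default_amplicon_template(),
                        anchor_length = 12, max_anchor_mismatches = 1,
                        min_base_quality = 20) {
  tpl <- template
  s <- tpl$motif_span[1]; e <- tpl$motif_span[2]
  if (s - anchor_length < 0 || e + anchor_length > nchar(tpl$template)) {
    stop("anchor_length exceeds template flanks", call. = FALSE)
  }
  anchor5 <- substr(tpl$template, s - anchor_length + 1L, s)
  anchor3 <- substr(tpl$template, e + 1L, e + anchor_length)
  for (a in c(anchor5, anchor3)) {
    if (Biostrings::countPattern(a, Biostrings::DNAString(tpl$template))
        != 1L) {
      stop("anchor '", a, "' is not unique in the template",
           call. = FALSE)
    }
  }

  quals <- NULL
  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    set <- tryCatch(
      Biostrings::readDNAStringSet(fastq, format = "fastq",
                                   with.qualities = TRUE),
      error = function(err) stop("unreadable FASTQ: ", fastq,
                                 call. = FALSE))
    reads <- as.character(set)
    ids <- names(set)
    if (min_base_quality > 0) {
      quals <- as.character(S4Vectors::mcols(set)$qualities)
    }
  } else if (methods::is(fastq, "DNAStringSet")) {
    reads <- as.character(fastq)
    ids <- names(fastq)
  } else {
    reads <- as.character(fastq)
    ids <- names(fastq)
  }
  n <- length(reads)
  if (is.null(ids)) ids <- sprintf("read_%07d", seq_len(n))

  n_codons <- (e - s) / 3L
  mutated <- tpl$mutated_codons
  fixed <- setdiff(seq_len(n_codons) - 1L, mutated)
  tpl_codons <- substring(substr(tpl$template, s + 1L, e),
                          seq(1L, e - s, 3L), seq(3L, e - s, 3L))

  reason <- rep(NA_character_, n)
  motif_start <- rep(s, n)  # 0-based start of motif in each read

  # anchors at the expected offsets first (the simulator emits
  # fixed-layout substitution-only reads); exact search as a fallback for
  # shifted reads.
  a5 <- substr(reads, s - anchor_length + 1L, s)
  a3 <- substr(reads, e + 1L, e + anchor_length)
  mm5 <- .mm_by_unique(a5, anchor5)
  mm3 <- .mm_by_unique(a3, anchor3)
  located <- !is.na(mm5) & !is.na(mm3) &
    mm5 <= max_anchor_mismatches & mm3 <= max_anchor_mismatches
  for (i in which(!located)) {
    p5 <- regexpr(anchor5, reads[i], fixed = TRUE)
    p3 <- regexpr(anchor3, reads[i], fixed = TRUE)
    if (p5 < 0L || p3 < 0L) { reason[i] <- "anchor_mismatch"; next }
    gap <- (p3 - 1L) - (p5 - 1L + anchor_length)
    if (gap != (e - s)) { reason[i] <- "frame"; next }
    motif_start[i] <- p5 - 1L + anchor_length
    located[i] <- TRUE
  }

  motif_nt <- rep(NA_character_, n)
  ok <- located
  motif_nt[ok] <- substr(reads[ok], motif_start[ok] + 1L,
                         motif_start[ok] + (e - s))
  short <- ok & nchar(motif_nt) < (e - s)
  reason[short] <- "frame"; ok[short] <- FALSE

  if (!is.null(quals) && min_base_quality > 0) {
    qsub <- substr(quals, motif_start + 1L, motif_start + (e - s))
    uq <- unique(qsub[ok])
    minq <- vapply(uq, function(q) min(utf8ToInt(q)) - 33L, integer(1))
    low <- ok & (minq[match(qsub, uq)] < min_base_quality)
    reason[low] <- "low_quality"; ok[low] <- FALSE
  }

  # classify unique motif nt strings (few, at low error rates)
  um <- unique(motif_nt[ok])
  if (length(um)) {
    cls <- lapply(um, function(mn) {
      codons <- substring(mn, seq(1L, e - s, 3L), seq(3L, e - s, 3L))
      if (grepl("[^ACGT]", mn)) {
        return(list(reason = "ambiguous_base"))
      }
      if (any(codons[fixed + 1L] != tpl_codons[fixed + 1L])) {
        return(list(reason = "off_target_mutation"))
      }
      aa <- translate_codon(codons[mutated + 1L])
      if (any(aa == "*")) return(list(reason = "stop_codon"))
      full <- translate_codon(codons)
      list(reason = NA_character_, aa = aa,
           motif = paste(full, collapse = ""),
           codons = paste(codons[mutated + 1L], collapse = ","))
    })
    names(cls) <- um
    idx <- match(motif_nt, um)
    creason <- vapply(cls, `[[`, character(1), "reason")
    hit <- ok & !is.na(idx)
    reason[hit] <- creason[idx[hit]]
  }

  pass <- located & is.na(reason)
  out <- data.frame(read_id = ids, pass = pass, reason = reason,
                    stringsAsFactors = FALSE)
  for (k in seq_along(mutated)) {
    col <- rep(NA_character_, n)
    if (length(um)) {
      aa_u <- vapply(cls, function(x)
        if (is.na(x$reason)) x$aa[k] else NA_character_, character(1))
      col[pass] <- aa_u[idx[pass]]
    }
    out[[paste0("aa_", mutated[k])]] <- col
  }
  out$motif <- NA_character_
  out$codons <- NA_character_
  if (length(um)) {
    motif_u <- vapply(cls, function(x)
      if (is.na(x$reason)) x$motif else NA_character_, character(1))
    codons_u <- vapply(cls, function(x)
      if (is.na(x$reason)) x$codons else NA_character_, character(1))
    out$motif[pass] <- motif_u[idx[pass]]
    out$codons[pass] <- codons_u[idx[pass]]
  }
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Count, rank and normalise variant calls per population
#'
#' Passing calls are aggregated at the amino-acid level; frequency is
#' count over the column's passing total; rank 1 is the most frequent
#' variant, ties broken lexicographically by motif string.
#'
#' @param calls A `variant_calls` data.frame, or a named list of them
#'   (one per population column).
#' @param column Column label (`"R<round>_<population>"`) when `calls` is
#'   a single table.
#' @return data.frame of class `rank_table`: `column`, `population`,
#'   `round`, `variant`, `count`, `frequency`, `rank`. Columns with zero
#'   passing calls are recorded in `attr(, "empty_columns")`.
#' @export
count_and_rank <- function(calls, column = "R1_UNKNOWN") {
  if (inherits(calls, "variant_calls")) {
    calls <- stats::setNames(list(calls), column)
  }
  out <- list(); empty <- character(0)
  for (col in names(calls)) {
    tab <- calls[[col]]
    tab <- tab[tab$pass, , drop = FALSE]
    if (nrow(tab) == 0L) { empty <- c(empty, col); next }
    agg <- table(tab$motif)
    df <- data.frame(variant = names(agg), count = as.integer(agg),
                     stringsAsFactors = FALSE)
    out[[col]] <- .rank_column(df, col)
  }
  if (!length(out)) {
    stop("no passing calls in any column", call. = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  attr(res, "empty_columns") <- empty
  class(res) <- c("rank_table", "data.frame")
  res
}

.rank_column <- function(df, col) {
  m <- regmatches(col, regexec("^R(\\d+)_(.+)$", col))[[1]]
  pop <- if (length(m) == 3L) m[3] else col
  rnd <- if (length(m) == 3L) as.integer(m[2]) else NA_integer_
  df <- df[order(-df$count, df$variant), , drop = FALSE]
  df$frequency <- df$count / sum(df$count)
  df$rank <- seq_len(nrow(df))
  cbind(data.frame(column = col, population = pop, round = rnd,
                   stringsAsFactors = FALSE), df)
}

#' Rank table directly from a read-count matrix
#'
#' Convenience path used when working at count level (no FASTQ): applies
#' the same frequency/rank rules as [count_and_rank()], dropping
#' zero-count variants (unobserved).
#'
#' @param counts Integer matrix, rows named by variant, columns by
#'   population (`R<round>_<population>`).
#' @return A `rank_table` (see [count_and_rank()]).
#' @export
rank_table_from_counts <- function(counts) {
  out <- list(); empty <- character(0)
  for (col in colnames(counts)) {
    cts <- counts[, col]
    cts <- cts[cts > 0L]
    if (!length(cts)) { empty <- c(empty, col); next }
    df <- data.frame(variant = names(cts), count = as.integer(cts),
                     stringsAsFactors = FALSE)
    out[[col]] <- .rank_column(df, col)
  }
  if (!length(out)) {
    stop("no observed variants in any column", call. = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  attr(res, "empty_columns") <- empty
  class(res) <- c("rank_table", "data.frame")
  res
}

#' Export a rank table as TSV
#' @param table A `rank_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank/frequency trajectories between a reference and selected columns
#'
#' For every variant observed in the reference column, records its rank
#' and frequency there and in each selected column, the rank change
#' `delta_rank = rank(selected) - rank(reference)` and the log2
#' enrichment `log2((f_sel + eps) / (f_ref + eps))` with pseudocount
#' `eps = 1 / (2 * selected-column read total)`. Variants unobserved in a
#' selected column are flagged `missing`; their frequency enters the
#' enrichment as 0 and their rank change uses the effective rank
#' `n_observed + 1` (one past the bottom of the selected column).
#'
#' @param table A `rank_table`.
#' @param reference_column Reference column name (e.g. `"R3_DEX_CD3"`).
#' @param selected_columns Selected column names.
#' @param epsilon Optional fixed pseudocount overriding the per-column
#'   default.
#' @return data.frame of class `rank_trajectories` (long format: one row
#'   per variant x selected column).
#' @export
build_trajectories <- function(table, reference_column, selected_columns,
                               epsilon = NULL) {
  tab <- as.data.frame(table)
  have <- unique(tab$column)
  miss <- setdiff(c(reference_column, selected_columns), have)
  if (reference_column %in% miss) {
    stop("reference column '", reference_column,
         "' is empty or absent from the rank table", call. = FALSE)
  }
  if (length(miss)) {
    stop("selected column(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ref <- tab[tab$column == reference_column, , drop = FALSE]
  out <- list()
  for (sel in selected_columns) {
    st <- tab[tab$column == sel, , drop = FALSE]
    depth <- sum(st$count)
    eps <- if (is.null(epsilon)) 1 / (2 * depth) else epsilon
    i <- match(ref$variant, st$variant)
    f_sel <- ifelse(is.na(i), 0, st$frequency[i])
    r_sel <- st$rank[i]
    eff_rank <- ifelse(is.na(r_sel), nrow(st) + 1L, r_sel)
    out[[sel]] <- data.frame(
      variant = ref$variant, reference = reference_column,
      selected = sel, ref_rank = ref$rank, ref_frequency = ref$frequency,
      sel_rank = r_sel, sel_frequency = f_sel,
      missing = is.na(i),
      delta_rank = eff_rank - ref$rank,
      log2_enrichment = log2((f_sel + eps) / (ref$frequency + eps)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  class(res) <- c("rank_trajectories", "data.frame")
  res
}
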