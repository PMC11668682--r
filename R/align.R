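# Progressive multiple sequence alignment of germline genes.
#
# Germline J/V segments are short (<= ~120 aa) and near-identical, so exact
# affine-gap dynamic programming (Gotoh) on pairs and on profiles is both
# affordable and testable against an independent pairwise optimum.

#' Load a named substitution score matrix
#'
#' Currently ships `BLOSUM62` (the standard NCBI matrix) as plain text
#' under `inst/extdata`.
#'
#' @param name Matrix name; only `"BLOSUM62"`.
#' @return Numeric matrix with residue row/column names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  name <- match.arg(name, "BLOSUM62")
  key <- paste0("submat_", name)
  if (is.null(.aed_env[[key]])) {
    path <- system.file("extdata", paste0(name, ".tsv"),
                        package = "aedscreen", mustWork = TRUE)
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    .aed_env[[key]] <- m
  }
  .aed_env[[key]]
}

# Gotoh global alignment of two column sequences under an arbitrary
# column-pair score function. A gap of length L costs gap_open + L *
# gap_extend (the convention of Biostrings::pairwiseAlignment, which the
# test-suite uses as an independent oracle). Returns the optimal score and
# the aligned paths as integer vectors (0 = gap, otherwise input index).
.gotoh <- function(n, m, score_fun, gap_open, gap_extend) {
  NEG <- -Inf
  open <- gap_open + gap_extend
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in B (consumes A)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in A (consumes B)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2L:(n + 1L), 1L] <- -(gap_open + gap_extend * seq_len(n))
  if (m >= 1L) Y[1L, 2L:(m + 1L)] <- -(gap_open + gap_extend * seq_len(m))
  for (i in seq_len(n)) {
    si <- score_fun(i, seq_len(m))
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- si[j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open,
                               X[i, j + 1L] - gap_extend,
                               Y[i, j + 1L] - open)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open,
                               X[i + 1L, j] - open,
                               Y[i + 1L, j] - gap_extend)
    }
  }
  fin <- c(M = M[n + 1L, m + 1L], X = X[n + 1L, m + 1L],
           Y = Y[n + 1L, m + 1L])
  state <- names(which.max(fin))
  # traceback
  pa <- integer(0); pb <- integer(0)
  i <- n; j <- m
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "M") {
      s <- score_fun(i, j)
      prev <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      state <- names(which(abs(prev + s - M[i + 1L, j + 1L]) < tol))[1L]
      pa <- c(i, pa); pb <- c(j, pb)
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      cur <- X[i + 1L, j + 1L]
      prev <- c(M = M[i, j + 1L] - open, X = X[i, j + 1L] - gap_extend,
                Y = Y[i, j + 1L] - open)
      state <- names(which(abs(prev - cur) < tol))[1L]
      pa <- c(i, pa); pb <- c(0L, pb)
      i <- i - 1L
    } else {
      cur <- Y[i + 1L, j + 1L]
      prev <- c(M = M[i + 1L, j] - open, X = X[i + 1L, j] - open,
                Y = Y[i + 1L, j] - gap_extend)
      state <- names(which(abs(prev - cur) < tol))[1L]
      pa <- c(0L, pa); pb <- c(j, pb)
      j <- j - 1L
    }
    if (i == 0L && j > 0L) { pa <- c(rep(0L, j), pa); pb <- c(seq_len(j), pb); j <- 0L }
    if (j == 0L && i > 0L) { pa <- c(seq_len(i), pa); pb <- c(rep(0L, i), pb); i <- 0L }
  }
  list(score = unname(max(fin)), path_a = pa, path_b = pb)
}

#' Optimal global pairwise alignment (affine gaps)
#'
#' Exact Needleman--Wunsch/Gotoh alignment of two amino-acid sequences.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param a,b Amino-acid strings.
#' @param substitution_matrix Score matrix name (see
#'   [substitution_matrix()]).
#' @param gap_open,gap_extend Positive gap costs.
#' @return List with `score` and gapped strings `a_gapped`, `b_gapped`.
#' @export
pairwise_align <- function(a, b, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 1) {
  S <- substitution_matrix(substitution_matrix)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  sf <- function(i, j) S[ca[i], cb[j]]
  g <- .gotoh(length(ca), length(cb), sf, gap_open, gap_extend)
  gapfill <- function(ch, path) {
    out <- rep("-", length(path)); out[path > 0L] <- ch[path[path > 0L]]
    paste(out, collapse = "")
  }
  list(score = g$score, a_gapped = gapfill(ca, g$path_a),
       b_gapped = gapfill(cb, g$path_b))
}

# Profile-profile alignment. Profiles are character matrices (rows x
# columns, '-' for gaps). Column score = mean BLOSUM score over non-gap
# residue pairs (gap pairs contribute 0); gap penalties are not scaled.
.align_profiles <- function(A, B, S, gap_open, gap_extend) {
  nA <- nrow(A); nB <- nrow(B)
  # per-column residue frequency representation over the score alphabet
  alpha <- rownames(S)
  colfreq <- function(P) {
    apply(P, 2L, function(col) {
      col <- col[col != "-"]
      tabulate(match(col, alpha), length(alpha))
    })
  }
  FA <- colfreq(A); FB <- colfreq(B)  # alphabet x columns
  denom <- nA * nB
  sf <- function(i, j) {
    fa <- FA[, i]
    nz <- which(fa > 0)
    if (length(j) > 1L) {
      vapply(j, function(jj) {
        fb <- FB[, jj]
        sum(outer(fa[nz], fb, "*") * S[nz, , drop = FALSE]) / denom
      }, numeric(1))
    } else {
      fb <- FB[, j]
      sum(outer(fa[nz], fb, "*") * S[nz, , drop = FALSE]) / denom
    }
  }
  g <- .gotoh(ncol(A), ncol(B), sf, gap_open, gap_extend)
  take <- function(P, path) {
    out <- matrix("-", nrow(P), length(path))
    out[, path > 0L] <- P[, path[path > 0L]]
    out
  }
  rbind(take(A, g$path_a), take(B, g$path_b))
}

#' Progressive multiple sequence alignment
#'
#' Aligns a set of germline genes progressively along a UPGMA guide tree.
#' Pairwise identity distances are computed from exact pairwise Gotoh
#' alignments; profile merges use sum-of-pairs column scores with the same
#' affine gap model. For two sequences the result is the exact pairwise
#' optimum.
#'
#' @param genes List of [germline_gene()] objects (length >= 1).
#' @inheritParams pairwise_align
#' @return An `aligned_set`: list with `genes`, `rows` (named gapped
#'   strings, equal length) and `column_map` (per row, an integer vector
#'   mapping alignment columns to 0-based ungapped positions, `NA` at
#'   gaps).
#' @export
align_sequences <- function(genes, substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 1) {
  if (length(genes) == 0L) stop("no sequences to align", call. = FALSE)
  seqs <- vapply(genes, `[[`, character(1), "sequence")
  nms <- vapply(genes, `[[`, character(1), "name")
  n <- length(seqs)
  S <- substitution_matrix(substitution_matrix)
  as_mat <- function(s) matrix(strsplit(s, "")[[1]], nrow = 1L)
  if (n == 1L) {
    rows <- stats::setNames(seqs, nms)
    return(.new_aligned_set(genes, rows))
  }
  # guide tree over pairwise identity distances
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pw <- pairwise_align(seqs[i], seqs[j], substitution_matrix,
                           gap_open, gap_extend)
      ai <- strsplit(pw$a_gapped, "")[[1]]
      bj <- strsplit(pw$b_gapped, "")[[1]]
      D[i, j] <- D[j, i] <- 1 - sum(ai == bj & ai != "-") / length(ai)
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- vector("list", n - 1L)
  members <- vector("list", n - 1L)
  getp <- function(k) {
    if (k < 0L) list(p = as_mat(seqs[-k]), m = -k) else
      list(p = profiles[[k]], m = members[[k]])
  }
  for (s in seq_len(n - 1L)) {
    a <- getp(hc$merge[s, 1L]); b <- getp(hc$merge[s, 2L])
    profiles[[s]] <- .align_profiles(a$p, b$p, S, gap_open, gap_extend)
    members[[s]] <- c(a$m, b$m)
  }
  final <- profiles[[n - 1L]]
  ord <- order(members[[n - 1L]])
  final <- final[ord, , drop = FALSE]
  rows <- stats::setNames(apply(final, 1L, paste, collapse = ""), nms)
  .new_aligned_set(genes, rows)
}

.new_aligned_set <- function(genes, rows) {
  widths <- unique(nchar(rows))
  stopifnot(length(widths) == 1L)
  cmap <- lapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    idx <- rep(NA_integer_, length(ch))
    idx[ch != "-"] <- seq_len(sum(ch != "-")) - 1L
    idx
  })
  # round-trip invariant: degapping reproduces the input
  for (i in seq_along(genes)) {
    if (gsub("-", "", rows[[i]], fixed = TRUE) != genes[[i]]$sequence) {
      stop("internal error: alignment row ", i,
           " does not degap to its input sequence", call. = FALSE)
    }
  }
  structure(list(genes = genes, rows = rows, column_map = cmap),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[[1]])))
  invisible(x)
}

#' Alignment as a character matrix (rows x columns)
#' @param aln An `aligned_set`.
#' @return Character matrix of residues and `'-'`.
#' @export
alignment_matrix <- function(aln) {
  do.call(rbind, lapply(aln$rows, function(r) strsplit(r, "")[[1]]))
}

#' Write an alignment as aligned FASTA
#' @param aln An `aligned_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  s <- Biostrings::AAStringSet(aln$rows)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
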