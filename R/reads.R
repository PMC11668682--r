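# Synthetic amplicon read emission (FASTQ, Phred-33).

#' Default amplicon template for the mutated motif
#'
#' A 75-nt single-end amplicon: 30-nt fixed flanks around the 15-nt motif
#' `TTT GAA CAG TGG ACC` (FEQWT, the library cloning backbone), with the
#' two NNK-mutated codons at motif codon indices 1 and 3.
#'
#' @return List with `template` (nt string), `motif_span` (0-based
#'   half-open nt interval), `mutated_codons` (0-based codon indices
#'   within the motif) and `motif_aa` (translation of the template motif).
#' @export
default_amplicon_template <- function() {
  flank5 <- "ACGGTCTTGAGCCAAGTGACGAGTCCATCT"
  flank3 <- "CGACTTGAGGCAACTCGTAAGCCTGGTTCA"
  motif <- "TTTGAACAGTGGACC"
  list(template = paste0(flank5, motif, flank3),
       motif_span = c(nchar(flank5), nchar(flank5) + nchar(motif)),
       mutated_codons = c(1L, 3L),
       motif_aa = paste(translate_codon(substring(motif,
                                                  seq(1, 13, 3),
                                                  seq(3, 15, 3))),
                        collapse = ""))
}

# Lexicographically first NNK codon per amino acid (canonical codon used
# when emitting reads; synonymous codons collapse at parsing anyway).
.nnk_codon_table <- function() {
  if (is.null(.aed_env$nnk_codons)) {
    cods <- expand_degenerate_codon("NNK")
    aa <- translate_codon(cods)
    keep <- aa != "*"
    .aed_env$nnk_codons <- vapply(split(cods[keep], aa[keep]), min,
                                  character(1))
  }
  .aed_env$nnk_codons
}

# Build the error-free read for one variant motif string.
.variant_read <- function(motif_variant, tpl) {
  s <- tpl$motif_span[1]; e <- tpl$motif_span[2]
  codons <- substring(substr(tpl$template, s + 1L, e),
                      seq(1L, e - s, 3L), seq(3L, e - s, 3L))
  aa <- strsplit(motif_variant, "")[[1]]
  nnk <- .nnk_codon_table()
  for (k in tpl$mutated_codons) codons[k + 1L] <- nnk[[aa[k + 1L]]]
  paste0(substr(tpl$template, 1L, s), paste(codons, collapse = ""),
         substr(tpl$template, e + 1L, nchar(tpl$template)))
}

#' Emit synthetic amplicon reads per population
#'
#' Every read is the amplicon template with the variant's canonical NNK
#' codons substituted at the mutated positions, plus i.i.d. substitution
#' errors at `error_rate`; the quality line is constant Phred-33 `'I'`.
#' One FASTQ file per count-matrix column is written, named
#' `<round>_<population>.fastq` when column names follow the
#' `R<round>_<population>` convention (otherwise `<column>.fastq`).
#'
#' @param read_counts Integer matrix of reads per variant (rows named by
#'   variant motif) and population (named columns), e.g. from
#'   [sample_reads()].
#' @param dir Output directory (created if needed); `NULL` returns
#'   in-memory `Biostrings::DNAStringSet`s instead of writing files.
#' @param template Amplicon template list (see
#'   [default_amplicon_template()]).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return Named list (per column) of file paths, or of `DNAStringSet`s
#'   when `dir` is `NULL`.
#' @export
emit_reads <- function(read_counts, dir = tempfile("reads"),
                       template = default_amplicon_template(),
                       error_rate = 0.001, seed = 1) {
  if (inherits(read_counts, "screen_counts")) {
    read_counts <- read_counts$counts
  }
  stopifnot(!is.null(rownames(read_counts)), !is.null(colnames(read_counts)))
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  base_reads <- vapply(rownames(read_counts), .variant_read,
                       character(1), tpl = template)
  L <- nchar(base_reads[[1]])
  bases <- c("A", "C", "G", "T")
  out <- stats::setNames(vector("list", ncol(read_counts)),
                         colnames(read_counts))
  for (j in seq_len(ncol(read_counts))) {
    col <- colnames(read_counts)[j]
    cts <- read_counts[, j]
    reads <- rep(base_reads, cts)
    nr <- length(reads)
    if (nr > 0L && error_rate > 0) {
      withr::with_seed(.split_seed(seed, 30L + j), {
        nerr <- rbinom(nr, L, error_rate)
        for (i in which(nerr > 0L)) {
          pos <- sample.int(L, nerr[i])
          ch <- strsplit(reads[i], "")[[1]]
          ch[pos] <- vapply(ch[pos],
                            function(b) sample(setdiff(bases, b), 1L),
                            character(1))
          reads[i] <- paste(ch, collapse = "")
        }
      })
    }
    ids <- if (nr > 0L) sprintf("%s:%07d", col, seq_len(nr)) else
      character(0)
    set <- Biostrings::DNAStringSet(stats::setNames(reads, ids))
    if (is.null(dir)) {
      out[[j]] <- set
    } else {
      m <- regmatches(col, regexec("^R(\\d+)_(.+)$", col))[[1]]
      fname <- if (length(m) == 3L) sprintf("%s_%s.fastq", m[2], m[3]) else
        paste0(col, ".fastq")
      path <- file.path(dir, fname)
      quals <- Biostrings::BStringSet(
        stats::setNames(vapply(nchar(reads),
                               function(w) strrep("I", w), character(1)),
                        ids))
      Biostrings::writeXStringSet(set, path, format = "fastq",
                                  qualities = quals)
      out[[j]] <- path
    }
  }
  out
}
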