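# Degenerate-codon (NNK) saturation-mutagenesis library design.
#
# NNK (N = A/C/G/T, K = G/T) encodes all 20 amino acids with 32 codons and
# a single stop (TAG); replacing two motif positions with NNK therefore
# gives 1,024 codon combinations and 20 x 20 = 400 stop-free protein
# variants.

#' Expand a degenerate IUPAC codon to concrete codons
#'
#' @param codon 3-character IUPAC nucleotide pattern, e.g. `"NNK"`.
#' @return Character vector of all matching concrete codons, sorted
#'   lexicographically, without duplicates.
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("codon pattern must have length 3",
                               call. = FALSE)
  ch <- strsplit(codon, "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(ch, names(map))
  if (length(bad)) stop("invalid IUPAC code(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sets <- lapply(ch, function(x) strsplit(map[[x]], "")[[1]])
  g <- expand.grid(sets[[3]], sets[[2]], sets[[1]],
                   stringsAsFactors = FALSE)
  sort(unique(paste0(g[[3]], g[[2]], g[[1]])))
}

#' Translate a concrete codon under the standard genetic code
#'
#' @param codon 3-mer over A/C/G/T (vectorised).
#' @return One-letter amino acid, or `"*"` for a stop codon.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) {
    stop("not a concrete A/C/G/T codon: ",
         paste(codon[is.na(aa)], collapse = ", "), call. = FALSE)
  }
  unname(aa)
}

#' Substitute amino acids into a parent motif
#'
#' @param parent_motif Amino-acid string, e.g. `"FGQGT"`.
#' @param substitutions Named character vector; names are 0-based motif
#'   positions, values single amino acids (e.g. `c("1" = "E", "3" = "W")`
#'   turns FGQGT into FEQWT).
#' @return The substituted motif string.
#' @export
variant_protein <- function(parent_motif, substitutions = character()) {
  ch <- strsplit(parent_motif, "")[[1]]
  if (length(substitutions)) {
    pos <- as.integer(names(substitutions))
    if (anyNA(pos) || any(pos < 0L) || any(pos >= length(ch))) {
      stop("substitution position out of motif bounds", call. = FALSE)
    }
    aa <- toupper(unlist(substitutions))
    if (any(aa == "*")) stop("cannot substitute a stop symbol",
                             call. = FALSE)
    if (!all(aa %in% setdiff(AA_ALPHABET, "X"))) {
      stop("substitution is not a standard amino acid", call. = FALSE)
    }
    ch[pos + 1L] <- aa
  }
  paste(ch, collapse = "")
}

#' Design a degenerate-codon mutagenesis library
#'
#' Enumerates the Cartesian product of degenerate-codon expansions at the
#' mutated motif positions, translates every codon combination, excludes
#' stop-containing combinations, and aggregates synonymous codons into
#' unique amino-acid variants. The theoretical protein diversity of a
#' two-position NNK library over a 5-residue motif is 400.
#'
#' @param parent_motif Amino-acid string (e.g. `"FGQGT"`).
#' @param mutated_positions 0-based indices into the motif (e.g. `c(1, 3)`
#'   for both glycines of FGQGT). May be empty.
#' @param scheme Degenerate codon pattern, recycled over positions
#'   (default `"NNK"`), or one pattern per position.
#' @return A `library_design`: parent motif, positions, scheme,
#'   `codon_variants` (data.frame of stop-free codon combinations and
#'   their translations), `protein_variants` (data.frame of unique
#'   amino-acid combinations, the substituted full motif, and synonymous
#'   codon counts, sorted), `theoretical_protein_diversity`, and
#'   `n_codon_combinations` (including stop-containing ones).
#' @export
design_library <- function(parent_motif, mutated_positions = integer(),
                           scheme = "NNK") {
  parent_motif <- toupper(parent_motif)
  ch <- strsplit(parent_motif, "")[[1]]
  if (!all(ch %in% setdiff(AA_ALPHABET, "X"))) {
    stop("parent motif contains non-standard amino acids", call. = FALSE)
  }
  p <- as.integer(mutated_positions)
  if (anyNA(p) || any(p < 0L) || any(p >= length(ch))) {
    stop("mutated position out of motif bounds", call. = FALSE)
  }
  if (anyDuplicated(p)) stop("duplicate mutated positions", call. = FALSE)
  if (length(scheme) == 1L) scheme <- rep(scheme, length(p))
  stopifnot(length(scheme) == length(p))

  if (length(p) == 0L) {
    pv <- data.frame(motif = parent_motif, n_codons = 1L,
                     stringsAsFactors = FALSE)
    return(structure(list(parent_motif = parent_motif,
                          mutated_positions = p, scheme = scheme,
                          codon_variants = data.frame(),
                          protein_variants = pv,
                          theoretical_protein_diversity = 1L,
                          n_codon_combinations = 1L),
                     class = "library_design"))
  }

  expansions <- lapply(scheme, expand_degenerate_codon)
  grid <- expand.grid(rev(expansions), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(expansions)), drop = FALSE]
  names(grid) <- paste0("codon_", p)
  n_total <- nrow(grid)
  aa <- vapply(seq_along(p), function(k) translate_codon(grid[[k]]),
               character(n_total))
  aa <- matrix(aa, nrow = n_total)
  has_stop <- apply(aa == "*", 1L, any)
  cod <- grid[!has_stop, , drop = FALSE]
  aa <- aa[!has_stop, , drop = FALSE]
  for (k in seq_along(p)) cod[[paste0("aa_", p[k])]] <- aa[, k]
  key <- apply(aa, 1L, paste, collapse = "")
  ord <- order(key, apply(cod[, seq_along(p), drop = FALSE], 1L,
                          paste, collapse = ""))
  cod <- cod[ord, , drop = FALSE]
  key <- key[ord]
  row.names(cod) <- NULL

  ukey <- unique(key)
  aa_u <- do.call(rbind, strsplit(ukey, ""))
  pv <- as.data.frame(aa_u, stringsAsFactors = FALSE)
  names(pv) <- paste0("aa_", p)
  pv$motif <- vapply(seq_len(nrow(pv)), function(i) {
    variant_protein(parent_motif,
                    stats::setNames(as.character(aa_u[i, ]),
                                    as.character(p)))
  }, character(1))
  pv$n_codons <- as.integer(table(key)[ukey])
  structure(list(parent_motif = parent_motif, mutated_positions = p,
                 scheme = scheme, codon_variants = cod,
                 protein_variants = pv,
                 theoretical_protein_diversity = nrow(pv),
                 n_codon_combinations = n_total),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf(paste0("<library_design> parent %s, %d position(s) [%s],",
                     " %d protein variants (%d codon combinations)\n"),
              x$parent_motif, length(x$mutated_positions),
              paste(x$scheme, collapse = ","),
              x$theoretical_protein_diversity, x$n_codon_combinations))
  invisible(x)
}

#' Emit degenerate mutagenic oligonucleotides
#'
#' Builds one degenerate oligo: fixed template flanks of `flank_length`
#' nucleotides on each side of the motif span, with the scheme's IUPAC
#' codes substituted at the mutated codons.
#'
#' @param template_nt Nucleotide template string.
#' @param motif_nt_span 0-based half-open nucleotide interval of the motif
#'   on the template; must be codon-aligned (length divisible by 3).
#' @param mutated_codons 0-based codon indices within the motif span.
#' @param scheme Degenerate codon pattern(s), recycled.
#' @param flank_length Fixed flank length on each side.
#' @return Named character vector of length 1 (the oligo).
#' @export
make_mutagenic_oligos <- function(template_nt, motif_nt_span,
                                  mutated_codons, scheme = "NNK",
                                  flank_length = 15) {
  template_nt <- toupper(template_nt)
  s <- motif_nt_span[1]; e <- motif_nt_span[2]
  L <- nchar(template_nt)
  if (s < 0 || e > L || e <= s) stop("motif span outside template",
                                     call. = FALSE)
  if ((e - s) %% 3L != 0L) stop("motif span is not codon-aligned",
                                call. = FALSE)
  if (s - flank_length < 0 || e + flank_length > L) {
    stop("flank_length exceeds template", call. = FALSE)
  }
  n_codons <- (e - s) / 3L
  if (any(mutated_codons < 0L) || any(mutated_codons >= n_codons)) {
    stop("mutated codon index outside motif span", call. = FALSE)
  }
  if (length(scheme) == 1L) scheme <- rep(scheme, length(mutated_codons))
  motif <- substr(template_nt, s + 1L, e)
  codons <- substring(motif, seq(1L, e - s, 3L), seq(3L, e - s, 3L))
  codons[mutated_codons + 1L] <- toupper(scheme)
  oligo <- paste0(substr(template_nt, s - flank_length + 1L, s),
                  paste(codons, collapse = ""),
                  substr(template_nt, e + 1L, e + flank_length))
  stats::setNames(oligo, sprintf("oligo_%d_%d", s, e))
}

#' Export a library design as TSV
#' @param design A [design_library()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(design, path) {
  pv <- design$protein_variants
  pv$variant_id <- pv$motif
  utils::write.table(pv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export oligos as FASTA
#' @param oligos Named character vector from [make_mutagenic_oligos()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligos_fasta <- function(oligos, path) {
  s <- Biostrings::BStringSet(oligos)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
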