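# Shared fixtures and independent oracles.

# Independent pairwise alignment oracle (exhaustive affine-gap DP from
# Biostrings, not the package's Gotoh implementation).
oracle_pairwise_score <- function(a, b, gap_open = 10, gap_extend = 1) {
  S <- get(data("BLOSUM62", package = "Biostrings",
                envir = environment()), envir = environment())
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = S, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"))
}

# Random amino-acid sequence.
random_aa <- function(n) {
  paste(sample(setdiff(aedscreen:::AA_ALPHABET, "X"), n, replace = TRUE),
        collapse = "")
}

# Build an aligned_set directly from gapped rows (bypasses the aligner;
# used to plant exact column structures).
make_aligned_set <- function(rows, region = "TRAJ", annotations = NULL) {
  genes <- lapply(seq_along(rows), function(i) {
    germline_gene(sprintf("G%02d", i),
                  gsub("-", "", rows[i], fixed = TRUE),
                  region = region, annotations = annotations)
  })
  aedscreen:::.new_aligned_set(genes,
                               stats::setNames(rows,
                                               vapply(genes, `[[`,
                                                      character(1),
                                                      "name")))
}

# Minimal variant_calls table from a vector of motif strings (all
# passing).
make_calls <- function(motifs) {
  n <- length(motifs)
  df <- data.frame(read_id = sprintf("r%04d", seq_len(n)),
                   pass = TRUE, reason = NA_character_,
                   aa_1 = substr(motifs, 2, 2),
                   aa_3 = substr(motifs, 4, 4),
                   motif = motifs,
                   codons = NA_character_, stringsAsFactors = FALSE)
  class(df) <- c("variant_calls", "data.frame")
  df
}

# Brute-force radial bin means: independent double loop over pixels.
brute_force_bin_means <- function(image, centre, max_radius_um,
                                  bin_width_um, pixel_size_um) {
  nbins <- ceiling(max_radius_um / bin_width_um)
  sums <- numeric(nbins); cnts <- numeric(nbins)
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      d <- sqrt((i - centre[1])^2 + (j - centre[2])^2) * pixel_size_um
      k <- floor(d / bin_width_um) + 1
      if (k <= nbins) {
        sums[k] <- sums[k] + image[i, j]
        cnts[k] <- cnts[k] + 1
      }
    }
  }
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

# Small screen world used where full 10^6-cell scale is unnecessary.
small_screen_config <- function(...) {
  screen_config(n_cells = 2e4, read_depth = 2e4, ...)
}
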