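# Bundled synthetic germline set.
#
# Fifteen synthetic TRAJ-like amino-acid sequences (no IMGT material)
# with the hallmark structure of J genes: a variable CDR3 tail followed
# by the highly conserved F-G-x-G-T run at the start of the framework.
# A fully conserved 4-mer (DYKL) is planted *inside* the CDR3 span as a
# decoy that motif filtering must remove. Columns are fixed by design
# (no RNG): 14/15 sequences share F and T (93% identity), the 'x'
# column mixes Q/K/R/S below any sensible conservation threshold.

.SYN_TRAJ_COLS <- c(
  "AAASSSTTTNNNGGA",  # 0  variable
  "SSTTAANNGGSSTAN",  # 1  variable
  "DDDDDDDDDDDDDDD",  # 2  decoy D
  "YYYYYYYYYYYYYYY",  # 3  decoy Y
  "KKKKKKKKKKKKKKK",  # 4  decoy K
  "LLLLLLLLLLLLLLL",  # 5  decoy L
  "NTSGANTSGANTSGA",  # 6  variable (breaks decoy/motif bridging)
  "GGASSNNTTAGSATN",  # 7  variable
  "FFFFFFFFFFFFFFL",  # 8  motif F (14/15)
  "GGGGGGGGGGGGGGG",  # 9  motif G
  "QQQQQKKKKRRRSSS",  # 10 motif x (modal 5/15)
  "GGGGGGGGGGGGGGG",  # 11 motif G
  "TTTTTTTTTTTTTTS",  # 12 motif T (14/15)
  "RRRRRRKKKKKSSSS",  # 13 variable
  "TISANTISANTISAN",  # 14 variable
  "LLLLLLLLLLLLLLL",  # 15 conserved framework L
  "VVVVVVVVVVVVVVI",  # 16 conserved framework V
  "PKEDGPKEDGPKEDG")  # 17 variable

#' Synthetic TRAJ-like germline set
#'
#' Deterministically constructed stand-in for a cross-species TRAJ
#' germline collection (see source comments for the planted column
#' structure). Each gene carries a CDR3 annotation spanning ungapped
#' positions `[0, 8)`; the conserved FGxGT run starts at position 8,
#' just outside it.
#'
#' @param with_annotations Attach the CDR3 spans (default `TRUE`).
#' @return List of 15 [germline_gene()] objects (10 "human", 5
#'   "mouse" labels).
#' @export
synthetic_germline_set <- function(with_annotations = TRUE) {
  cols <- do.call(rbind, strsplit(.SYN_TRAJ_COLS, ""))
  lapply(seq_len(ncol(cols)), function(i) {
    ann <- if (with_annotations) {
      data.frame(start = 0L, end = 8L, label = "CDR3",
                 stringsAsFactors = FALSE)
    } else NULL
    germline_gene(sprintf("SYNTRAJ%02d", i),
                  paste(cols[, i], collapse = ""),
                  region = "TRAJ",
                  species = if (i <= 10L) "human" else "mouse",
                  annotations = ann)
  })
}
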