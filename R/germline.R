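# Germline gene containers and FASTA / annotation I/O.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

GERMLINE_REGIONS <- c("TRAJ", "TRAV", "TRBJ", "TRBV", "TRAC", "TRBC",
                      "IGH-J", "IGL-J")

#' Construct a germline gene record
#'
#' A `germline_gene` holds one annotated germline amino-acid sequence:
#' its name, receptor region (e.g. `TRAJ`), species, one-letter sequence,
#' and optional labelled spans (CDR1/2/3, aCPM, ...) given as 0-based
#' half-open intervals on the ungapped sequence.
#'
#' @param name Identifier (FASTA header word).
#' @param sequence Amino-acid string; one-letter codes, `X` allowed.
#' @param region One of `r paste(GERMLINE_REGIONS, collapse = ", ")`.
#' @param species Free-text species label.
#' @param annotations Optional `data.frame` with columns `start`, `end`,
#'   `label`; 0-based half-open spans on the ungapped sequence.
#' @return An object of class `germline_gene`.
#' @export
germline_gene <- function(name, sequence, region, species = "unknown",
                          annotations = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  region <- match.arg(region, GERMLINE_REGIONS)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("germline gene '", name, "': empty sequence", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET)
  if (length(bad)) {
    stop("germline gene '", name, "': illegal residue character(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("start", "end", "label") %in% names(annotations)))
    annotations$start <- as.integer(annotations$start)
    annotations$end <- as.integer(annotations$end)
    n <- nchar(sequence)
    if (any(annotations$start < 0L) || any(annotations$end > n) ||
        any(annotations$end < annotations$start)) {
      stop("germline gene '", name, "': annotation span outside sequence ",
           "bounds or negative length", call. = FALSE)
    }
  }
  structure(list(name = name, region = region, species = species,
                 sequence = sequence, annotations = annotations),
            class = "germline_gene")
}

#' @export
print.germline_gene <- function(x, ...) {
  cat(sprintf("<germline_gene> %s [%s, %s] %d aa\n", x$name, x$region,
              x$species, nchar(x$sequence)))
  invisible(x)
}

#' Read germline amino-acid sequences from FASTA
#'
#' One `germline_gene` is produced per record, in file order, with the
#' supplied region and species attached. Wrapped (multi-line) FASTA is
#' accepted; header text after the first whitespace is dropped.
#'
#' @param path Path to an amino-acid FASTA file.
#' @param region Region label applied to every record.
#' @param species Species label applied to every record.
#' @return List of [germline_gene()] objects.
#' @export
read_germline_fasta <- function(path, region, species = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not FASTA-formatted: ", path,
                                           call. = FALSE))
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  nm <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  lapply(seq_along(set), function(i) {
    germline_gene(nm[i], as.character(set[[i]]), region = region,
                  species = species)
  })
}

#' Write germline genes to FASTA
#'
#' @param genes List of [germline_gene()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(genes, path) {
  seqs <- Biostrings::AAStringSet(vapply(genes, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(genes, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read annotation spans from a BED-like TSV
#'
#' Expected columns (tab-separated, with header): `name`, `start`, `end`,
#' `label`; coordinates are 0-based half-open on the ungapped sequence.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with those four columns.
#' @export
read_annotations_tsv <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end", "label") %in% names(ann)))
  ann
}

#' Attach annotation spans to germline genes
#'
#' @param genes List of [germline_gene()] objects.
#' @param annotations `data.frame` as returned by [read_annotations_tsv()].
#' @return The gene list with per-gene `annotations` filled in (genes
#'   absent from the table get an empty annotation table).
#' @export
attach_annotations <- function(genes, annotations) {
  lapply(genes, function(g) {
    a <- annotations[annotations$name == g$name, c("start", "end", "label"),
                     drop = FALSE]
    germline_gene(g$name, g$sequence, g$region, g$species,
                  annotations = a)
  })
}
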