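#' Construct a circular genome object
#'
#' The package analyses one circular replicon at a time; every coordinate is
#' 0-based and interpreted modulo the genome length `L`.
#'
#' @param length Genome length in base pairs (`L`). Must be a single positive
#'   integer-valued number.
#' @param name Replicon identifier.
#' @param sequence Optional nucleotide sequence (single character string of
#'   exactly `length` characters, alphabet ACGT).
#' @return An object of class `redc_genome`: a list with elements `name`,
#'   `length`, `circular` (always `TRUE`) and `sequence` (possibly `NULL`).
#' @export
redc_genome <- function(length, name = "replicon", sequence = NULL) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length <= 0 || length != floor(length)) {
    stop("genome length must be a single positive integer")
  }
  length <- as.numeric(length)
  if (!is.null(sequence)) {
    if (!is.character(sequence) || length(sequence) != 1L) {
      stop("sequence must be a single character string")
    }
    if (nchar(sequence) != length) {
      stop(sprintf("sequence length (%d) does not equal genome length (%d)",
                   nchar(sequence), length))
    }
  }
  structure(
    list(name = name, length = length, circular = TRUE, sequence = sequence),
    class = "redc_genome"
  )
}

#' @export
print.redc_genome <- function(x, ...) {
  cat(sprintf("Circular genome '%s': %s bp%s\n", x$name,
              format(x$length, big.mark = ",", scientific = FALSE),
              if (is.null(x$sequence)) " (no sequence)" else ""))
  invisible(x)
}

#' Load a genome from a FASTA file
#'
#' Exactly one record is required: the pipeline supports a single circular
#' replicon per run, and multi-replicon input is rejected explicitly.
#'
#' @param path Path to a FASTA file with exactly one sequence record.
#' @return A [redc_genome()] object with the sequence attached.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  if (length(seqs) > 1L) {
    stop("unsupported replicon structure: expected exactly one record, found ",
         length(seqs))
  }
  if (Biostrings::width(seqs)[1] == 0L) stop("empty sequence in ", path)
  nm <- sub("\\s.*$", "", names(seqs)[1])
  redc_genome(length = Biostrings::width(seqs)[1], name = nm,
              sequence = as.character(seqs[[1]]))
}

#' Write a genome to a FASTA file
#'
#' @param genome A [redc_genome()] with a sequence.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "redc_genome"))
  if (is.null(genome$sequence)) stop("genome has no sequence to write")
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Shortest-arc distance on a circular genome
#'
#' For coordinates `a` and `b` on a circle of length `L`, computes
#' `d1 = |a - b|`, `d2 = |d1 - L|` and returns the lesser of the two: the
#' length of the shorter arc between the points. Vectorised over `a` and `b`.
#'
#' @param a,b Coordinates in `[0, L)` (0-based; recycled to common length).
#' @param L Genome length in bp.
#' @return Numeric vector of distances in `[0, L/2]`.
#' @export
circular_distance <- function(a, b, L) {
  if (any(a < 0 | a >= L, na.rm = TRUE) || any(b < 0 | b >= L, na.rm = TRUE)) {
    stop("coordinates must lie in [0, L)")
  }
  d1 <- abs(a - b)
  d2 <- abs(d1 - L)
  pmin(d1, d2)
}

#' Midpoint of a gene on a circular genome
#'
#' Non-wrapping genes use `floor((start + end) / 2)`; the floor tie-break makes
#' interval membership deterministic. Genes wrapping the origin
#' (`start > end`) use the modular midpoint of the unwrapped interval.
#'
#' @param gene A single-row gene record (list or data.frame row) with `start`
#'   and `end` (0-based half-open), or a genes data.frame (vectorised).
#' @param L Genome length in bp.
#' @return Midpoint coordinate(s) in `[0, L)`.
#' @export
gene_middle <- function(gene, L) {
  start <- gene$start
  end <- gene$end
  wrap <- start > end
  end2 <- ifelse(wrap, end + L, end)
  floor((start + end2) / 2) %% L
}

# offset of position `pos` from `origin` walking forward (increasing
# coordinates) on the circle; result in [0, L)
.fwd_offset <- function(pos, origin, L) {
  (pos - origin) %% L
}
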