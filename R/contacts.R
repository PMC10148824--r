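# split possibly origin-wrapping gene intervals into linear IRanges rows,
# keeping a map back to the gene row index
.gene_ranges <- function(genes, L) {
  wrap <- genes$start > genes$end
  nw <- which(!wrap)
  w <- which(wrap)
  starts <- c(genes$start[nw], genes$start[w], rep(0, length(w)))
  ends <- c(genes$end[nw], rep(L, length(w)), genes$end[w])
  idx <- c(nw, w, w)
  list(ranges = IRanges::IRanges(start = starts + 1L, end = ends), idx = idx)
}

#' Assign RNA 3' portions to source genes
#'
#' The RNA 3'-end coordinate (a single point) must fall inside the gene body
#' and the RNA portion must map to the strand opposite to that of the gene,
#' as the ligation chemistry dictates. Contacts whose 3' end overlaps more
#' than one qualifying gene are flagged ambiguous and left unassigned;
#' intergenic or same-strand contacts are simply unassigned.
#'
#' @param contacts Contact data.frame with `rna3_pos` and `rna3_strand`.
#' @param genes Gene table (see [annotation-tables]).
#' @param L Genome length.
#' @return `contacts` with `gene_id`, `rna_class` (of the source gene) and
#'   logical `ambiguous` columns added.
#' @export
assign_rna_to_genes <- function(contacts, genes, L) {
  n <- nrow(contacts)
  contacts$gene_id <- rep(NA_character_, n)
  contacts$rna_class <- rep(NA_character_, n)
  contacts$ambiguous <- rep(FALSE, n)
  if (n == 0L || nrow(genes) == 0L) return(contacts)
  gr <- .gene_ranges(genes, L)
  pts <- IRanges::IRanges(start = contacts$rna3_pos + 1L, width = 1L)
  ov <- IRanges::findOverlaps(pts, gr$ranges)
  if (length(ov) == 0L) return(contacts)
  qh <- S4Vectors::queryHits(ov)
  gi <- gr$idx[S4Vectors::subjectHits(ov)]
  # opposite-strand rule
  qual <- contacts$rna3_strand[qh] != genes$strand[gi]
  qh <- qh[qual]; gi <- gi[qual]
  if (length(qh) == 0L) return(contacts)
  nhit <- tabulate(qh, nbins = n)
  uniq <- nhit[qh] == 1L
  contacts$gene_id[qh[uniq]] <- genes$gene_id[gi[uniq]]
  contacts$rna_class[qh[uniq]] <- genes$rna_class[gi[uniq]]
  contacts$ambiguous[unique(qh[!uniq])] <- TRUE
  contacts
}

#' Whole-genome contact profile of one RNA
#'
#' DNA anchors of all contacts assigned to a single gene, binned along the
#' genome.
#'
#' @param contacts Assigned contact table (see [assign_rna_to_genes()]).
#' @param gene_id Source gene identifier.
#' @param L Genome length.
#' @param bin_size Bin width in bp.
#' @param genes Optional gene table; when given, an unknown `gene_id` is an
#'   error (a known gene with zero contacts yields a zero vector).
#' @return Numeric vector of per-bin counts (length `ceiling(L/bin_size)`);
#'   its sum equals the RNA's total assigned contacts.
#' @export
build_rna_profile <- function(contacts, gene_id, L, bin_size = 100,
                              genes = NULL) {
  if (!"gene_id" %in% names(contacts)) stop("contacts are not gene-assigned")
  if (!is.null(genes) && !gene_id %in% genes$gene_id) {
    stop("unknown gene_id: ", gene_id)
  }
  sel <- !is.na(contacts$gene_id) & contacts$gene_id == gene_id
  n_bins <- ceiling(L / bin_size)
  v <- numeric(n_bins)
  if (any(sel)) {
    b <- floor(contacts$dna_pos[sel] / bin_size) + 1L
    tb <- tabulate(b, nbins = n_bins)
    v <- as.numeric(tb)
  }
  v
}

#' Build a binned RNA-source x DNA-target contact matrix
#'
#' Rows index the bin of the RNA 3'-end position, columns the bin of the DNA
#' anchor. The matrix is held sparse; its total equals the number of
#' contributing contacts.
#'
#' @param contacts Contact table with `rna3_pos` and `dna_pos`.
#' @param L Genome length.
#' @param bin_size Bin width in bp (default 100, the working map resolution).
#' @return Object of class `contact_matrix`: list with `counts`
#'   (dgCMatrix), `bin_size`, `L`, `n_bins`.
#' @export
build_contact_map <- function(contacts, L, bin_size = 100) {
  if (bin_size <= 0) stop("bin_size must be positive")
  n_bins <- as.integer(ceiling(L / bin_size))
  if (nrow(contacts) > 0L) {
    i <- floor(contacts$rna3_pos / bin_size) + 1L
    j <- floor(contacts$dna_pos / bin_size) + 1L
    counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                   dims = c(n_bins, n_bins))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(n_bins, n_bins))
  }
  structure(list(counts = counts, bin_size = bin_size, L = L, n_bins = n_bins),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("RNA-DNA contact matrix: %d x %d bins of %g bp (L = %s), %s contacts\n",
              x$n_bins, x$n_bins, x$bin_size, format(x$L, big.mark = ",", scientific = FALSE),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Heatmap of a contact-matrix region
#'
#' @param x A `contact_matrix`.
#' @param from,to Genomic range to display in bp (defaults to whole genome;
#'   keep it small at fine resolutions).
#' @param log Show log10(1 + count).
#' @param ... Passed to [graphics::image()].
#' @export
plot.contact_matrix <- function(x, from = 0, to = x$L, log = TRUE, ...) {
  b1 <- floor(from / x$bin_size) + 1L
  b2 <- min(ceiling(to / x$bin_size), x$n_bins)
  m <- as.matrix(x$counts[b1:b2, b1:b2, drop = FALSE])
  if (log) m <- log10(1 + m)
  graphics::image(x = seq(from, to, length.out = nrow(m)),
                  y = seq(from, to, length.out = ncol(m)),
                  z = m, xlab = "RNA 3' position (bp)",
                  ylab = "DNA anchor (bp)", useRaster = TRUE, ...)
  invisible(x)
}

# Pearson correlation of two flattened sparse matrices without densifying
.sparse_pearson <- function(a, b) {
  n <- prod(dim(a))
  sx <- sum(a); sy <- sum(b)
  sxx <- sum(a * a); syy <- sum(b * b); sxy <- sum(a * b)
  num <- sxy - sx * sy / n
  den <- sqrt((sxx - sx^2 / n) * (syy - sy^2 / n))
  if (den == 0) return(NA_real_)
  as.numeric(num / den)
}

#' Merge two replicate contact maps
#'
#' Element-wise sum of two maps on the same grid, with the Pearson
#' correlation of the flattened matrices reported as a reproducibility score.
#'
#' @param mapA,mapB `contact_matrix` objects with identical `L` and
#'   `bin_size`.
#' @return List with `map` (merged `contact_matrix`) and `correlation`.
#' @export
merge_replicates <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "contact_matrix"), inherits(mapB, "contact_matrix"))
  if (mapA$bin_size != mapB$bin_size || mapA$L != mapB$L) {
    stop("replicate maps must share bin_size and L")
  }
  merged <- mapA
  merged$counts <- mapA$counts + mapB$counts
  list(map = merged, correlation = .sparse_pearson(mapA$counts, mapB$counts))
}

# --- disk formats ----------------------------------------------------------

#' Write / read a contacts TSV
#'
#' The on-disk layout extends the read-processing output with the assignment
#' columns when present.
#'
#' @param contacts Contact data.frame.
#' @param path File path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_contacts_tsv <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts_tsv
#' @export
read_contacts_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a contact matrix as a sparse-triplet TSV
#'
#' Header comment lines record `L` and `bin_size`; body columns are
#' `row_bin`, `col_bin` (0-based), `count`. The round trip is bit-exact.
#'
#' @param map A `contact_matrix`.
#' @param path File path.
#' @export
write_contact_matrix <- function(map, path) {
  stopifnot(inherits(map, "contact_matrix"))
  tm <- methods::as(map$counts, "TsparseMatrix")
  ord <- order(tm@i, tm@j)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# L=%.0f", map$L),
               sprintf("# bin_size=%.0f", map$bin_size),
               "row_bin\tcol_bin\tcount"), con)
  if (length(tm@i)) {
    writeLines(sprintf("%d\t%d\t%.0f", tm@i[ord], tm@j[ord], tm@x[ord]), con)
  }
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  hdr <- readLines(path, n = 2L)
  L <- as.numeric(sub("# L=", "", hdr[1], fixed = TRUE))
  bin_size <- as.numeric(sub("# bin_size=", "", hdr[2], fixed = TRUE))
  tab <- utils::read.delim(path, skip = 2L)
  n_bins <- as.integer(ceiling(L / bin_size))
  counts <- Matrix::sparseMatrix(i = tab$row_bin + 1L, j = tab$col_bin + 1L,
                                 x = tab$count, dims = c(n_bins, n_bins))
  structure(list(counts = counts, bin_size = bin_size, L = L, n_bins = n_bins),
            class = "contact_matrix")
}
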