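#' Gene and operon tables
#'
#' Genes are stored as a plain data.frame with columns `gene_id`, `start`,
#' `end` (0-based half-open), `strand` ("+"/"-"), `rna_class` (one of
#' `r paste(RNA_CLASSES, collapse = ", ")`), and optionally `operon_id` and
#' `rank` (1-based position in transcription order within the operon).
#' A gene wrapping the replicon origin is stored with `start > end`.
#'
#' Operons are a data.frame with columns `operon_id`, `start`, `end`,
#' `strand`; member genes point at them through `genes$operon_id`.
#'
#' @name annotation-tables
NULL

#' Recognised RNA classes
#' @export
RNA_CLASSES <- c("mRNA", "rRNA16S", "rRNA23S", "rRNA5S", "tRNA", "6S", "other")

#' Pooled ribosomal RNA classes
#' @export
RRNA_CLASSES <- c("rRNA16S", "rRNA23S", "rRNA5S")

.validate_genes <- function(genes, L) {
  need <- c("gene_id", "start", "end", "strand", "rna_class")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("unknown strand character in gene table (must be '+' or '-')")
  }
  if (any(genes$start < 0 | genes$start >= L | genes$end < 0 | genes$end > L)) {
    stop("gene coordinates outside [0, L]")
  }
  if (any(genes$start == genes$end)) stop("zero-length gene in table")
  if (any(!genes$rna_class %in% RNA_CLASSES)) {
    stop("unknown rna_class value(s): ",
         paste(unique(setdiff(genes$rna_class, RNA_CLASSES)), collapse = ", "))
  }
  invisible(genes)
}

# Mapping from annotation feature type / biotype text to the internal RNA
# class. Product/Name strings are consulted for rRNA subunits and for the
# 6S RNA gene (ssrS in E. coli).
.infer_rna_class <- function(type, attrs) {
  type <- tolower(type)
  attrs <- tolower(attrs)
  cls <- rep("other", length(type))
  cls[type %in% c("gene", "cds", "mrna")] <- "mRNA"
  cls[type == "trna"] <- "tRNA"
  is_rrna <- type == "rrna"
  cls[is_rrna & grepl("16s", attrs)] <- "rRNA16S"
  cls[is_rrna & grepl("23s", attrs)] <- "rRNA23S"
  cls[is_rrna & grepl("5s", attrs)] <- "rRNA5S"
  cls[grepl("6s rna|\\bssrs\\b|\\b6s\\b", attrs)] <- "6S"
  cls
}

#' Load gene annotation from GFF3 or BED
#'
#' Coordinates are normalised to the package's internal 0-based half-open
#' convention at the boundary (GFF3 is 1-based closed, BED already 0-based
#' half-open). The RNA class of each feature is taken from an explicit
#' `rna_class` GFF attribute when present, otherwise inferred from the feature
#' type and product/Name attributes; BED names may carry the class as an
#' `id:class` suffix.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param genome A [redc_genome()]; used for coordinate validation.
#' @param operons Optional path to an operon sidecar TSV (see
#'   [load_operons()]); member genes are matched by `gene_id`.
#' @return A list with elements `genes` (data.frame) and `operons`
#'   (data.frame or `NULL`).
#' @export
load_annotation <- function(path, genome, operons = NULL) {
  stopifnot(inherits(genome, "redc_genome"))
  L <- genome$length
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff"
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) == 0L) stop("no features in annotation: ", path)
  start1 <- GenomicRanges::start(gr)   # 1-based closed from rtracklayer
  end1 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand character in annotation (must be '+' or '-')")
  }
  if (any(start1 < 1 | end1 > L)) {
    stop("annotation coordinates outside [1, L]")
  }
  md <- S4Vectors::mcols(gr)
  if (fmt == "bed") {
    nm <- if ("name" %in% names(md)) as.character(md$name) else
      sprintf("feat%05d", seq_along(gr))
    parts <- strsplit(nm, ":", fixed = TRUE)
    gene_id <- vapply(parts, `[`, "", 1L)
    cls <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "mRNA", "")
  } else {
    gene_id <- if ("ID" %in% names(md)) as.character(md$ID) else
      if ("Name" %in% names(md)) as.character(md$Name) else
        sprintf("feat%05d", seq_along(gr))
    if ("rna_class" %in% names(md) && !all(is.na(md$rna_class))) {
      cls <- as.character(md$rna_class)
    } else {
      extra <- paste(if ("product" %in% names(md)) as.character(md$product) else "",
                     if ("Name" %in% names(md)) as.character(md$Name) else "")
      cls <- .infer_rna_class(as.character(md$type), extra)
    }
  }
  genes <- data.frame(
    gene_id = gene_id,
    start = start1 - 1L,          # to 0-based half-open
    end = end1,
    strand = strand,
    rna_class = cls,
    stringsAsFactors = FALSE
  )
  .validate_genes(genes, L)
  ops <- NULL
  if (!is.null(operons)) {
    loaded <- load_operons(operons, genome)
    ops <- loaded$operons
    m <- match(genes$gene_id, loaded$members$gene_id)
    genes$operon_id <- loaded$members$operon_id[m]
    genes$rank <- loaded$members$rank[m]
  }
  list(genes = genes, operons = ops)
}

#' Write a gene table as GFF3
#'
#' Internal 0-based half-open coordinates convert back to GFF3 1-based closed
#' at the boundary; the RNA class is stored in an `rna_class` attribute so the
#' round trip is the identity.
#'
#' @param genes Gene data.frame (see [annotation-tables]).
#' @param genome A [redc_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(genes, genome, path) {
  .validate_genes(genes, genome$length)
  type_of <- c(mRNA = "gene", rRNA16S = "rRNA", rRNA23S = "rRNA",
               rRNA5S = "rRNA", tRNA = "tRNA", `6S` = "ncRNA", other = "ncRNA")
  lines <- sprintf(
    "%s\tredcontacts\t%s\t%d\t%d\t.\t%s\t.\tID=%s;rna_class=%s",
    genome$name, type_of[genes$rna_class],
    genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$rna_class
  )
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", genome$name, genome$length),
               lines), path)
  invisible(path)
}

#' Load operon definitions from a sidecar TSV
#'
#' Operons are supplied, never inferred: the sidecar has one row per member
#' gene with columns `operon_id`, `gene_id`, `rank` (1-based transcription
#' order), `start`, `end`, `strand`, where `start`/`end`/`strand` describe the
#' operon extent (repeated on every member row).
#'
#' @param path TSV path.
#' @param genome A [redc_genome()].
#' @return List with `operons` (one row per operon) and `members` (one row per
#'   member gene).
#' @export
load_operons <- function(path, genome) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("operon_id", "gene_id", "rank", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("operon sidecar lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(!tab$strand %in% c("+", "-"))) stop("unknown strand in operon sidecar")
  if (any(tab$start < 0 | tab$end > genome$length)) {
    stop("operon coordinates outside [0, L]")
  }
  first <- !duplicated(tab$operon_id)
  operons <- data.frame(
    operon_id = tab$operon_id[first],
    start = tab$start[first],
    end = tab$end[first],
    strand = tab$strand[first],
    n_genes = as.vector(table(tab$operon_id)[tab$operon_id[first]]),
    stringsAsFactors = FALSE
  )
  list(operons = operons,
       members = tab[order(tab$operon_id, tab$rank),
                     c("operon_id", "gene_id", "rank")])
}

#' Write an operon sidecar TSV
#'
#' @param operons Operon data.frame.
#' @param genes Gene data.frame carrying `operon_id` and `rank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_operons_tsv <- function(operons, genes, path) {
  memb <- genes[!is.na(genes$operon_id), c("gene_id", "operon_id", "rank")]
  m <- match(memb$operon_id, operons$operon_id)
  out <- data.frame(
    operon_id = memb$operon_id,
    gene_id = memb$gene_id,
    rank = memb$rank,
    start = operons$start[m],
    end = operons$end[m],
    strand = operons$strand[m],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$operon_id, out$rank), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
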