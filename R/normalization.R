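# wrap-aware gene-body membership of DNA anchors: [start, end), flanks
# excluded
.anchor_in_body <- function(pos, start, end, L) {
  if (start <= end) pos >= start & pos < end else pos >= start | pos < end
}

#' Transcriptional-activity estimate of a protein-coding gene
#'
#' The number of contacts that the gene's own mRNA establishes near the gene:
#' DNA anchors within `window` bp (circular distance, closed edge) of the
#' gene middle. This near-gene contact count tracks the cellular mRNA level.
#'
#' @param contacts Assigned contact table.
#' @param gene One-row gene record, or a gene_id present in `genes`.
#' @param L Genome length.
#' @param window Half-width of the activity window in bp (default 5,000).
#' @param genes Optional gene table used to resolve a `gene_id` given as
#'   `gene`; an unknown id is an error.
#' @return Integer contact count.
#' @export
gene_activity <- function(contacts, gene, L, window = 5000, genes = NULL) {
  if (is.character(gene)) {
    if (is.null(genes)) stop("supply `genes` to resolve a gene_id")
    hit <- genes[genes$gene_id == gene, , drop = FALSE]
    if (nrow(hit) != 1L) stop("unknown gene: ", gene)
    gene <- hit
  }
  mid <- gene_middle(gene, L)
  sel <- !is.na(contacts$gene_id) & contacts$gene_id == gene$gene_id
  if (!any(sel)) return(0L)
  sum(circular_distance(contacts$dna_pos[sel], mid, L) <= window)
}

#' Distal-mRNA background contacts of a gene
#'
#' Counts mRNA contacts whose DNA anchor lies inside the gene body and whose
#' RNA 3' end originates from a remote genomic region (circular distance from
#' the gene middle greater than `min_dist`). These "came-from-afar" mRNA
#' fragments estimate nonspecific background ligation, absorbing gene length,
#' cross-linking, digestion and mappability biases.
#'
#' @param contacts Assigned contact table.
#' @param gene One-row gene record.
#' @param L Genome length; must exceed `2 * min_dist` or the distal region is
#'   empty.
#' @param min_dist Distance threshold in bp (default 250,000).
#' @return Integer contact count.
#' @export
background_count <- function(contacts, gene, L, min_dist = 250000) {
  if (L <= 2 * min_dist) {
    stop("genome too short for the distal-background rule (need L > ",
         2 * min_dist, ")")
  }
  mid <- gene_middle(gene, L)
  sel <- !is.na(contacts$rna_class) & contacts$rna_class == "mRNA" &
    !is.na(contacts$gene_id)
  pos <- contacts$dna_pos[sel]
  r3 <- contacts$rna3_pos[sel]
  inb <- .anchor_in_body(pos, gene$start, gene$end, L)
  sum(inb & circular_distance(r3, mid, L) > min_dist)
}

#' Background-normalized contacts of a target RNA with protein-coding genes
#'
#' For every protein-coding gene, counts the DNA anchors of all contacts made
#' by the target RNA class (pooled ribosomal RNA, or 6S RNA) inside the gene
#' body, normalizes by the distal-mRNA background count of the same gene, and
#' attaches the activity estimate. Genes with background below
#' `min_background` are flagged excluded and get no ratio.
#'
#' @param contacts Assigned contact table.
#' @param target_class `"rRNA"` (pools 16S, 23S and 5S) or `"6S"`.
#' @param genes Gene table.
#' @param L Genome length.
#' @param min_background Minimum background count for inclusion (default 10).
#' @param min_dist Distal-background distance threshold in bp.
#' @param activity_window Activity half-window in bp.
#' @return data.frame (class `norm_gene_table`): `gene_id`, `length`,
#'   `target_count`, `background_count`, `ratio`, `activity`, `included`.
#' @export
normalized_gene_contacts <- function(contacts, target_class = c("rRNA", "6S"),
                                     genes, L, min_background = 10,
                                     min_dist = 250000,
                                     activity_window = 5000) {
  target_class <- match.arg(target_class)
  target_set <- if (target_class == "rRNA") RRNA_CLASSES else "6S"
  pc <- genes[genes$rna_class == "mRNA", , drop = FALSE]
  if (nrow(pc) == 0L) stop("no protein-coding genes in the table")
  if (L <= 2 * min_dist) {
    stop("genome too short for the distal-background rule (need L > ",
         2 * min_dist, ")")
  }

  is_target <- !is.na(contacts$rna_class) & contacts$rna_class %in% target_set
  tpos <- contacts$dna_pos[is_target]

  is_mrna <- !is.na(contacts$rna_class) & contacts$rna_class == "mRNA" &
    !is.na(contacts$gene_id)
  bpos <- contacts$dna_pos[is_mrna]
  br3 <- contacts$rna3_pos[is_mrna]

  gr <- .gene_ranges(pc, L)
  count_in_bodies <- function(pos, extra_filter = NULL) {
    out <- integer(nrow(pc))
    if (length(pos) == 0L) return(out)
    pts <- IRanges::IRanges(start = pos + 1L, width = 1L)
    ov <- IRanges::findOverlaps(pts, gr$ranges)
    qh <- S4Vectors::queryHits(ov)
    gi <- gr$idx[S4Vectors::subjectHits(ov)]
    if (!is.null(extra_filter)) {
      keep <- extra_filter(qh, gi)
      qh <- qh[keep]; gi <- gi[keep]
    }
    tab <- tabulate(gi, nbins = nrow(pc))
    tab
  }

  target_count <- count_in_bodies(tpos)
  mids <- gene_middle(pc, L)
  bg_count <- count_in_bodies(bpos, extra_filter = function(qh, gi) {
    circular_distance(br3[qh], mids[gi], L) > min_dist
  })

  own <- contacts[!is.na(contacts$gene_id), c("gene_id", "dna_pos")]
  act <- integer(nrow(pc))
  if (nrow(own) > 0L) {
    grp <- split(own$dna_pos, own$gene_id)
    hit <- match(pc$gene_id, names(grp))
    for (i in which(!is.na(hit))) {
      act[i] <- sum(circular_distance(grp[[hit[i]]], mids[i], L) <=
                      activity_window)
    }
  }

  included <- bg_count >= min_background
  out <- data.frame(
    gene_id = pc$gene_id,
    length = (pc$end - pc$start) %% L,
    target_count = target_count,
    background_count = bg_count,
    ratio = ifelse(included, target_count / bg_count, NA_real_),
    activity = act,
    included = included,
    stringsAsFactors = FALSE
  )
  attr(out, "target_class") <- target_class
  class(out) <- c("norm_gene_table", "data.frame")
  out
}

#' Correlate background-normalized contacts with gene activity
#'
#' Pearson correlation and linear regression of the normalized contact ratio
#' against the activity estimate, over all included genes or the
#' highest-activity decile. Values are log10(x+1)-transformed by default.
#'
#' @param table A `norm_gene_table`, or a numeric vector `x` when `y` is
#'   given.
#' @param y Optional response vector paired with a numeric `table`.
#' @param subset `"all"` or `"top10"` (highest-activity decile).
#' @param scale `"log"` (log10(x+1)) or `"raw"`.
#' @return List of class `activity_correlation`: `r`, `p`, `slope`,
#'   `intercept`, `n`, `subset`, `scale`.
#' @export
correlate_activity <- function(table, y = NULL, subset = c("all", "top10"),
                               scale = c("log", "raw")) {
  subset <- match.arg(subset)
  scale <- match.arg(scale)
  if (is.numeric(table) && !is.null(y)) {
    x <- table
  } else {
    stopifnot(inherits(table, "norm_gene_table"))
    tab <- table[table$included, , drop = FALSE]
    x <- tab$activity
    y <- tab$ratio
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (subset == "top10") {
    keep <- order(x, decreasing = TRUE)[seq_len(ceiling(0.1 * length(x)))]
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3L) stop("fewer than 3 paired values after subsetting")
  if (scale == "log") {
    x <- log10(x + 1)
    y <- log10(y + 1)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x), subset = subset, scale = scale),
            class = "activity_correlation")
}

#' @export
print.activity_correlation <- function(x, ...) {
  cat(sprintf(
    "Pearson r = %.3f (p = %.3g, n = %d, subset = %s, %s scale)\nregression: slope = %.3g, intercept = %.3g\n",
    x$r, x$p, x$n, x$subset, x$scale, x$slope, x$intercept))
  invisible(x)
}

#' Correlate per-gene contact counts with an external expression table
#'
#' Joins an expression table (columns `gene_id`, `value`) against the per-gene
#' assigned-contact totals and reports the Pearson correlation on
#' log10(x+1)-transformed values, the standard check that contact counts per
#' mRNA track transcript abundance.
#'
#' @param contacts Assigned contact table.
#' @param expression A data.frame with `gene_id` and `value`, or a path to a
#'   TSV with those columns.
#' @param genes Gene table; only protein-coding genes enter the comparison.
#' @return An `activity_correlation` object.
#' @export
correlate_with_expression <- function(contacts, expression, genes) {
  if (is.character(expression)) {
    expression <- utils::read.delim(expression, stringsAsFactors = FALSE)
  }
  if (!all(c("gene_id", "value") %in% names(expression))) {
    stop("expression table needs columns gene_id and value")
  }
  pc <- genes$gene_id[genes$rna_class == "mRNA"]
  tot <- table(factor(contacts$gene_id[!is.na(contacts$gene_id)], levels = pc))
  m <- match(pc, expression$gene_id)
  ok <- !is.na(m)
  correlate_activity(as.numeric(expression$value[m[ok]]),
                     as.numeric(tot[ok]), subset = "all", scale = "log")
}
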