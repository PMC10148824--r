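# measure of the overlap between a set of linear arcs [s, e) on the circle
# (possibly wrapping) and the set of positions at circular distance [a, b)
# from `mid`; used to correct interval lengths for masked loci
.mask_band_overlap <- function(mask, mid, a, b, L) {
  if (is.null(mask) || nrow(mask) == 0L) return(0)
  # offset space o = (p - mid) mod L; band = [a, b) on the right arm plus
  # (L - b, L - a] on the left arm
  pieces <- list()
  for (k in seq_len(nrow(mask))) {
    os <- (mask$start[k] - mid) %% L
    oe <- os + ((mask$end[k] - mask$start[k]) %% L)
    if (oe <= L) pieces[[length(pieces) + 1L]] <- c(os, oe)
    else {
      pieces[[length(pieces) + 1L]] <- c(os, L)
      pieces[[length(pieces) + 1L]] <- c(0, oe - L)
    }
  }
  band <- list(c(a, b), c(L - b, L - a))
  tot <- 0
  for (p in pieces) for (bd in band) {
    tot <- tot + max(0, min(p[2], bd[2]) - max(p[1], bd[1]))
  }
  tot
}

.in_mask <- function(pos, mask, L) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(mask))) {
    s <- mask$start[k]; e <- mask$end[k]
    hit <- hit | if (s <= e) pos >= s & pos < e else pos >= s | pos < e
  }
  hit
}

#' Cis/trans interval preference of one RNA
#'
#' Counts the RNA's DNA anchors in four consecutive genomic intervals
#' measured by circular distance from the middle of the encoding gene
#' (by default within 5 kb; 5-50 kb; 50-500 kb, both sides pooled; and
#' beyond 500 kb), converts counts to frequencies per bp of interval, and
#' expresses them relative to the RNA's genome-average contact frequency
#' (total contacts / genome length). Optionally a set of masked loci is
#' excluded from both the counts and the interval lengths (used for rRNA,
#' whose parental operons are unmappable in real data).
#'
#' @param contacts Assigned contact table.
#' @param gene One-row gene record (the encoding gene).
#' @param L Genome length; must exceed 1 Mb for the canonical edges.
#' @param mask Optional data.frame of excluded intervals (`start`, `end`,
#'   0-based half-open, may wrap).
#' @param edges Inner interval edges in bp (half-open on circular distance).
#' @param min_contacts Reporting threshold on the RNA's total contacts; an
#'   RNA below it is computed anyway but flagged `filtered_out`.
#' @return data.frame (class `interval_preference`) with one row per
#'   interval: `interval`, `d_lo`, `d_hi`, `length`, `count`, `freq`,
#'   `rel_freq`; attributes `total`, `total_used`, `filtered_out`.
#' @export
interval_preference <- function(contacts, gene, L, mask = NULL,
                                edges = c(5000, 50000, 500000),
                                min_contacts = 500) {
  if (L / 2 <= max(edges)) {
    stop("genome too short for these interval edges (need L > ",
         2 * max(edges), ")")
  }
  mid <- gene_middle(gene, L)
  sel <- !is.na(contacts$gene_id) & contacts$gene_id == gene$gene_id
  pos <- contacts$dna_pos[sel]
  total <- length(pos)
  masked <- .in_mask(pos, mask, L)
  pos_used <- pos[!masked]

  lo <- c(0, edges)
  hi <- c(edges, L / 2)
  d <- circular_distance(pos_used, mid, L)
  # half-open bands [lo, hi), except the outermost which is closed at L/2
  band <- findInterval(d, c(lo, L / 2), rightmost.closed = TRUE)
  count <- tabulate(band, nbins = 4L)

  len <- c(2 * edges[1],
           2 * (edges[2] - edges[1]),
           2 * (edges[3] - edges[2]),
           L - 2 * edges[3])
  mask_len_tot <- 0
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (i in 1:4) {
      ov <- .mask_band_overlap(mask, mid, lo[i], hi[i], L)
      len[i] <- len[i] - ov
      mask_len_tot <- mask_len_tot + ov
    }
  }
  total_used <- length(pos_used)
  avg <- total_used / (L - mask_len_tot)
  freq <- ifelse(len > 0, count / len, NA_real_)
  out <- data.frame(
    interval = c("I1", "I2", "I3", "I4"),
    d_lo = lo, d_hi = hi, length = len, count = count,
    freq = freq,
    rel_freq = if (avg > 0) freq / avg else rep(NA_real_, 4L),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  attr(out, "total_used") <- total_used
  attr(out, "filtered_out") <- total < min_contacts
  class(out) <- c("interval_preference", "data.frame")
  out
}

#' Interval-preference table over all sufficiently covered RNAs
#'
#' @param contacts Assigned contact table.
#' @param genes Gene table.
#' @param L Genome length.
#' @param mask,edges,min_contacts See [interval_preference()]; only RNAs with
#'   at least `min_contacts` assigned contacts are included here.
#' @return data.frame with one row per RNA: `rna_id`, `rna_class`, `total`,
#'   `count_I1..I4`, `relfreq_I1..I4`.
#' @export
interval_preference_table <- function(contacts, genes, L, mask = NULL,
                                      edges = c(5000, 50000, 500000),
                                      min_contacts = 500) {
  tot <- table(contacts$gene_id[!is.na(contacts$gene_id)])
  keep <- names(tot)[tot >= min_contacts]
  rows <- lapply(keep, function(g) {
    gene <- genes[genes$gene_id == g, , drop = FALSE]
    if (nrow(gene) != 1L) return(NULL)
    ip <- interval_preference(contacts, gene, L, mask = mask, edges = edges,
                              min_contacts = min_contacts)
    stats_row <- data.frame(rna_id = g, rna_class = gene$rna_class,
                            total = attr(ip, "total"),
                            stringsAsFactors = FALSE)
    stats_row[paste0("count_", ip$interval)] <- as.list(ip$count)
    stats_row[paste0("relfreq_", ip$interval)] <- as.list(ip$rel_freq)
    stats_row
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Upstream/downstream side and distance of a contact
#'
#' Determines whether the DNA anchor lies upstream or downstream of the RNA
#' 3'-end coordinate with respect to the direction of transcription, on the
#' shorter arc of the circle. Implements the eight-case rule: with
#' `diff = rna - dna`, `d1 = |diff|`, `d2 = |d1 - L|`, a sense-strand contact
#' is upstream when (`diff > 0` and `d1 < d2`) or (`diff < 0` and
#' `d1 >= d2`), downstream otherwise; antisense mirrors the signs. The
#' coincident case `rna == dna` has distance 0, is assigned downstream by
#' convention, and is flagged `tie` so callers can exclude it.
#'
#' @param rna3_pos,dna_pos Coordinate vectors in `[0, L)`.
#' @param gene_strand `"+"` (sense) or `"-"` (antisense) per contact.
#' @param L Genome length.
#' @return data.frame with `side` (`"upstream"`/`"downstream"`), `distance`
#'   (shorter-arc bp) and `tie`.
#' @export
updown_assign <- function(rna3_pos, dna_pos, gene_strand, L) {
  if (any(!gene_strand %in% c("+", "-"))) stop("unknown strand")
  if (any(rna3_pos < 0 | rna3_pos >= L | dna_pos < 0 | dna_pos >= L)) {
    stop("coordinates must lie in [0, L)")
  }
  diff <- rna3_pos - dna_pos
  d1 <- abs(diff)
  d2 <- abs(d1 - L)
  near <- d1 < d2
  sense <- gene_strand == "+"
  up <- (diff > 0 & near) | (diff < 0 & !near)
  up[!sense] <- ((diff < 0 & near) | (diff > 0 & !near))[!sense]
  side <- ifelse(diff == 0, "downstream",
                 ifelse(up, "upstream", "downstream"))
  data.frame(side = side, distance = pmin(d1, d2), tie = diff == 0,
             stringsAsFactors = FALSE)
}

# doubling distance-bin edges 0, 64, 128, 256, ... capped at L/2
.updown_edges <- function(L) {
  e <- 64
  edges <- c(0)
  while (e < L / 2) {
    edges <- c(edges, e)
    e <- e * 2
  }
  c(edges, L / 2)
}

#' Upstream/downstream contact-frequency profile of nascent mRNA
#'
#' Restricts to contacts whose RNA 3' portion is assigned to a protein-coding
#' gene (proper-strand rule), assigns each to an upstream or downstream
#' distance bin of doubling width ([0,64), [64,128), [128,256), ...), and
#' reports per-bin frequencies (count / bin length) and the
#' downstream/upstream frequency ratio.
#'
#' @param contacts Assigned contact table.
#' @param genes Gene table (for the encoding-gene strand).
#' @param L Genome length.
#' @param drop_ties Exclude coincident (`rna == dna`) contacts.
#' @return data.frame (class `updown_profile`): `bin_lo`, `bin_hi`,
#'   `up_count`, `down_count`, `up_freq`, `down_freq`, `ratio`.
#' @export
updown_frequency_profile <- function(contacts, genes, L, drop_ties = FALSE) {
  sel <- !is.na(contacts$gene_id) & !is.na(contacts$rna_class) &
    contacts$rna_class == "mRNA"
  cc <- contacts[sel, , drop = FALSE]
  edges <- .updown_edges(L)
  nb <- length(edges) - 1L
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    up_count = 0L, down_count = 0L)
  if (nrow(cc) > 0L) {
    strand <- genes$strand[match(cc$gene_id, genes$gene_id)]
    ud <- updown_assign(cc$rna3_pos, cc$dna_pos, strand, L)
    if (drop_ties) ud <- ud[!ud$tie, , drop = FALSE]
    bin <- findInterval(ud$distance, edges, rightmost.closed = TRUE)
    bin[bin > nb] <- nb
    up <- ud$side == "upstream"
    out$up_count <- tabulate(bin[up], nbins = nb)
    out$down_count <- tabulate(bin[!up], nbins = nb)
  }
  w <- out$bin_hi - out$bin_lo
  out$up_freq <- out$up_count / w
  out$down_freq <- out$down_count / w
  out$ratio <- ifelse(out$up_count > 0, out$down_freq / out$up_freq, NA_real_)
  class(out) <- c("updown_profile", "data.frame")
  out
}

#' @export
plot.updown_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  mids <- sqrt(pmax(x$bin_lo, 1) * x$bin_hi)
  graphics::matplot(mids, cbind(x$up_freq, x$down_freq), log = "xy",
                    type = "b", pch = c(1, 16), lty = 1,
                    xlab = "", ylab = "contacts / bp", ...)
  graphics::legend("topright", c("upstream", "downstream"), pch = c(1, 16))
  graphics::plot(mids, x$ratio, log = "x", type = "b", pch = 16,
                 xlab = "distance (bp)", ylab = "down / up ratio")
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Cumulative operon contact maps
#'
#' Each operon with flanking regions of half-operon length is divided into 24
#' equal bins (the operon spans the central 12); proper-strand mRNA contacts
#' with both the RNA 3' end and the DNA anchor inside the window increment
#' the (RNA bin, DNA bin) cell of that operon's 24 x 24 matrix. Matrices are
#' summed in genomic (unflipped) orientation, separately for operons
#' transcribed in the sense and antisense direction.
#'
#' @param contacts Assigned contact table.
#' @param operons Operon table.
#' @param L Genome length.
#' @return List of class `operon_map_set`: `sense`, `antisense` (24 x 24
#'   matrices), `n_sense`, `n_antisense`.
#' @export
operon_cumulative_map <- function(contacts, operons, L) {
  sel <- !is.na(contacts$gene_id) & !is.na(contacts$rna_class) &
    contacts$rna_class == "mRNA"
  cc <- contacts[sel, , drop = FALSE]
  maps <- list(`+` = matrix(0, 24, 24), `-` = matrix(0, 24, 24))
  n_ops <- c(`+` = 0L, `-` = 0L)
  for (k in seq_len(nrow(operons))) {
    oplen <- (operons$end[k] - operons$start[k]) %% L
    if (oplen == 0) {
      warning("skipping zero-length operon ", operons$operon_id[k])
      next
    }
    strand <- operons$strand[k]
    n_ops[strand] <- n_ops[strand] + 1L
    if (nrow(cc) == 0L) next
    wstart <- (operons$start[k] - oplen / 2) %% L
    wlen <- 2 * oplen
    off_r <- (cc$rna3_pos - wstart) %% L
    off_d <- (cc$dna_pos - wstart) %% L
    inw <- off_r < wlen & off_d < wlen
    if (!any(inw)) next
    bw <- wlen / 24
    bi <- pmin(floor(off_r[inw] / bw), 23)
    bj <- pmin(floor(off_d[inw] / bw), 23)
    add <- tabulate(bj * 24L + bi + 1L, nbins = 576L)
    maps[[strand]] <- maps[[strand]] + matrix(add, 24, 24)
  }
  structure(list(sense = maps[["+"]], antisense = maps[["-"]],
                 n_sense = n_ops[["+"]], n_antisense = n_ops[["-"]]),
            class = "operon_map_set")
}

#' Write a 24 x 24 operon map as TSV
#'
#' Header comments record the orientation class and the number of operons
#' summed.
#'
#' @param maps An `operon_map_set`.
#' @param orientation `"sense"` or `"antisense"`.
#' @param path File path.
#' @export
write_operon_map <- function(maps, orientation = c("sense", "antisense"),
                             path) {
  orientation <- match.arg(orientation)
  m <- maps[[orientation]]
  n <- if (orientation == "sense") maps$n_sense else maps$n_antisense
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# orientation=%s", orientation),
               sprintf("# n_operons=%d", n)), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fraction of off-diagonal operon-map mass above the diagonal
#'
#' Summary used to quantify the triangular pattern of nascent polycistronic
#' transcription: for sense operons mass accumulates above the main diagonal
#' (DNA bin beyond RNA bin), for antisense operons below.
#'
#' @param m A 24 x 24 matrix.
#' @return Fraction of total window mass strictly above the diagonal.
#' @export
above_diagonal_fraction <- function(m) {
  tot <- sum(m)
  if (tot == 0) return(NA_real_)
  sum(m[upper.tri(m)]) / tot
}
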