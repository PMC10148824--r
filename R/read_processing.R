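#' Scan a batch of read pairs for bridge, GGG tag and portion boundaries
#'
#' The DNA portion is the forward-read region upstream of the first bridge
#' occurrence; the RNA 3' portion is the region downstream of the bridge,
#' truncated at the first CCC occurrence when `trim_ccc` is on (the CCC run
#' marks read-through into the template-switch tail); the RNA 5' portion is
#' the reverse-read region downstream of the first GGG. Rejections are data,
#' not errors: each pair carries a reason code.
#'
#' @param fwd,rev Character vectors of forward/reverse read sequences.
#' @param bridge Bridge adapter sequence.
#' @param max_mismatch Mismatches tolerated in the bridge match (0 or 1).
#' @param trim_ccc Truncate the RNA 3' portion at the first CCC occurrence.
#' @param dna_len_range Accepted DNA-portion lengths before CATG reattachment.
#' @param min_rna Minimum accepted RNA portion length.
#' @param read_id Optional read identifiers.
#' @return data.frame with `read_id`, `dna_seq`, `rna3_seq`, `rna5_seq`,
#'   portion offsets, `ok` and `reason` (`""`, `no_bridge`, `no_ggg`,
#'   `dna_len`, `rna3_short`, `rna5_short`).
#' @export
scan_reads <- function(fwd, rev, bridge, max_mismatch = 0, trim_ccc = TRUE,
                       dna_len_range = c(18L, 20L), min_rna = 10L,
                       read_id = NULL) {
  stopifnot(length(fwd) == length(rev))
  n <- length(fwd)
  if (is.null(read_id)) read_id <- sprintf("read%07d", seq_len(n))
  blen <- nchar(bridge)

  if (max_mismatch == 0) {
    bpos <- regexpr(bridge, fwd, fixed = TRUE)  # 1-based, -1 if absent
  } else {
    m <- Biostrings::vmatchPattern(bridge, Biostrings::DNAStringSet(fwd),
                                   max.mismatch = max_mismatch)
    st <- Biostrings::startIndex(m)
    bpos <- vapply(st, function(s) if (length(s)) min(s) else -1L, 0L)
  }
  gpos <- regexpr("GGG", rev, fixed = TRUE)

  dna_seq <- ifelse(bpos > 0, substr(fwd, 1L, bpos - 1L), "")
  rna3_seq <- ifelse(bpos > 0, substr(fwd, bpos + blen, nchar(fwd)), "")
  if (trim_ccc) {
    cpos <- regexpr("CCC", rna3_seq, fixed = TRUE)
    has_c <- cpos > 0
    rna3_seq[has_c] <- substr(rna3_seq[has_c], 1L, cpos[has_c] - 1L)
  }
  rna5_seq <- ifelse(gpos > 0, substr(rev, gpos + 3L, nchar(rev)), "")

  reason <- character(n)
  reason[gpos <= 0] <- "no_ggg"
  reason[bpos <= 0] <- "no_bridge"   # bridge failure takes precedence
  dl <- nchar(dna_seq)
  len_bad <- reason == "" & (dl < dna_len_range[1] | dl > dna_len_range[2])
  reason[len_bad] <- "dna_len"
  reason[reason == "" & nchar(rna3_seq) < min_rna] <- "rna3_short"
  reason[reason == "" & nchar(rna5_seq) < min_rna] <- "rna5_short"

  data.frame(read_id = read_id, dna_seq = dna_seq, rna3_seq = rna3_seq,
             rna5_seq = rna5_seq,
             dna_offset = 0L,
             rna3_offset = ifelse(bpos > 0, bpos + blen - 1L, NA_integer_),
             rna5_offset = ifelse(gpos > 0, gpos + 2L, NA_integer_),
             ok = reason == "", reason = reason,
             stringsAsFactors = FALSE)
}

#' Scan a single read pair
#'
#' Convenience wrapper around [scan_reads()] for one forward/reverse pair.
#'
#' @inheritParams scan_reads
#' @return A one-row data.frame (see [scan_reads()]).
#' @export
scan_read_pair <- function(fwd, rev, bridge, max_mismatch = 0, ...) {
  if (!nzchar(fwd) || !nzchar(rev)) stop("empty read")
  scan_reads(fwd, rev, bridge, max_mismatch = max_mismatch, ...)
}

#' Reattach the blunted NlaIII overhang to DNA portions
#'
#' The restriction overhang (CATG) removed during library preparation is
#' appended computationally, extending 18-20 nt portions to 22-24 nt and
#' improving unique mapping.
#'
#' @param dna_seq Character vector of DNA portions, each 18-20 nt.
#' @return The extended sequences.
#' @export
reattach_catg <- function(dna_seq) {
  len <- nchar(dna_seq)
  if (any(len < 18L | len > 20L)) {
    stop("DNA portion length outside [18, 20]: cannot reattach CATG")
  }
  paste0(dna_seq, "CATG")
}

#' Build an exact-match index over both strands of a circular genome
#'
#' @param genome A [redc_genome()] with sequence.
#' @param margin Origin overlap in bp (must exceed the longest query).
#' @return An object of class `redc_genome_index`.
#' @export
genome_index <- function(genome, margin = 300L) {
  stopifnot(inherits(genome, "redc_genome"))
  if (is.null(genome$sequence)) stop("genome has no sequence to index")
  concat <- paste0(genome$sequence, substr(genome$sequence, 1, margin))
  structure(list(subject = Biostrings::DNAString(concat),
                 L = genome$length, margin = margin),
            class = "redc_genome_index")
}

# occurrences of each pattern in the circular subject; returns list of
# 0-based forward-strand start vectors (one element per pattern)
.match_starts <- function(seqs, index, tb_width) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs),
                          tb.start = 1L, tb.end = tb_width)
  m <- Biostrings::matchPDict(pd, index$subject)
  st <- Biostrings::startIndex(m)
  L <- index$L
  lapply(st, function(s) {
    if (is.null(s)) integer(0) else (s[s <= L]) - 1L
  })
}

#' Map portions to the genome by exact search over both strands
#'
#' A portion is `unique` if it has exactly one exact occurrence counting both
#' strands, `multi` if more, `unmapped` if none. Reverse-strand hits are
#' reported with the position of the match's leftmost base on the forward
#' strand. Sequences containing non-ACGT characters are `unmapped`.
#'
#' @param seqs Character vector of portions (each at least 10 nt).
#' @param index A [genome_index()].
#' @return data.frame with `pos` (0-based leftmost forward-strand base, NA
#'   unless unique), `strand`, `width`, `n_hits`, `status`.
#' @export
map_portions <- function(seqs, index) {
  stopifnot(inherits(index, "redc_genome_index"))
  n <- length(seqs)
  out <- data.frame(pos = rep(NA_real_, n), strand = NA_character_,
                    width = nchar(seqs), n_hits = 0L,
                    status = "unmapped", stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  valid <- !is.na(seqs) & nchar(seqs) >= 10L & !grepl("[^ACGT]", seqs)
  if (!any(valid)) return(out)
  vs <- seqs[valid]
  fw <- .match_starts(vs, index, 10L)
  rc <- .match_starts(.revcomp(vs), index, 10L)
  nf <- lengths(fw)
  nr <- lengths(rc)
  tot <- nf + nr
  status <- ifelse(tot == 0L, "unmapped", ifelse(tot > 1L, "multi", "unique"))
  pos <- rep(NA_real_, length(vs))
  strand <- rep(NA_character_, length(vs))
  uf <- tot == 1L & nf == 1L
  ur <- tot == 1L & nr == 1L
  pos[uf] <- vapply(fw[uf], `[`, 0L, 1L)
  strand[uf] <- "+"
  pos[ur] <- vapply(rc[ur], `[`, 0L, 1L)
  strand[ur] <- "-"
  out$pos[valid] <- pos
  out$strand[valid] <- strand
  out$n_hits[valid] <- tot
  out$status[valid] <- status
  out
}

#' Map a single portion
#'
#' @param seq A single sequence (at least 10 nt).
#' @param index A [genome_index()].
#' @return One-row data.frame as in [map_portions()].
#' @export
map_portion <- function(seq, index) {
  if (nchar(seq) < 10L) stop("sequence shorter than the index seed (10 nt)")
  map_portions(seq, index)
}

#' Template-switch proximity/strand filter
#'
#' A mapped triple is accepted only when the RNA 3' and RNA 5' portions lie
#' within `max_gap` of each other on the circle and map to opposite strands;
#' violations indicate intermolecular template switching of the reverse
#' transcriptase.
#'
#' @param rna3_pos,rna3_strand,rna5_pos,rna5_strand Mapped RNA portion
#'   positions and strands (vectors).
#' @param L Genome length.
#' @param max_gap Maximum tolerated circular distance in bp (default 10,000).
#' @return data.frame with `ok` and `reason` (`""`, `far_apart`,
#'   `same_strand`).
#' @export
filter_triple <- function(rna3_pos, rna3_strand, rna5_pos, rna5_strand, L,
                          max_gap = 10000) {
  d <- circular_distance(rna3_pos, rna5_pos, L)
  reason <- character(length(d))
  reason[d > max_gap] <- "far_apart"
  reason[reason == "" & rna3_strand == rna5_strand] <- "same_strand"
  data.frame(ok = reason == "", reason = reason, stringsAsFactors = FALSE)
}

# RNA 3'-end coordinate from a unique mapping: the portion's first base is
# the cDNA of the RNA 3' end, so a "-" hit puts the 3' end at the rightmost
# forward-strand base, a "+" hit at the leftmost
.rna3_end_coord <- function(pos, strand, width, L) {
  ifelse(strand == "-", (pos + width - 1) %% L, pos)
}

# DNA anchor: position of the extended portion's end adjoining the NlaIII
# site, exclusive on the forward strand for "+" hits
.dna_anchor_coord <- function(pos, strand, width, L) {
  ifelse(strand == "+", (pos + width) %% L, pos)
}

#' Run the full read-filtering and mapping cascade
#'
#' Scans read pairs, applies the length filters, reattaches CATG, maps the
#' three portions independently, keeps triples in which all three map
#' uniquely, and applies the template-switch proximity/strand filter. The
#' per-stage survivor counts mirror the processing-statistics layout of the
#' protocol.
#'
#' @param fastq_fwd,fastq_rev Paths to the paired FASTQ files.
#' @param genome A [redc_genome()] with sequence (or a prebuilt
#'   [genome_index()]).
#' @param bridge Bridge adapter sequence.
#' @param max_mismatch Bridge mismatch tolerance.
#' @param trim_ccc Truncate RNA 3' portions at the first CCC (see
#'   [scan_reads()]); disable for synthetic reads that carry no
#'   template-switch tail.
#' @param max_gap Proximity-filter threshold in bp.
#' @return List with `contacts` (data.frame: `read_id`, `rna3_pos`,
#'   `rna3_strand`, `rna5_pos`, `rna5_strand`, `dna_pos`, `dna_strand`) and
#'   `stats` (data.frame `step`, `n`; monotone non-increasing).
#' @export
process_run <- function(fastq_fwd, fastq_rev, genome, bridge,
                        max_mismatch = 0, trim_ccc = TRUE, max_gap = 10000) {
  idx <- if (inherits(genome, "redc_genome_index")) genome else
    genome_index(genome)
  L <- idx$L
  fwd <- Biostrings::readDNAStringSet(fastq_fwd, format = "fastq")
  rev <- Biostrings::readDNAStringSet(fastq_rev, format = "fastq")
  if (length(fwd) != length(rev)) stop("unequal number of forward/reverse reads")
  ids <- sub("\\s.*$", "", names(fwd))

  empty <- data.frame(read_id = character(0), rna3_pos = numeric(0),
                      rna3_strand = character(0), rna5_pos = numeric(0),
                      rna5_strand = character(0), dna_pos = numeric(0),
                      dna_strand = character(0), stringsAsFactors = FALSE)
  steps <- c("total_pairs", "bridge_ggg_found", "portion_lengths_ok",
             "triple_unique", "proximity_strand_pass")
  if (length(fwd) == 0L) {
    return(list(contacts = empty,
                stats = data.frame(step = steps, n = 0L)))
  }

  sc <- scan_reads(as.character(fwd), as.character(rev), bridge,
                   max_mismatch = max_mismatch, trim_ccc = trim_ccc,
                   read_id = ids)
  n_total <- nrow(sc)
  n_bridge <- sum(!sc$reason %in% c("no_bridge", "no_ggg"))
  n_len <- sum(sc$ok)

  keep <- sc[sc$ok, , drop = FALSE]
  if (nrow(keep) > 0L) {
    dna_ext <- reattach_catg(keep$dna_seq)
    mdna <- map_portions(dna_ext, idx)
    mr3 <- map_portions(keep$rna3_seq, idx)
    mr5 <- map_portions(keep$rna5_seq, idx)
    all_unique <- mdna$status == "unique" & mr3$status == "unique" &
      mr5$status == "unique"
  } else {
    all_unique <- logical(0)
  }
  n_unique <- sum(all_unique)

  if (n_unique > 0L) {
    ku <- which(all_unique)
    rna3_pos <- .rna3_end_coord(mr3$pos[ku], mr3$strand[ku], mr3$width[ku], L)
    rna5_pos <- mr5$pos[ku] %% L
    dna_pos <- .dna_anchor_coord(mdna$pos[ku], mdna$strand[ku],
                                 mdna$width[ku], L)
    ft <- filter_triple(rna3_pos, mr3$strand[ku], rna5_pos, mr5$strand[ku],
                        L, max_gap = max_gap)
    contacts <- data.frame(
      read_id = keep$read_id[ku][ft$ok],
      rna3_pos = rna3_pos[ft$ok],
      rna3_strand = mr3$strand[ku][ft$ok],
      rna5_pos = rna5_pos[ft$ok],
      rna5_strand = mr5$strand[ku][ft$ok],
      dna_pos = dna_pos[ft$ok],
      dna_strand = mdna$strand[ku][ft$ok],
      stringsAsFactors = FALSE
    )
    rejected <- data.frame(read_id = keep$read_id[ku][!ft$ok],
                           reason = ft$reason[!ft$ok],
                           stringsAsFactors = FALSE)
  } else {
    contacts <- empty
    rejected <- data.frame(read_id = character(0), reason = character(0))
  }

  stats <- data.frame(step = steps,
                      n = c(n_total, n_bridge, n_len, n_unique,
                            nrow(contacts)))
  list(contacts = contacts, stats = stats, rejected = rejected)
}

#' Ingest externally produced portion alignments from a SAM file
#'
#' Escape hatch for real data aligned with an external program: reads a
#' plain-text SAM file of portion alignments and returns them in the
#' [map_portions()] layout (0-based leftmost position, strand from FLAG 0x10,
#' `unique` unless the record is unmapped (FLAG 0x4) or carries mapping
#' quality 0, which conventionally marks multi-mappers).
#'
#' @param path SAM file path.
#' @return data.frame with `read_id`, `pos`, `strand`, `width`, `status`.
#' @export
read_portions_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(0), pos = numeric(0),
                      strand = character(0), width = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  mapq <- vapply(f, function(x) as.integer(x[5]), 0L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  status <- ifelse(unmapped, "unmapped", ifelse(mapq == 0L, "multi", "unique"))
  data.frame(
    read_id = vapply(f, `[`, "", 1L),
    pos = ifelse(unmapped, NA_real_, vapply(f, function(x) as.numeric(x[4]), 0) - 1),
    strand = ifelse(unmapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    width = vapply(f, function(x) nchar(x[10]), 0L),
    status = status,
    stringsAsFactors = FALSE
  )
}
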