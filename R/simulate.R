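#' Configuration for the synthetic RedC data generator
#'
#' The generator emulates the biological structure of a stationary-phase
#' bacterial RNA-DNA interactome on a single circular replicon: operonic
#' protein-coding genes whose nascent transcripts are dragged by RNA
#' polymerase to the operon end, ribosomal RNA spread genome-wide with
#' enrichment proportional to gene activity, 6S RNA depleted from active
#' genes, and tRNA contacting the genome uniformly. Defaults define the
#' generator's reference conditions and are not meant to be tuned per run.
#'
#' @param seed Integer seed; every downstream draw is reproducible from it.
#' @param L Genome length in bp. The default 2,400,000 keeps the canonical
#'   four-interval analysis (which needs a >500 kb interval) valid.
#' @param n_operons Number of protein-coding operons.
#' @param genes_per_operon_mean Mean of the geometric distribution of genes
#'   per operon (default 3, a typical bacterial value).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters; defaults give a median of 0.8 kb, the E. coli median.
#' @param expression_meanlog,expression_sdlog Log-normal per-operon
#'   expression level.
#' @param p_cis Probability that an mRNA contact is captured near its
#'   transcription site (the drag model) rather than anywhere in the genome.
#' @param lambda Laplace scale (bp) of local capture noise around the
#'   polymerase position.
#' @param alpha rRNA/activity coupling strength (>= 0): rRNA anchor density is
#'   proportional to `1 + alpha * activity` over gene bodies.
#' @param gamma 6S depletion strength in `[0, 1]`: 6S anchor density is
#'   proportional to `1 - gamma * activity / max(activity)` over gene bodies.
#' @param n_contacts Total number of contacts to draw.
#' @param class_props Named proportions of contacts per RNA class
#'   (`mRNA`, `rRNA`, `tRNA`, `6S`); realised counts match these exactly.
#' @param n_trna Number of tRNA genes.
#' @param bridge Bridge adapter sequence used in emitted reads; the default is
#'   a fixed 30-mer chosen to avoid GGG/CCC runs and, with overwhelming
#'   probability, absence from a random genome.
#' @param ggg_tag Template-switch tag at the start of the reverse read.
#' @param dna_len_range Pre-reattachment DNA-portion lengths (the type IIS
#'   cut leaves 18-20 nt).
#' @param rna3_len_range,rna5_len_range RNA portion lengths in emitted reads.
#' @param fragment_len_range RNA fragment length (distance between the 5' end
#'   read out by the reverse read and the 3' end at the bridge).
#' @param artifact_frac Fraction of emitted read pairs that deliberately
#'   violate the template-switch proximity/strand filter (to exercise it).
#' @param error_rate Per-base substitution rate applied to emitted reads.
#' @param nlaiii_aware If `TRUE`, the contact model itself restricts DNA
#'   anchors to CATG junction positions (reproducing the streaked map
#'   pattern); default `FALSE`, anchors are continuous at the model level.
#' @return A list of class `redc_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              L = 2400000,
                              n_operons = 250,
                              genes_per_operon_mean = 3,
                              gene_length_meanlog = log(800),
                              gene_length_sdlog = 0.45,
                              expression_meanlog = 0,
                              expression_sdlog = 1,
                              p_cis = 0.75,
                              lambda = 200,
                              alpha = 0.5,
                              gamma = 0.5,
                              n_contacts = 100000,
                              class_props = c(mRNA = 0.70, rRNA = 0.15,
                                              tRNA = 0.10, `6S` = 0.05),
                              n_trna = 20,
                              bridge = "GCTGAGGATCGATCGTTAACTCGAGCATTG",
                              ggg_tag = "GGG",
                              dna_len_range = c(18L, 20L),
                              rna3_len_range = c(20L, 35L),
                              rna5_len_range = c(20L, 35L),
                              fragment_len_range = c(50L, 500L),
                              artifact_frac = 0,
                              error_rate = 0,
                              nlaiii_aware = FALSE) {
  stopifnot(L > 0, genes_per_operon_mean >= 1,
            p_cis >= 0, p_cis <= 1, alpha >= 0, gamma >= 0, gamma <= 1,
            lambda >= 0, artifact_frac >= 0, artifact_frac <= 1,
            error_rate >= 0, error_rate < 1)
  if (abs(sum(class_props) - 1) > 1e-8) stop("class_props must sum to 1")
  if (!all(names(class_props) %in% c("mRNA", "rRNA", "tRNA", "6S"))) {
    stop("class_props names must be mRNA, rRNA, tRNA, 6S")
  }
  structure(as.list(environment()), class = "redc_sim_config")
}

# Laplace(0, b) noise
.rlaplace <- function(n, b) {
  if (b == 0) return(numeric(n))
  stats::rexp(n, 1 / b) - stats::rexp(n, 1 / b)
}

#' Simulate a circular genome and its annotation
#'
#' Places non-overlapping operons of protein-coding genes on both strands,
#' one ribosomal locus (16S/23S/5S), `n_trna` tRNA genes and one 6S gene, and
#' writes a random nucleotide sequence. Genes are tiled within operons in
#' transcription order; no simulated gene wraps the origin. Per-operon
#' expression levels are drawn log-normally and shared by member genes.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` ([redc_genome()]), `genes`, `operons`
#'   (data.frames, see [annotation-tables]) and `expression` (named per-operon
#'   vector).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "redc_sim_config"))
  set.seed(config$seed)
  L <- config$L

  n_op <- config$n_operons
  ngenes <- if (n_op > 0) {
    stats::rgeom(n_op, 1 / config$genes_per_operon_mean) + 1L
  } else integer(0)

  blocks <- list()  # each: list(kind, strand, gene_lengths, gaps, classes)
  for (i in seq_len(n_op)) {
    k <- ngenes[i]
    glen <- pmax(150L, round(stats::rlnorm(k, config$gene_length_meanlog,
                                           config$gene_length_sdlog)))
    gaps <- if (k > 1) sample(10:50, k - 1L, replace = TRUE) else integer(0)
    blocks[[length(blocks) + 1L]] <- list(
      kind = "operon", id = sprintf("op%04d", i),
      strand = sample(c("+", "-"), 1L),
      glen = glen, gaps = gaps, classes = rep("mRNA", k)
    )
  }
  # one rRNA locus (16S, 23S, 5S in transcription order), typical lengths
  blocks[[length(blocks) + 1L]] <- list(
    kind = "rrn", id = "rrn", strand = sample(c("+", "-"), 1L),
    glen = c(1542L, 2904L, 120L), gaps = c(60L, 60L),
    classes = c("rRNA16S", "rRNA23S", "rRNA5S")
  )
  for (i in seq_len(config$n_trna)) {
    blocks[[length(blocks) + 1L]] <- list(
      kind = "trna", id = sprintf("trna%02d", i),
      strand = sample(c("+", "-"), 1L),
      glen = 76L, gaps = integer(0), classes = "tRNA"
    )
  }
  blocks[[length(blocks) + 1L]] <- list(
    kind = "sixS", id = "ssrS", strand = sample(c("+", "-"), 1L),
    glen = 183L, gaps = integer(0), classes = "6S"
  )

  block_len <- vapply(blocks, function(b) sum(b$glen) + sum(b$gaps), 0)
  total_mass <- sum(block_len)
  if (total_mass > 0.95 * L) {
    stop(sprintf("requested gene mass (%d bp) exceeds genome capacity (%d bp)",
                 total_mass, L))
  }
  ord <- sample(seq_along(blocks))
  free <- L - total_mass
  w <- stats::rexp(length(blocks) + 1L)
  gaps_between <- floor(free * w / sum(w))

  rows <- vector("list", length(blocks))
  pos <- gaps_between[1]
  for (j in seq_along(ord)) {
    b <- blocks[[ord[j]]]
    k <- length(b$glen)
    starts <- ends <- integer(k)
    p <- pos
    for (g in seq_len(k)) {
      starts[g] <- p
      ends[g] <- p + b$glen[g]
      p <- ends[g] + if (g < k) b$gaps[g] else 0L
    }
    # transcription order: for "-" strand the first transcribed gene is the
    # rightmost one
    rank <- if (b$strand == "+") seq_len(k) else rev(seq_len(k))
    rows[[j]] <- data.frame(
      gene_id = if (k == 1L && b$kind != "operon") b$id else
        sprintf("%s_g%d", b$id, rank),
      start = starts, end = ends, strand = b$strand,
      rna_class = b$classes,
      operon_id = if (b$kind == "operon") b$id else NA_character_,
      rank = if (b$kind == "operon") rank else NA_integer_,
      block_id = b$id, block_start = pos, block_end = p,
      stringsAsFactors = FALSE
    )
    pos <- p + gaps_between[j + 1L]
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$start), ]
  rownames(genes) <- NULL

  op_rows <- genes[!is.na(genes$operon_id) & !duplicated(genes$operon_id), ]
  operons <- data.frame(
    operon_id = op_rows$operon_id,
    start = op_rows$block_start,
    end = op_rows$block_end,
    strand = op_rows$strand,
    stringsAsFactors = FALSE
  )
  operons <- operons[order(operons$start), ]
  rownames(operons) <- NULL
  genes$block_start <- genes$block_end <- genes$block_id <- NULL

  sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
  genome <- redc_genome(L, name = sprintf("sim%d", config$seed),
                        sequence = sequence)

  expression <- stats::rlnorm(nrow(operons), config$expression_meanlog,
                              config$expression_sdlog)
  names(expression) <- operons$operon_id

  list(genome = genome, genes = genes, operons = operons,
       expression = expression)
}

# locate the sorted, non-overlapping mRNA genes covering positions `pos`;
# returns gene row index or NA (simulated genes never wrap the origin)
.pos_to_gene_idx <- function(pos, starts, ends) {
  i <- findInterval(pos, starts)
  i[i == 0L] <- NA_integer_
  hit <- !is.na(i) & pos < ends[pmax(i, 1L)]
  ifelse(hit, i, NA_integer_)
}

#' Simulate ground-truth RNA-DNA contacts
#'
#' Implements the generative contact model. For each mRNA contact of gene `g`
#' in operon `O`: with probability `p_cis` the RNA fragment 3' end `r` is
#' placed uniformly within `g`, the polymerase position is drawn uniformly on
#' the transcribed path from `r` to the end of `O` (downstream drag), and the
#' DNA anchor is that position plus Laplace(0, `lambda`) noise, modulo `L`;
#' otherwise the anchor is uniform on the genome. rRNA anchors have density
#' proportional to `1 + alpha * activity` over gene bodies; 6S anchors to
#' `1 - gamma * activity/max(activity)`; tRNA anchors are uniform. Contact
#' counts per RNA are proportional to expression, and the RNA 3' portion
#' strand is always opposite to the source gene strand.
#'
#' @param config A [simulation_config()].
#' @param genome,genes,operons As returned by [simulate_annotation()].
#' @param expression Named per-operon expression vector.
#' @return data.frame of truth contacts: `contact_id`, `rna_class` (internal
#'   class, e.g. `rRNA16S`), `source_gene_id`, `rna3_pos`, `rna_strand`,
#'   `dna_pos`, `dna_strand`.
#' @export
simulate_contacts <- function(config, genome, genes, operons, expression) {
  stopifnot(inherits(config, "redc_sim_config"))
  set.seed(config$seed + 1000L)
  L <- genome$length
  n <- config$n_contacts

  props <- config$class_props[c("mRNA", "rRNA", "tRNA", "6S")]
  props[is.na(props)] <- 0
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) {  # largest-remainder rule keeps realised proportions exact
    frac <- props * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }

  mg <- genes[genes$rna_class == "mRNA", , drop = FALSE]
  mg <- mg[order(mg$start), ]
  act <- rep(1, nrow(mg))
  if (nrow(mg) > 0) {
    act <- unname(expression[mg$operon_id])
    act <- act / mean(act)   # normalised activity, mean 1 over mRNA genes
  }

  draw_class <- function(cls, n_cls) {
    if (n_cls == 0L) return(NULL)
    if (cls == "mRNA") {
      if (nrow(mg) == 0L) stop("mRNA contacts requested but no mRNA genes")
      gi <- sample.int(nrow(mg), n_cls, replace = TRUE, prob = act)
      r <- mg$start[gi] + floor(stats::runif(n_cls) * (mg$end[gi] - mg$start[gi]))
      cis <- stats::runif(n_cls) < config$p_cis
      dna <- floor(stats::runif(n_cls) * L)
      if (any(cis)) {
        oi <- match(mg$operon_id[gi[cis]], operons$operon_id)
        plus <- operons$strand[oi] == "+"
        ddown <- ifelse(plus, operons$end[oi] - r[cis], r[cis] - operons$start[oi])
        u <- stats::runif(sum(cis))
        pol <- ifelse(plus, r[cis] + u * ddown, r[cis] - u * ddown)
        dna[cis] <- floor(pol + .rlaplace(sum(cis), config$lambda)) %% L
      }
      data.frame(rna_class = "mRNA", source_gene_id = mg$gene_id[gi],
                 rna3_pos = r, gene_strand = mg$strand[gi], dna_pos = dna,
                 stringsAsFactors = FALSE)
    } else {
      src <- switch(cls,
                    rRNA = genes[genes$rna_class %in% RRNA_CLASSES, , drop = FALSE],
                    tRNA = genes[genes$rna_class == "tRNA", , drop = FALSE],
                    `6S` = genes[genes$rna_class == "6S", , drop = FALSE])
      if (nrow(src) == 0L) stop("no source genes for class ", cls)
      glen <- src$end - src$start
      gi <- sample.int(nrow(src), n_cls, replace = TRUE, prob = glen)
      r <- src$start[gi] + floor(stats::runif(n_cls) * glen[gi])
      dna <- switch(cls,
                    rRNA = .sample_rrna_anchor(n_cls, L, mg, act, config$alpha),
                    tRNA = floor(stats::runif(n_cls) * L),
                    `6S` = .sample_sixs_anchor(n_cls, L, mg, act, config$gamma))
      data.frame(rna_class = src$rna_class[gi], source_gene_id = src$gene_id[gi],
                 rna3_pos = r, gene_strand = src$strand[gi], dna_pos = dna,
                 stringsAsFactors = FALSE)
    }
  }

  parts <- Map(draw_class, names(counts), counts)
  truth <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  rownames(truth) <- NULL

  if (config$nlaiii_aware) {
    if (is.null(genome$sequence)) stop("nlaiii_aware requires a genome sequence")
    strand_tmp <- sample(c("+", "-"), nrow(truth), replace = TRUE)
    truth$dna_pos <- .snap_to_catg(truth$dna_pos, strand_tmp, genome)
    truth$dna_strand <- strand_tmp
  } else {
    truth$dna_strand <- sample(c("+", "-"), nrow(truth), replace = TRUE)
  }
  truth$rna_strand <- ifelse(truth$gene_strand == "+", "-", "+")
  truth$gene_strand <- NULL
  truth$contact_id <- sprintf("c%07d", seq_len(nrow(truth)))
  truth[, c("contact_id", "rna_class", "source_gene_id", "rna3_pos",
            "rna_strand", "dna_pos", "dna_strand")]
}

# rRNA anchors: mixture of uniform background and activity-weighted gene mass
.sample_rrna_anchor <- function(n, L, mg, act, alpha) {
  if (alpha == 0 || nrow(mg) == 0L) return(floor(stats::runif(n) * L))
  glen <- mg$end - mg$start
  extra <- alpha * sum(act * glen)
  on_gene <- stats::runif(n) >= L / (L + extra)
  dna <- floor(stats::runif(n) * L)
  k <- sum(on_gene)
  if (k > 0) {
    gi <- sample.int(nrow(mg), k, replace = TRUE, prob = act * glen)
    dna[on_gene] <- mg$start[gi] + floor(stats::runif(k) * glen[gi])
  }
  dna
}

# 6S anchors: thinned uniform draws with acceptance max(0, 1 - gamma * act)
# inside mRNA gene bodies (activity normalised to mean 1, so highly active
# genes can be fully depleted), 1 elsewhere
.sample_sixs_anchor <- function(n, L, mg, act, gamma) {
  if (gamma == 0 || nrow(mg) == 0L) return(floor(stats::runif(n) * L))
  out <- numeric(0)
  starts <- mg$start; ends <- mg$end
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    cand <- floor(stats::runif(m) * L)
    gi <- .pos_to_gene_idx(cand, starts, ends)
    p_acc <- ifelse(is.na(gi), 1,
                    pmax(0, 1 - gamma * act[ifelse(is.na(gi), 1L, gi)]))
    keep <- stats::runif(m) < p_acc
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

# --- read emission ---------------------------------------------------------

# modular substring extraction against a genome string extended past the
# origin; start0 is 0-based, may be negative or >= L as long as the slice
# stays within the overlap margin
.substr_circ <- function(concat, start0, len, L) {
  s <- start0 %% L
  substring(concat, s + 1, s + len)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# snap DNA anchors to the nearest NlaIII-compatible junction: the extended
# DNA portion must end in the genomic CATG it adjoins. CATG is palindromic,
# so for "+" fragments the admissible anchors are (site + 4) and for "-"
# fragments the site starts themselves.
.snap_to_catg <- function(pos, strand, genome) {
  L <- genome$length
  concat <- paste0(genome$sequence, substr(genome$sequence, 1, 3))
  hits <- gregexpr("CATG", concat, fixed = TRUE)[[1]]
  if (hits[1] == -1L) stop("genome contains no CATG site")
  sites <- as.integer(hits) - 1L       # 0-based site starts, in [0, L)
  sites <- sites[sites < L]
  snap_one_set <- function(p, anchors) {
    anchors <- sort(unique(anchors %% L))
    ext <- c(anchors[length(anchors)] - L, anchors, anchors[1] + L)
    i <- findInterval(p, ext)
    lo <- ext[i]; hi <- ext[pmin(i + 1L, length(ext))]
    ifelse(p - lo <= hi - p, lo, hi) %% L
  }
  out <- pos
  plus <- strand == "+"
  if (any(plus)) out[plus] <- snap_one_set(pos[plus], sites + 4L)
  if (any(!plus)) out[!plus] <- snap_one_set(pos[!plus], sites)
  out
}

.add_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  alph <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- sample(alph, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Emit RedC-style paired reads for a truth contact table
#'
#' Builds the forward read as `[DNA portion (18-20 nt, terminal CATG
#' removed)][bridge][cDNA of the RNA fragment, 3' end first]` and the reverse
#' read as `[GGG][transcript 5' segment in sense orientation]`. Because the
#' reattached CATG must match the genome at the ligation junction, each DNA
#' anchor is snapped to the nearest CATG-compatible junction before emission;
#' the returned truth table (and sidecar TSV) records the coordinates actually
#' emitted. A configurable fraction of pairs violates the template-switch
#' proximity/strand expectations so the downstream filter can be exercised;
#' those rows are labelled in the sidecar.
#'
#' @param truth Contact table from [simulate_contacts()].
#' @param genome A [redc_genome()] with sequence.
#' @param genes Gene table (for transcript orientation of the RNA 5' segment).
#' @param config The [simulation_config()] used to generate `truth`.
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_truth.tsv`.
#' @return Invisibly, a list with `fwd`, `rev`, `truth_path` and the emitted
#'   `truth` data.frame (snapped coordinates, `artifact` column added).
#' @export
emit_reads <- function(truth, genome, genes, config, prefix) {
  stopifnot(inherits(config, "redc_sim_config"))
  if (is.null(genome$sequence)) stop("read emission requires a genome sequence")
  set.seed(config$seed + 2000L)
  L <- genome$length
  if (any(truth$rna3_pos < 0 | truth$rna3_pos >= L |
          truth$dna_pos < 0 | truth$dna_pos >= L)) {
    stop("truth coordinates outside genome")
  }
  n <- nrow(truth)
  margin <- 600L
  concat <- paste0(genome$sequence, substr(genome$sequence, 1, margin))

  truth$dna_pos <- .snap_to_catg(truth$dna_pos, truth$dna_strand, genome)

  dlen <- sample(seq(config$dna_len_range[1], config$dna_len_range[2]),
                 n, replace = TRUE)
  plus <- truth$dna_strand == "+"
  dna_part <- character(n)
  # "+": portion covers [a-dlen-4, a-4), genome CATG at [a-4, a)
  dna_part[plus] <- .substr_circ(concat, truth$dna_pos[plus] - dlen[plus] - 4L,
                                 dlen[plus], L)
  # "-": portion is revcomp of [a+4, a+dlen+4), genome CATG at [a, a+4)
  dna_part[!plus] <- .revcomp(.substr_circ(concat, truth$dna_pos[!plus] + 4L,
                                           dlen[!plus], L))

  gstrand <- ifelse(truth$rna_strand == "+", "-", "+")  # source gene strand
  r3len <- sample(seq(config$rna3_len_range[1], config$rna3_len_range[2]),
                  n, replace = TRUE)
  gplus <- gstrand == "+"
  rna3_part <- character(n)
  rna3_part[gplus] <- .revcomp(.substr_circ(
    concat, truth$rna3_pos[gplus] - r3len[gplus] + 1L, r3len[gplus], L))
  rna3_part[!gplus] <- .substr_circ(concat, truth$rna3_pos[!gplus],
                                    r3len[!gplus], L)

  # RNA 5' end of the same fragment, upstream (5'-ward) of the 3' end
  flen <- sample(seq(config$fragment_len_range[1], config$fragment_len_range[2]),
                 n, replace = TRUE)
  artifact <- rep("none", n)
  if (config$artifact_frac > 0) {
    bad <- stats::runif(n) < config$artifact_frac
    kind <- sample(c("far_apart", "same_strand"), n, replace = TRUE)
    artifact[bad] <- kind[bad]
  }
  # mapped-position distance is flen-1 ("+" genes) or flen-r5len ("-" genes);
  # the base offset keeps both beyond the 10 kb proximity filter
  flen[artifact == "far_apart"] <- 10050L +
    floor(stats::runif(sum(artifact == "far_apart")) * 50000)
  r5len <- sample(seq(config$rna5_len_range[1], config$rna5_len_range[2]),
                  n, replace = TRUE)
  f5 <- ifelse(gplus, truth$rna3_pos - flen + 1L, truth$rna3_pos + flen - 1L) %% L
  rna5_part <- character(n)
  rna5_part[gplus] <- .substr_circ(concat, f5[gplus], r5len[gplus], L)
  rna5_part[!gplus] <- .revcomp(.substr_circ(
    concat, f5[!gplus] - r5len[!gplus] + 1L, r5len[!gplus], L))
  ss <- artifact == "same_strand"   # emit rna5 on the rna3 strand instead
  if (any(ss)) rna5_part[ss] <- .revcomp(rna5_part[ss])

  fwd <- paste0(dna_part, config$bridge, rna3_part)
  rev <- paste0(config$ggg_tag, rna5_part)
  fwd <- .add_seq_errors(fwd, config$error_rate)
  rev <- .add_seq_errors(rev, config$error_rate)

  read_id <- paste0("rd_", truth$contact_id)
  f1 <- paste0(prefix, "_R1.fastq")
  f2 <- paste0(prefix, "_R2.fastq")
  qual1 <- strrep("I", nchar(fwd))
  qual2 <- strrep("I", nchar(rev))
  writeLines(paste0("@", read_id, "\n", fwd, "\n+\n", qual1), f1)
  writeLines(paste0("@", read_id, "\n", rev, "\n+\n", qual2), f2)

  out <- truth
  out$read_id <- read_id
  out$artifact <- artifact
  out <- out[, c("read_id", "contact_id", "rna_class", "source_gene_id",
                 "rna3_pos", "rna_strand", "dna_pos", "dna_strand", "artifact")]
  tpath <- paste0(prefix, "_truth.tsv")
  utils::write.table(out, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fwd = f1, rev = f2, truth_path = tpath, truth = out))
}
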