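test_that("updown_assign reproduces the stated worked cases", {
  # sense gene, dna slightly ahead of rna: downstream at 50 bp
  a <- updown_assign(100000, 100050, "+", 1e6)
  expect_equal(a$side, "downstream")
  expect_equal(a$distance, 50)
  # antisense gene, dna behind rna in coordinates: downstream at 50 bp
  b <- updown_assign(100000, 99950, "-", 1e6)
  expect_equal(b$side, "downstream")
  expect_equal(b$distance, 50)
  # sense gene across the origin: the far-branch case
  d <- updown_assign(10, 980, "+", 1000)
  expect_equal(d$side, "upstream")
  expect_equal(d$distance, 30)
  # coincident contact: distance 0, flagged tie
  e <- updown_assign(5, 5, "+", 1000)
  expect_equal(e$distance, 0)
  expect_true(e$tie)
  expect_error(updown_assign(1, 2, "x", 10), "strand")
})

test_that("updown_assign equals the circle-walk oracle exhaustively", {
  for (L in c(11, 64, 101)) {
    grid <- expand.grid(rna = 0:(L - 1), dna = 0:(L - 1),
                        strand = c("+", "-"), stringsAsFactors = FALSE)
    got <- updown_assign(grid$rna, grid$dna, grid$strand, L)
    want_side <- character(nrow(grid))
    want_dist <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      w <- walk_updown(grid$rna[i], grid$dna[i], grid$strand[i], L)
      want_side[i] <- w$side
      want_dist[i] <- w$distance
    }
    expect_identical(got$side, want_side)
    expect_equal(got$distance, want_dist)
  }
})

test_that("doubling distance bins partition [0, L/2]", {
  for (L in c(1000, 131072, 2400000)) {
    edges <- redcontacts:::.updown_edges(L)
    expect_equal(edges[1], 0)
    expect_equal(edges[length(edges)], L / 2)
    expect_true(all(diff(edges) > 0))
    # every admissible distance falls in exactly one bin
    d <- c(0, 1, 63, 64, 100, L / 4, L / 2)
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    expect_true(all(bin >= 1 & bin <= length(edges) - 1))
  }
})

test_that("interval preference arithmetic on a point mass", {
  L <- 2400000
  gene <- data.frame(gene_id = "g", start = 1000000, end = 1001000,
                     strand = "+", rna_class = "mRNA",
                     stringsAsFactors = FALSE)
  mid <- gene_middle(gene, L)
  cc <- data.frame(gene_id = "g",
                   rna3_pos = rep(1000300, 600),
                   dna_pos = round(mid + seq(-4999, 4999, length.out = 600)),
                   stringsAsFactors = FALSE)
  ip <- interval_preference(cc, gene, L)
  # all contacts in I1: relative frequency = L / (2*5kb) = 240
  expect_equal(ip$count, c(600, 0, 0, 0))
  expect_equal(ip$rel_freq[1], L / 10000)
  expect_false(attr(ip, "filtered_out"))
  # length-weighted mean of relative frequencies is 1
  expect_equal(sum(ip$length * ip$rel_freq) / L, 1)
  # too-short genome is a configuration error
  expect_error(interval_preference(cc, gene, 900000), "too short")
  # below-threshold RNA flagged, not an error
  ip2 <- interval_preference(cc[1:10, ], gene, L)
  expect_true(attr(ip2, "filtered_out"))
})

test_that("interval counts and normalization identity hold on simulation", {
  sim <- small_sim()
  L <- sim$cfg$L
  cc <- assign_rna_to_genes(truth_as_contacts(sim$truth), sim$ann$genes, L)
  gid <- names(sort(table(cc$gene_id), decreasing = TRUE))[1]
  gene <- sim$ann$genes[sim$ann$genes$gene_id == gid, ]
  edges <- c(2000, 20000, 80000)   # scaled to the 400 kb test circle
  ip <- interval_preference(cc, gene, L, edges = edges)
  expect_equal(sum(ip$count), attr(ip, "total"))
  expect_equal(sum(ip$length), L)
  expect_equal(sum(ip$length * ip$rel_freq) / L, 1)
})

test_that("masked loci leave counts + masked = total and adjust lengths", {
  sim <- small_sim()
  L <- sim$cfg$L
  cc <- assign_rna_to_genes(truth_as_contacts(sim$truth), sim$ann$genes, L)
  gid <- names(sort(table(cc$gene_id), decreasing = TRUE))[1]
  gene <- sim$ann$genes[sim$ann$genes$gene_id == gid, ]
  mid <- gene_middle(gene, L)
  mask <- data.frame(start = (mid + 3000) %% L, end = (mid + 9000) %% L)
  edges <- c(2000, 20000, 80000)
  ip <- interval_preference(cc, gene, L, edges = edges)
  ipm <- interval_preference(cc, gene, L, mask = mask, edges = edges)
  n_masked <- attr(ip, "total") - attr(ipm, "total_used")
  expect_equal(sum(ipm$count) + n_masked, attr(ip, "total"))
  # 6 kb of mask: 2 kb falls in I1's right arm? no: mask starts at +3000,
  # so 17 kb-band I2 loses [3000,9000) -> 6 kb total
  expect_equal(sum(ip$length) - sum(ipm$length), 6000)
  expect_equal(ipm$length[2], ip$length[2] - 6000)
  # identity still holds on the masked geometry
  expect_equal(sum(ipm$length * ipm$rel_freq) / (L - 6000), 1)
})

test_that("uniform contacts give flat up/down profiles (binomial check)", {
  set.seed(40)
  L <- 8192
  genes <- data.frame(gene_id = "g", start = 0, end = L, strand = "+",
                      rna_class = "mRNA", stringsAsFactors = FALSE)
  n <- 40000
  cc <- data.frame(gene_id = "g", rna_class = "mRNA",
                   rna3_pos = sample(0:(L - 1), n, TRUE),
                   dna_pos = sample(0:(L - 1), n, TRUE),
                   stringsAsFactors = FALSE)
  up <- updown_frequency_profile(cc, genes, L, drop_ties = TRUE)
  # per-bin two-sided binomial test, Bonferroni at alpha 0.01
  ps <- vapply(seq_len(nrow(up)), function(i) {
    k <- up$up_count[i] + up$down_count[i]
    if (k == 0) return(1)
    stats::binom.test(up$up_count[i], k, 0.5)$p.value
  }, 0)
  expect_true(all(ps > 0.01 / nrow(up)))
})

test_that("single contact lands in the right distance bin with freq 1/64", {
  L <- 131072
  genes <- data.frame(gene_id = "g", start = 1000, end = 1200, strand = "+",
                      rna_class = "mRNA", stringsAsFactors = FALSE)
  cc <- data.frame(gene_id = "g", rna_class = "mRNA",
                   rna3_pos = 1100, dna_pos = 1170,
                   stringsAsFactors = FALSE)
  up <- updown_frequency_profile(cc, genes, L)
  row <- up[up$bin_lo == 64, ]
  expect_equal(row$down_count, 1L)
  expect_equal(row$down_freq, 1 / 64)
  expect_equal(sum(up$up_count) + sum(up$down_count), 1L)
})

test_that("operon windows split into 24 bins of window/24", {
  # operon of 1200 bp: window 2400 bp, bin width 100 bp; place one contact
  # per bin boundary and check the diagonal fills
  L <- 100000
  operons <- data.frame(operon_id = "op", start = 10000, end = 11200,
                        strand = "+", stringsAsFactors = FALSE)
  pos <- 10000 - 600 + seq(0, 2300, by = 100)   # window start + k*binw
  cc <- data.frame(gene_id = "g", rna_class = "mRNA",
                   rna3_pos = pos, dna_pos = pos, stringsAsFactors = FALSE)
  om <- operon_cumulative_map(cc, operons, L)
  expect_equal(diag(om$sense), rep(1, 24))
  expect_equal(sum(om$sense), 24)
  expect_equal(om$n_sense, 1L)
})

test_that("drag simulation yields sense mass above and antisense below", {
  sim <- small_sim()
  cc <- assign_rna_to_genes(truth_as_contacts(sim$truth), sim$ann$genes,
                            sim$cfg$L)
  om <- operon_cumulative_map(cc, sim$ann$operons, sim$cfg$L)
  expect_gt(above_diagonal_fraction(om$sense), 0.5)
  expect_lt(above_diagonal_fraction(om$antisense), 0.5)
  # and the map write round-trips through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_operon_map(om, "sense", f)
  m <- as.matrix(utils::read.delim(f, skip = 2, header = FALSE))
  expect_equal(unname(m), om$sense, ignore_attr = TRUE)
})

test_that("operon windows wrapping the origin are handled modularly", {
  L <- 10000
  operons <- data.frame(operon_id = "w", start = 9500, end = 500,
                        strand = "+", stringsAsFactors = FALSE)
  cc <- data.frame(gene_id = "g", rna_class = "mRNA",
                   rna3_pos = c(9800, 100), dna_pos = c(9900, 200),
                   stringsAsFactors = FALSE)
  om <- operon_cumulative_map(cc, operons, L)
  expect_equal(sum(om$sense), 2)
})
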