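BR <- "GCTGAGGATCGATCGTTAACTCGAGCATTG"

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("scan_read_pair extracts the three portions and reasons", {
  set.seed(5)
  dna <- rand_seq(19)
  rna3 <- gsub("CCC", "CAC", rand_seq(40))
  rna5 <- gsub("GGG", "GAG", rand_seq(35))
  sc <- scan_read_pair(paste0(dna, BR, rna3), paste0("GGG", rna5), BR)
  expect_true(sc$ok)
  expect_equal(nchar(sc$dna_seq), 19)
  expect_equal(sc$rna3_seq, rna3)
  expect_equal(sc$rna5_seq, rna5)

  # no bridge in the forward read
  sc2 <- scan_read_pair(rand_seq(80), paste0("GGG", rna5), BR)
  expect_false(sc2$ok)
  expect_equal(sc2$reason, "no_bridge")

  # no GGG in the reverse read
  sc3 <- scan_read_pair(paste0(dna, BR, rna3), gsub("G", "A", rand_seq(30)),
                        BR)
  expect_equal(sc3$reason, "no_ggg")
})

test_that("RNA 3' portion truncates at the first CCC", {
  set.seed(6)
  dna <- rand_seq(19)
  head12 <- gsub("C", "A", rand_seq(12))
  tail20 <- rand_seq(20)
  sc <- scan_read_pair(paste0(dna, BR, head12, "CCC", tail20),
                       paste0("GGG", gsub("GGG", "GAG", rand_seq(30))), BR)
  expect_equal(sc$rna3_seq, head12)
  expect_equal(nchar(sc$rna3_seq), 12)
  # truncation below the minimum length rejects the pair
  sc2 <- scan_read_pair(paste0(dna, BR, "ATATA", "CCC", tail20),
                        paste0("GGG", rand_seq(30)), BR)
  expect_equal(sc2$reason, "rna3_short")
  # trimming can be disabled for tail-free reads
  sc3 <- scan_read_pair(paste0(dna, BR, head12, "CCC", tail20),
                        paste0("GGG", gsub("GGG", "GAG", rand_seq(30))), BR,
                        trim_ccc = FALSE)
  expect_equal(sc3$rna3_seq, paste0(head12, "CCC", tail20))
})

test_that("DNA portion length gate is [18, 20]", {
  set.seed(7)
  rna3 <- gsub("CCC", "ACC", rand_seq(30))
  rna5 <- paste0("GGG", gsub("GGG", "AGG", rand_seq(30)))
  for (n in c(18, 20)) {
    expect_true(scan_read_pair(paste0(rand_seq(n), BR, rna3), rna5, BR)$ok)
  }
  for (n in c(17, 21)) {
    sc <- scan_read_pair(paste0(rand_seq(n), BR, rna3), rna5, BR)
    expect_equal(sc$reason, "dna_len")
  }
})

test_that("reattach_catg extends 18-20 nt to 22-24 nt and enforces bounds", {
  expect_equal(nchar(reattach_catg(strrep("A", 18))), 22)
  expect_equal(nchar(reattach_catg(strrep("A", 20))), 24)
  expect_true(endsWith(reattach_catg(strrep("A", 19)), "CATG"))
  expect_error(reattach_catg(strrep("A", 17)), "\\[18, 20\\]")
  expect_error(reattach_catg(strrep("A", 21)), "\\[18, 20\\]")
})

test_that("map_portions reports unique, multi and unmapped correctly", {
  set.seed(8)
  core <- rand_seq(5000)
  dup <- rand_seq(400)                      # duplicated rRNA-like block
  genome <- redc_genome(5800 + 2 * 400,
                        sequence = paste0(core, dup, rand_seq(800), dup))
  idx <- genome_index(genome)

  probe <- substr(core, 101, 130)           # unique location
  m <- map_portions(probe, idx)
  expect_equal(m$status, "unique")
  expect_equal(m$pos, 100)
  expect_equal(m$strand, "+")

  # reverse-complement query maps to "-" with the same leftmost base
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
  m2 <- map_portions(rc, idx)
  expect_equal(m2$status, "unique")
  expect_equal(m2$pos, 100)
  expect_equal(m2$strand, "-")

  # a read from the duplicated block is multi-mapped
  m3 <- map_portions(substr(dup, 11, 40), idx)
  expect_equal(m3$status, "multi")
  expect_equal(m3$n_hits, 2L)

  # absent sequence
  m4 <- map_portions(strrep("ACGT", 8), idx)
  expect_true(m4$status %in% c("unmapped", "multi"))
  expect_error(map_portion("ACGTACGT", idx), "shorter")
})

test_that("mapping is circular across the origin", {
  set.seed(9)
  s <- rand_seq(3000)
  genome <- redc_genome(3000, sequence = s)
  idx <- genome_index(genome)
  wrap_probe <- paste0(substr(s, 2991, 3000), substr(s, 1, 15))
  m <- map_portions(wrap_probe, idx)
  expect_equal(m$status, "unique")
  expect_equal(m$pos, 2990)
})

test_that("filter_triple applies the 10 kb circular-proximity and strand rules", {
  ft <- filter_triple(1000, "+", 1100, "-", 1e6)
  expect_true(ft$ok)
  ft2 <- filter_triple(1000, "+", 13000, "-", 1e6)
  expect_equal(ft2$reason, "far_apart")
  ft3 <- filter_triple(1000, "+", 1100, "+", 1e6)
  expect_equal(ft3$reason, "same_strand")
  # circular wrap: linearly far, circularly close
  ft4 <- filter_triple(10, "+", 999950, "-", 1e6)
  expect_true(ft4$ok)
  # boundary: exactly 10 kb is accepted
  expect_true(filter_triple(0, "+", 10000, "-", 1e6)$ok)
})

test_that("process_run recovers noiseless contacts exactly", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  sub <- sim$truth[1:2000, ]
  e <- emit_reads(sub, sim$ann$genome, sim$ann$genes, sim$cfg,
                  file.path(d, "run"))
  res <- process_run(e$fwd, e$rev, sim$ann$genome, sim$cfg$bridge,
                     trim_ccc = FALSE)
  expect_gte(nrow(res$contacts) / nrow(sub), 0.99)
  m <- merge(res$contacts, e$truth, by = "read_id")
  expect_true(all(m$dna_pos.x == m$dna_pos.y))
  expect_true(all(m$rna3_pos.x == m$rna3_pos.y))
  expect_true(all(m$rna3_strand == m$rna_strand))
  # stats monotone non-increasing
  expect_true(all(diff(res$stats$n) <= 0))
})

test_that("artifact read pairs are rejected with the correct reason", {
  sim <- small_sim()
  cfg <- sim$cfg
  cfg$artifact_frac <- 0.2
  d <- withr::local_tempdir()
  sub <- sim$truth[1:3000, ]
  e <- emit_reads(sub, sim$ann$genome, sim$ann$genes, cfg,
                  file.path(d, "art"))
  res <- process_run(e$fwd, e$rev, sim$ann$genome, cfg$bridge,
                     trim_ccc = FALSE)
  tr <- e$truth
  bad <- tr$read_id[tr$artifact != "none"]
  expect_gt(length(bad), 100)
  # artifact pairs are absent from the accepted contacts
  expect_length(intersect(res$contacts$read_id, bad), 0)
  # and carry the planted reason code in the rejection table
  rej <- merge(res$rejected, tr[, c("read_id", "artifact")], by = "read_id")
  expect_gt(nrow(rej), 100)
  expect_true(all(rej$reason == rej$artifact))
  # clean pairs are still recovered
  good <- tr$read_id[tr$artifact == "none"]
  expect_gte(length(intersect(res$contacts$read_id, good)) / length(good),
             0.99)
})

test_that("empty input produces an empty table and zero stats", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "e_R1.fastq"); f2 <- file.path(d, "e_R2.fastq")
  file.create(f1); file.create(f2)
  g <- redc_genome(1000, sequence = strrep("ACGT", 250))
  res <- process_run(f1, f2, g, BR)
  expect_equal(nrow(res$contacts), 0)
  expect_true(all(res$stats$n == 0))
})

test_that("SAM ingestion maps flags to the portion-alignment layout", {
  d <- withr::local_tempdir()
  f <- file.path(d, "x.sam")
  writeLines(c("@HD\tVN:1.6",
               "r1\t0\tchr\t101\t60\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
               "r2\t16\tchr\t201\t60\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
               "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTACGTACGTACGT\t*",
               "r4\t0\tchr\t301\t0\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*"), f)
  al <- read_portions_sam(f)
  expect_equal(al$status, c("unique", "unique", "unmapped", "multi"))
  expect_equal(al$pos[1:2], c(100, 200))
  expect_equal(al$strand[1:2], c("+", "-"))
})
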