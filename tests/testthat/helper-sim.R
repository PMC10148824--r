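# Shared small-scale simulation fixture, built once per test run.
# 400 kb circle, 40 operons: big enough for operon/profile structure,
# small enough to emit and process reads in seconds.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 101, L = 400000, n_operons = 40,
                               n_contacts = 20000)
      ann <- simulate_annotation(cfg)
      truth <- simulate_contacts(cfg, ann$genome, ann$genes, ann$operons,
                                 ann$expression)
      cache <<- list(cfg = cfg, ann = ann, truth = truth)
    }
    cache
  }
})

# brute-force shortest-arc oracle: walk the circle in both directions
walk_distance <- function(a, b, L) {
  fwd <- (b - a) %% L
  bwd <- (a - b) %% L
  min(fwd, bwd)
}

# independent up/down oracle: walk in the transcription direction; the
# shorter arc defines the side; exact ties follow the documented convention
# (side from the sign of rna - dna, mirrored for antisense)
walk_updown <- function(rna, dna, strand, L) {
  ddown <- if (strand == "+") (dna - rna) %% L else (rna - dna) %% L
  dup <- L - ddown
  if (rna == dna) return(list(side = "downstream", distance = 0))
  if (ddown < dup) return(list(side = "downstream", distance = ddown))
  if (ddown > dup) return(list(side = "upstream", distance = dup))
  # antipodal tie
  diff <- rna - dna
  side <- if (strand == "+") {
    if (diff > 0) "downstream" else "upstream"
  } else {
    if (diff > 0) "upstream" else "downstream"
  }
  list(side = side, distance = ddown)
}

# truth table -> the contact layout produced by assignment, bypassing reads
truth_as_contacts <- function(truth) {
  data.frame(read_id = truth$contact_id,
             rna3_pos = truth$rna3_pos,
             rna3_strand = truth$rna_strand,
             dna_pos = truth$dna_pos,
             dna_strand = truth$dna_strand,
             stringsAsFactors = FALSE)
}
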