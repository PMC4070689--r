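# Shared fixtures, built in code at load time (kept small so the suite is
# fast).

`%||%` <- function(a, b) if (is.null(a)) b else a

# A primer set over n samples named S1..Sn with distance->=3 barcodes.
fixture_primers <- function(n = 3, seed = 11, ...) {
  barcoded_primer_set(setNames(generate_barcodes(n, seed), paste0("S", seq_len(n))),
                      ...)
}

# A small simulated read set: n_taxa references, a steady community sampled
# on `days`, reads at the given depth/error rate. Returns scenario pieces
# plus the simulated reads and truth.
fixture_simulation <- function(n_taxa = 6, depth = 30, error_rate = 0,
                               days = c(5, 10, 15), seed = 21,
                               fraction_reverse = 0.35,
                               full_length_fraction = 0.8) {
  taxa <- generate_reference_sequences(n_taxa, site_fraction = 0.5, seed = seed)
  config <- reactor_config()
  dyn <- dynamics_spec(setNames(rep(1, n_taxa), taxa$taxon_id),
                       constant_growth(taxa$taxon_id, 1 / config$srt, max(days)))
  truth <- simulate_dynamics(dyn, config, max(days), sampling_days = days)
  barcodes <- generate_barcodes(length(days), seed = seed + 1)
  names(barcodes) <- sprintf("d%03d", days)
  primers <- barcoded_primer_set(barcodes)
  spec <- sequencing_spec(reads_per_sample = depth, error_rate = error_rate,
                          fraction_reverse = fraction_reverse,
                          full_length_fraction = full_length_fraction,
                          seed = seed + 2)
  sim <- sample_reads(truth, taxa, spec, primers)
  list(taxa = taxa, truth = truth, primers = primers, spec = spec,
       sim = sim, config = config)
}

# Brute-force T-RF oracle: scan all windows of recognition length, first hit
# wins; full length only with a detected reverse primer.
oracle_trf <- function(insert, had_rp, fwd, rev, recognition = "GTAC",
                       cut_offset = 2L) {
  full <- paste0(fwd, insert, if (had_rp) revcomp(rev) else "")
  n <- nchar(full); k <- nchar(recognition)
  for (s in seq_len(max(0, n - k + 1))) {
    if (substr(full, s, s + k - 1) == recognition) {
      return(list(trf = s - 1L + cut_offset, status = "cut"))
    }
  }
  if (had_rp) list(trf = n, status = "full_length") else
    list(trf = NA_integer_, status = "excluded")
}
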