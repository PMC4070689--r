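# Synthetic reactor community: reference sequences, biomass dynamics, and
# barcoded read simulation with ground truth.

#' Generate divergent reference amplicon sequences
#'
#' Draws `n_taxa` random amplicon inserts (the region between the forward and
#' reverse primers). A fraction `site_fraction` of them carry at least one
#' occurrence of the restriction recognition sequence (default GTAC, RsaI);
#' the remainder are scrubbed of all occurrences. Any pair of references with
#' pairwise identity of `max_pairwise_identity` or more is rejected and
#' redrawn (bounded retries), so that clustering at 97% is unambiguous.
#'
#' @param n_taxa number of reference taxa (>= 1).
#' @param length_range integer pair, insert length range (default 420-500 nt,
#'   the scale of a 27f/519r amplicon insert read on a 454 instrument).
#' @param site_fraction fraction of taxa carrying the recognition site.
#' @param seed integer seed; output is deterministic given the seed.
#' @param recognition recognition sequence to plant/scrub (default "GTAC").
#' @param max_pairwise_identity rejection threshold (default 0.90).
#' @param max_retries redraw budget per taxon before failing.
#' @return data.frame with columns `taxon_id`, `sequence`, `taxonomy_label`,
#'   `planted_trf` (1-based start of the first recognition site within the
#'   insert, NA when absent).
#' @export
generate_reference_sequences <- function(n_taxa, length_range = c(420L, 500L),
                                         site_fraction = 0.5, seed = 1L,
                                         recognition = "GTAC",
                                         max_pairwise_identity = 0.90,
                                         max_retries = 100L) {
  fail_if(n_taxa < 1, "n_taxa must be >= 1")
  fail_if(length_range[1] < 100 || length_range[2] > 2000 ||
            length_range[1] > length_range[2],
          "length range must lie within [100, 2000]")
  fail_if(site_fraction < 0 || site_fraction > 1, "site_fraction must be in [0, 1]")
  n_site <- round(site_fraction * n_taxa)
  withr::with_seed(seed, {
    seqs <- character(n_taxa)
    for (j in seq_len(n_taxa)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        len <- sample(length_range[1]:length_range[2], 1L)
        s <- random_dna(len)
        if (j <= n_site) {
          if (!grepl(recognition, s, fixed = TRUE)) {
            pos <- sample.int(len - nchar(recognition) + 1L, 1L)
            substr(s, pos, pos + nchar(recognition) - 1L) <- recognition
          }
        } else {
          guard <- 0L
          while (grepl(recognition, s, fixed = TRUE)) {
            p <- regexpr(recognition, s, fixed = TRUE)[1]
            mut <- sample(setdiff(c("A", "C", "G", "T"),
                                  substr(s, p + 1L, p + 1L)), 1L)
            substr(s, p + 1L, p + 1L) <- mut
            guard <- guard + 1L
            if (guard > len) stop("failed to scrub recognition sites")
          }
        }
        # divergence check against accepted references (k-mer screen first)
        divergent <- TRUE
        for (i in seq_len(j - 1L)) {
          shared <- sum(.kmers(s) %in% unique(.kmers(seqs[i])))
          if (!.kmer_can_reach(shared, nchar(s), nchar(seqs[i]),
                               max_pairwise_identity)) next
          if (pairwise_identity(s, seqs[i]) >= max_pairwise_identity) {
            divergent <- FALSE; break
          }
        }
        if (divergent) { seqs[j] <- s; ok <- TRUE; break }
      }
      if (!ok) stop("could not generate ", n_taxa,
                    " mutually divergent references within retry budget",
                    call. = FALSE)
    }
    planted <- vapply(seqs, function(s) {
      p <- regexpr(recognition, s, fixed = TRUE)[1]
      if (p > 0) as.integer(p) else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
    data.frame(
      taxon_id = sprintf("taxon%02d", seq_len(n_taxa)),
      sequence = seqs,
      taxonomy_label = sprintf("Synthetic;CommunityTaxon%02d", seq_len(n_taxa)),
      planted_trf = planted,
      stringsAsFactors = FALSE
    )
  })
}

#' Community dynamics specification
#'
#' Per-taxon initial biomass, a piecewise-constant specific growth-rate
#' schedule, and optional lysis events. Growth-rate intervals for a taxon
#' must not overlap; coverage of the simulation horizon is checked at
#' simulation time.
#'
#' @param initial_biomass named positive numeric vector (arbitrary mass
#'   units), one entry per taxon.
#' @param growth data.frame with columns `taxon_id`, `start_day`, `end_day`,
#'   `rate` (per day; negative rates are allowed).
#' @param lysis optional data.frame with columns `taxon_id`, `day`,
#'   `survival` (fraction in `[0, 1]` of biomass remaining after the event).
#' @return object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(initial_biomass, growth, lysis = NULL) {
  fail_if(is.null(names(initial_biomass)), "initial_biomass must be named")
  fail_if(any(!is.finite(initial_biomass)) || any(initial_biomass <= 0),
          "initial biomass must be positive and finite")
  fail_if(!all(c("taxon_id", "start_day", "end_day", "rate") %in% names(growth)),
          "growth needs columns taxon_id, start_day, end_day, rate")
  fail_if(any(!is.finite(growth$rate)), "NaN/NA growth rates are rejected")
  fail_if(any(growth$end_day <= growth$start_day), "growth intervals must have end > start")
  fail_if(!all(growth$taxon_id %in% names(initial_biomass)),
          "growth schedule references unknown taxa")
  for (tx in unique(growth$taxon_id)) {
    g <- growth[growth$taxon_id == tx, ]
    g <- g[order(g$start_day), ]
    if (nrow(g) > 1 && any(g$start_day[-1] < g$end_day[-nrow(g)] - 1e-9)) {
      stop("overlapping growth intervals for ", tx, call. = FALSE)
    }
  }
  if (!is.null(lysis) && nrow(lysis)) {
    fail_if(!all(c("taxon_id", "day", "survival") %in% names(lysis)),
            "lysis needs columns taxon_id, day, survival")
    fail_if(any(!is.finite(lysis$day)) || any(!is.finite(lysis$survival)),
            "NaN in lysis events is rejected")
    fail_if(any(lysis$survival < 0 | lysis$survival > 1),
            "survival must be in [0, 1]")
    fail_if(!all(lysis$taxon_id %in% names(initial_biomass)),
            "lysis references unknown taxa")
  }
  structure(list(initial_biomass = initial_biomass, growth = growth,
                 lysis = lysis), class = "dynamics_spec")
}

#' Constant growth schedule helper
#'
#' @param taxa character vector of taxon ids.
#' @param rate growth rate per day.
#' @param horizon_days schedule end.
#' @return growth data.frame suitable for [dynamics_spec()].
#' @export
constant_growth <- function(taxa, rate, horizon_days) {
  data.frame(taxon_id = taxa, start_day = 0, end_day = horizon_days,
             rate = rate, stringsAsFactors = FALSE)
}

#' Overlay a growth episode on a schedule
#'
#' Replaces the growth rate of `taxon` over `[start_day, end_day)` with
#' `rate`, splitting the surrounding intervals so the schedule still tiles
#' the horizon. Used to compose propagation/recession scenarios.
#'
#' @param growth growth data.frame (see [dynamics_spec()]).
#' @param taxon taxon id.
#' @param start_day,end_day episode bounds (days).
#' @param rate growth rate per day during the episode.
#' @return updated growth data.frame.
#' @export
overlay_episode <- function(growth, taxon, start_day, end_day, rate) {
  g <- growth[growth$taxon_id != taxon, ]
  own <- growth[growth$taxon_id == taxon, ]
  pieces <- list()
  for (i in seq_len(nrow(own))) {
    s <- own$start_day[i]; e <- own$end_day[i]; r <- own$rate[i]
    if (e <= start_day || s >= end_day) {
      pieces[[length(pieces) + 1L]] <- data.frame(taxon_id = taxon, start_day = s,
                                                  end_day = e, rate = r)
    } else {
      if (s < start_day) pieces[[length(pieces) + 1L]] <-
          data.frame(taxon_id = taxon, start_day = s, end_day = start_day, rate = r)
      if (e > end_day) pieces[[length(pieces) + 1L]] <-
          data.frame(taxon_id = taxon, start_day = end_day, end_day = e, rate = r)
    }
  }
  pieces[[length(pieces) + 1L]] <- data.frame(taxon_id = taxon, start_day = start_day,
                                              end_day = end_day, rate = rate)
  out <- rbind(g, do.call(rbind, pieces))
  out[order(out$taxon_id, out$start_day), ]
}

#' Simulate per-cycle community biomass dynamics in an SBR
#'
#' The reactor operates in discrete cycles of length \eqn{\Delta t} (from the
#' phase durations of `reactor`). Per cycle, each taxon's biomass is updated
#' as \eqn{X_j \leftarrow X_j e^{\mu_j \Delta t} (1 - w)}, where \eqn{w} is
#' the per-cycle wastage fraction implied by the SRT (see
#' [wastage_fraction_per_cycle()]; the default exact form makes the discrete
#' trajectory coincide with the continuous closed form
#' \eqn{X(t) = X_0 e^{(\mu - 1/\mathrm{SRT}) t}} on the cycle grid). Lysis
#' events multiply biomass by their survival fraction at the end of the cycle
#' containing the event day.
#'
#' @param spec a [dynamics_spec()].
#' @param reactor a [reactor_config()].
#' @param horizon_days simulation horizon (>= one cycle).
#' @param sampling_days days at which samples are sequenced; defaults to all
#'   whole days in `[1, horizon]`. Days are snapped to the cycle grid.
#' @param wastage `"exact"` (default) or `"nominal"`, see
#'   [wastage_fraction_per_cycle()].
#' @return object of class `community_truth`: list with `days` (cycle-end
#'   times, starting at 0), `biomass` (taxa x times matrix), `sampling_days`,
#'   `sampling_index` (columns of `biomass` for each sample), `taxa`.
#' @export
simulate_dynamics <- function(spec, reactor, horizon_days, sampling_days = NULL,
                              wastage = c("exact", "nominal")) {
  stopifnot(inherits(spec, "dynamics_spec"), inherits(reactor, "reactor_config"))
  wastage <- match.arg(wastage)
  dt <- cycle_length_days(reactor)
  fail_if(horizon_days < dt, "horizon must cover at least one cycle")
  # growth intervals must tile [0, horizon] for every taxon
  for (tx in names(spec$initial_biomass)) {
    g <- spec$growth[spec$growth$taxon_id == tx, ]
    fail_if(nrow(g) == 0, paste0("no growth schedule for ", tx))
    g <- g[order(g$start_day), ]
    cover <- g$start_day[1] <= 1e-9 &&
      all(abs(g$start_day[-1] - g$end_day[-nrow(g)]) < 1e-9) &&
      g$end_day[nrow(g)] >= horizon_days - 1e-9
    fail_if(!cover, paste0("growth intervals do not tile [0, horizon] for ", tx))
  }
  n_cycles <- floor(horizon_days / dt + 1e-9)
  # round the grid so whole days are representable exactly (4 h cycles)
  times <- round(dt * (0:n_cycles), 9)
  taxa <- names(spec$initial_biomass)
  w <- wastage_fraction_per_cycle(reactor, mode = wastage)
  X <- matrix(0, length(taxa), n_cycles + 1L,
              dimnames = list(taxa, NULL))
  X[, 1] <- spec$initial_biomass

  # per-taxon step-function rate lookup
  rate_at <- function(tx, t) {
    g <- spec$growth[spec$growth$taxon_id == tx, ]
    g <- g[order(g$start_day), ]
    i <- findInterval(t + 1e-12, g$start_day)
    g$rate[max(i, 1L)]
  }
  rates <- matrix(0, length(taxa), n_cycles)
  for (j in seq_along(taxa)) {
    g <- spec$growth[spec$growth$taxon_id == taxa[j], ]
    g <- g[order(g$start_day), ]
    idx <- findInterval(times[-length(times)] + 1e-12, g$start_day)
    idx[idx < 1L] <- 1L
    rates[j, ] <- g$rate[idx]
  }

  lysis <- spec$lysis
  for (i in seq_len(n_cycles)) {
    X[, i + 1L] <- X[, i] * exp(rates[, i] * dt) * (1 - w)
    if (!is.null(lysis) && nrow(lysis)) {
      hit <- which(lysis$day > times[i] + 1e-12 & lysis$day <= times[i + 1L] + 1e-12)
      for (h in hit) {
        j <- match(lysis$taxon_id[h], taxa)
        X[j, i + 1L] <- X[j, i + 1L] * lysis$survival[h]
      }
    }
  }

  if (is.null(sampling_days)) sampling_days <- seq_len(floor(horizon_days))
  fail_if(length(sampling_days) == 0, "sampling_days must be non-empty")
  idx <- vapply(sampling_days, function(d) which.min(abs(times - d)), integer(1))
  structure(list(days = times, biomass = X,
                 sampling_days = times[idx], sampling_index = idx,
                 taxa = taxa),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat("Community truth:", length(x$taxa), "taxa,",
      length(x$days) - 1L, "cycles,",
      length(x$sampling_days), "sampled time points\n")
  invisible(x)
}

#' Multinomial read-count sampling from a simulated community
#'
#' Draws per-taxon read counts for each sampled day multinomially with
#' probabilities proportional to biomass — the counting layer of sequencing,
#' without synthesizing read sequences. Useful for count-level tests of the
#' downstream statistics.
#'
#' @param truth a `community_truth`.
#' @param depth reads per sample (scalar or per-sample vector).
#' @param seed integer seed.
#' @return an [otu_count_table()] with samples named `d<day>` and `days` set.
#' @export
sample_counts <- function(truth, depth, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  ns <- length(truth$sampling_index)
  depth <- rep_len(as.integer(depth), ns)
  withr::with_seed(seed, {
    counts <- matrix(0L, ns, length(truth$taxa),
                     dimnames = list(sprintf("d%03d", round(truth$sampling_days)),
                                     truth$taxa))
    for (i in seq_len(ns)) {
      b <- truth$biomass[, truth$sampling_index[i]]
      fail_if(sum(b) <= 0, "sampled day has zero total biomass")
      counts[i, ] <- as.integer(rmultinom(1L, depth[i], b / sum(b)))
    }
    otu_count_table(counts,
                    days = setNames(truth$sampling_days, rownames(counts)))
  })
}

#' Sequencing specification for read simulation
#'
#' @param reads_per_sample reads per sample (scalar or per-sample vector);
#'   default 1,000.
#' @param error_rate per-base substitution error rate (default 0.002).
#' @param fraction_reverse fraction of reads emitted reverse-complemented
#'   (default 0.35).
#' @param full_length_fraction fraction of reads whose template covers the
#'   full amplicon including the downstream primer region (default 0.8);
#'   the remainder are truncated at the 3' end.
#' @param max_truncation maximum 3' truncation (bases) of non-full-length
#'   reads (default 60).
#' @param seed integer seed for the read simulation.
#' @return object of class `sequencing_spec`.
#' @export
sequencing_spec <- function(reads_per_sample = 1000L, error_rate = 0.002,
                            fraction_reverse = 0.35,
                            full_length_fraction = 0.8,
                            max_truncation = 60L, seed = 1L) {
  fail_if(any(reads_per_sample < 0), "reads_per_sample must be >= 0")
  fail_if(error_rate < 0 || error_rate >= 1, "error rate must be in [0, 1)")
  fail_if(fraction_reverse < 0 || fraction_reverse > 1,
          "fraction_reverse must be in [0, 1]")
  structure(list(reads_per_sample = reads_per_sample, error_rate = error_rate,
                 fraction_reverse = fraction_reverse,
                 full_length_fraction = full_length_fraction,
                 max_truncation = as.integer(max_truncation),
                 seed = as.integer(seed)),
            class = "sequencing_spec")
}

#' Generate sample barcodes with pairwise Hamming distance >= 3
#'
#' With distance >= 3, demultiplexing at 1 tolerated mismatch can never
#' misassign a read between two known barcodes.
#'
#' @param n number of barcodes.
#' @param seed integer seed.
#' @param min_distance minimum pairwise Hamming distance (default 3).
#' @return character vector of distinct 8-base barcodes.
#' @export
generate_barcodes <- function(n, seed = 1L, min_distance = 3L) {
  withr::with_seed(seed, {
    out <- character(0)
    hamming <- function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }
    guard <- 0L
    while (length(out) < n) {
      cand <- random_dna(8L)
      if (all(vapply(out, function(b) hamming(cand, b) >= min_distance, TRUE))) {
        out <- c(out, cand)
      }
      guard <- guard + 1L
      if (guard > 1000L * n) stop("could not generate barcodes", call. = FALSE)
    }
    out
  })
}

# Realize IUPAC ambiguity codes in a primer into concrete bases (one random
# realization, e.g. per taxon template).
realize_iupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c) {
    set <- IUPAC_SETS[[c]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

#' Simulate barcoded amplicon reads from a community truth
#'
#' For each sampled day, per-taxon read counts are drawn multinomially with
#' probabilities proportional to biomass. Each read is assembled as
#' `barcode + forward primer + insert` with the reverse primer's reverse
#' complement appended when the template is full length (see
#' [sequencing_spec()]); substitution errors are applied at the stated rate
#' and a stated fraction of reads is emitted reverse-complemented. Output is
#' byte-identical for identical seeds.
#'
#' @param truth a `community_truth`.
#' @param taxa reference data.frame from [generate_reference_sequences()].
#' @param seq_spec a [sequencing_spec()].
#' @param primers a [barcoded_primer_set()] whose barcode map covers the
#'   sample ids `d<day>` of the truth's sampling days.
#' @param dir optional output directory: writes `reads.fasta`, `truth.tsv`
#'   (read_id, sample_id, taxon_id), `mapping.tsv` (sample_id, barcode).
#' @return list with `reads` (named character vector), `truth` (data.frame),
#'   `mapping` (named barcode vector), `sample_days` (named numeric).
#' @export
sample_reads <- function(truth, taxa, seq_spec, primers, dir = NULL) {
  stopifnot(inherits(truth, "community_truth"),
            inherits(seq_spec, "sequencing_spec"),
            inherits(primers, "barcoded_primer_set"))
  fail_if(length(truth$sampling_index) == 0, "no sampling days")
  samples <- sprintf("d%03d", round(truth$sampling_days))
  fail_if(!all(samples %in% names(primers$barcodes)),
          "barcode map does not cover all sample ids")
  depth <- rep_len(as.integer(seq_spec$reads_per_sample), length(samples))
  seq_by_taxon <- setNames(taxa$sequence, taxa$taxon_id)
  fail_if(!all(truth$taxa %in% names(seq_by_taxon)),
          "taxa table does not cover all simulated taxa")

  withr::with_seed(seq_spec$seed, {
    # taxon-specific concrete primer realizations (templates carry real bases)
    fwd_by_taxon <- setNames(vapply(truth$taxa, function(t) realize_iupac(primers$forward),
                                    character(1)), truth$taxa)
    rev_by_taxon <- setNames(vapply(truth$taxa, function(t) realize_iupac(primers$reverse),
                                    character(1)), truth$taxa)
    rc_rev_by_taxon <- setNames(revcomp(rev_by_taxon), truth$taxa)
    all_reads <- character(0); all_ids <- character(0)
    truth_rows <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      b <- truth$biomass[, truth$sampling_index[i]]
      if (depth[i] == 0L) { truth_rows[[i]] <- NULL; next }
      fail_if(sum(b) <= 0, "sampled day has zero total biomass")
      cnt <- as.integer(rmultinom(1L, depth[i], b / sum(b)))
      taxon_of_read <- rep(truth$taxa, cnt)
      if (length(taxon_of_read) == 0) next
      taxon_of_read <- sample(taxon_of_read)   # shuffle read order
      bc <- primers$barcodes[[samples[i]]]
      reads <- vapply(taxon_of_read, function(tx) {
        ins <- seq_by_taxon[[tx]]
        full <- runif(1) < seq_spec$full_length_fraction
        if (!full && seq_spec$max_truncation > 0) {
          cut <- sample(0:seq_spec$max_truncation, 1L)
          if (cut > 0) ins <- substr(ins, 1L, max(1L, nchar(ins) - cut))
        }
        paste0(bc, fwd_by_taxon[[tx]], ins,
               if (full) rc_rev_by_taxon[[tx]] else "")
      }, character(1), USE.NAMES = FALSE)
      reads <- add_substitution_errors(reads, seq_spec$error_rate)
      flip <- runif(length(reads)) < seq_spec$fraction_reverse
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
      ids <- sprintf("%s_r%05d", samples[i], seq_along(reads))
      all_reads <- c(all_reads, reads)
      all_ids <- c(all_ids, ids)
      truth_rows[[i]] <- data.frame(read_id = ids, sample_id = samples[i],
                                    taxon_id = taxon_of_read,
                                    stringsAsFactors = FALSE)
    }
    names(all_reads) <- all_ids
    truth_df <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, TRUE)])
    if (is.null(truth_df)) {
      truth_df <- data.frame(read_id = character(0), sample_id = character(0),
                             taxon_id = character(0))
    }
    out <- list(reads = all_reads, truth = truth_df,
                mapping = primers$barcodes[samples],
                sample_days = setNames(truth$sampling_days, samples))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(out$reads, file.path(dir, "reads.fasta"))
      write.table(out$truth, file.path(dir, "truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_barcode_map(out$mapping, file.path(dir, "mapping.tsv"))
    }
    out
  })
}

#' Default synthetic reactor scenario
#'
#' Builds the shipped study-like scenario: a community of `n_taxa` taxa in a
#' 10 L SBR (SRT 10 d) followed over `horizon` days at roughly 75 sampling
#' points, with several taxa undergoing propagation/recession episodes and
#' one designated taxon (`taxon15`) that mimics the striking boom-and-lysis
#' pattern: a rise from about 2% to about 30% of the community within 5 days,
#' followed by an abrupt lysis event (survival 5%) ten days later. The
#' `taxon15` reference is a synthetic sequence planted so that its RsaI
#' terminal restriction fragment, measured from the 27f 5' end, is 484 bp.
#'
#' @param n_taxa number of taxa (default 30).
#' @param reads_per_sample sequencing depth (default 1,000).
#' @param horizon days of operation (default 245).
#' @param n_sampling_points approximate number of sampled days (default 75).
#' @param error_rate per-base substitution error rate (default 0.002).
#' @param seed master seed.
#' @return list of class `scenario` with elements `taxa`, `dynamics`,
#'   `reactor`, `sampling_days`, `sequencing`, `primers`, `focal` (the
#'   lysis-event taxon id), `lysis_day`.
#' @export
default_scenario <- function(n_taxa = 30L, reads_per_sample = 1000L,
                             horizon = 245, n_sampling_points = 75L,
                             error_rate = 0.002, seed = 101L) {
  fail_if(n_taxa < 5, "scenario needs at least 5 taxa")
  taxa <- generate_reference_sequences(n_taxa, site_fraction = 0.6, seed = seed)
  # designated boom-and-lysis taxon: plant its first RsaI site so the T-RF
  # from the 27f 5' end is 484 bp (20 nt primer + site start 463 + cut 2)
  focal <- "taxon15"
  if (!focal %in% taxa$taxon_id) focal <- taxa$taxon_id[min(15L, n_taxa)]
  fi <- match(focal, taxa$taxon_id)
  withr::with_seed(seed + 1L, {
    ins <- random_dna(480L)
    while (grepl("GTAC", substr(ins, 1, 462), fixed = TRUE)) {
      p <- regexpr("GTAC", ins, fixed = TRUE)[1]
      substr(ins, p + 1L, p + 1L) <- sample(c("A", "C", "G"), 1L)
    }
    substr(ins, 463L, 466L) <- "GTAC"
    taxa$sequence[fi] <- ins
    taxa$planted_trf[fi] <- 463L
    reactor <- reactor_config()
    # baseline growth balances wastage (community at steady state)
    base <- 1 / reactor$srt
    growth <- constant_growth(taxa$taxon_id, base, horizon)
    # overlay an episode, clipped to the horizon
    ep <- function(g, tx, s, e, rate) {
      if (s >= horizon) return(g)
      overlay_episode(g, tx, s, min(e, horizon), rate)
    }
    # focal: boom day 30-35 (2% -> ~30%), lysis at day 45, later episodes
    growth <- ep(growth, focal, 30, 35, 0.72)
    growth <- ep(growth, focal, 100, 110, 0.35)
    growth <- ep(growth, focal, 125, 140, 0.0)
    growth <- ep(growth, focal, 190, 200, 0.35)
    # a few other taxa with repeated propagation/recession episodes
    others <- setdiff(taxa$taxon_id, focal)
    episodic <- sample(others, min(6L, length(others)))
    for (k in seq_along(episodic)) {
      s1 <- 15 + 30 * k
      growth <- ep(growth, episodic[k], s1, s1 + 10, 0.25)
      growth <- ep(growth, episodic[k], s1 + 25, s1 + 35, 0.02)
    }
    init <- rlnorm(length(others), meanlog = 0, sdlog = 0.6)
    names(init) <- others
    init_focal <- setNames(0.02 / 0.98 * sum(init), focal)
    initial <- c(init, init_focal)[taxa$taxon_id]
    lysis <- data.frame(taxon_id = focal, day = 45.05, survival = 0.05)
    dyn <- dynamics_spec(initial, growth, lysis)
    sampling <- sort(unique(round(seq(2, horizon, length.out = n_sampling_points))))
    barcodes <- generate_barcodes(length(sampling), seed = seed + 2L)
    names(barcodes) <- sprintf("d%03d", sampling)
    primers <- barcoded_primer_set(barcodes)
    seqspec <- sequencing_spec(reads_per_sample = reads_per_sample,
                               error_rate = error_rate, seed = seed + 3L)
    structure(list(taxa = taxa, dynamics = dyn, reactor = reactor,
                   sampling_days = sampling, sequencing = seqspec,
                   primers = primers, focal = focal, lysis_day = 45.05),
              class = "scenario")
  })
}

#' @export
print.scenario <- function(x, ...) {
  cat("Synthetic reactor scenario:", nrow(x$taxa), "taxa,",
      length(x$sampling_days), "sampling days, focal taxon", x$focal, "\n")
  invisible(x)
}
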