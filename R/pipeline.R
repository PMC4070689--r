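# Pipeline orchestration: staged runs over on-disk artifacts with a
# machine-readable manifest.

#' Pipeline configuration
#'
#' Plain key-value configuration shared by all stages. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param out_dir artifact directory.
#' @param seed master seed for the simulate stage.
#' @param n_taxa,reads_per_sample,horizon,n_sampling_points,error_rate
#'   scenario scale, see [default_scenario()].
#' @param clustering_threshold OTU identity threshold (default 0.97).
#' @param major_threshold major-OTU mean-fraction threshold, percent
#'   (default 0.5).
#' @param ci_level confidence level (default 0.95).
#' @param enzyme enzyme name from [restriction_enzymes()] (default "RsaI").
#' @param washout_otu,washout_t0 focal OTU and user-chosen anchor day for the
#'   washout stage (the anchor is never auto-detected); NULL disables the
#'   stage unless supplied.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "otudyn_run", seed = 101L,
                            n_taxa = 12L, reads_per_sample = 60L,
                            horizon = 60, n_sampling_points = 20L,
                            error_rate = 0.002,
                            clustering_threshold = 0.97,
                            major_threshold = 0.5, ci_level = 0.95,
                            enzyme = "RsaI",
                            washout_otu = NULL, washout_t0 = NULL) {
  fail_if(clustering_threshold <= 0 || clustering_threshold > 1,
          "clustering_threshold must be in (0, 1]")
  fail_if(ci_level <= 0 || ci_level >= 1, "ci_level must be in (0, 1)")
  fail_if(!enzyme %in% names(restriction_enzymes()),
          paste0("unknown enzyme: ", enzyme))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_taxa = as.integer(n_taxa),
                 reads_per_sample = as.integer(reads_per_sample),
                 horizon = horizon,
                 n_sampling_points = as.integer(n_sampling_points),
                 error_rate = error_rate,
                 clustering_threshold = clustering_threshold,
                 major_threshold = major_threshold, ci_level = ci_level,
                 enzyme = enzyme, washout_otu = washout_otu,
                 washout_t0 = washout_t0),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key=value file
#'
#' @param path plain-text file, one `key=value` per line (`#` comments).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  kv <- read_key_values(path)
  num <- function(k, default) if (k %in% names(kv)) as.numeric(kv[[k]]) else default
  chr <- function(k, default) if (k %in% names(kv)) kv[[k]] else default
  known <- c("out_dir", "seed", "n_taxa", "reads_per_sample", "horizon",
             "n_sampling_points", "error_rate", "clustering_threshold",
             "major_threshold", "ci_level", "enzyme", "washout_otu",
             "washout_t0")
  unknown <- setdiff(names(kv), known)
  fail_if(length(unknown) > 0,
          paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  pipeline_config(
    out_dir = chr("out_dir", "otudyn_run"), seed = num("seed", 101),
    n_taxa = num("n_taxa", 12), reads_per_sample = num("reads_per_sample", 60),
    horizon = num("horizon", 60),
    n_sampling_points = num("n_sampling_points", 20),
    error_rate = num("error_rate", 0.002),
    clustering_threshold = num("clustering_threshold", 0.97),
    major_threshold = num("major_threshold", 0.5),
    ci_level = num("ci_level", 0.95), enzyme = chr("enzyme", "RsaI"),
    washout_otu = chr("washout_otu", NULL),
    washout_t0 = if ("washout_t0" %in% names(kv)) as.numeric(kv[["washout_t0"]]) else NULL
  )
}

.artifact <- function(config, name) file.path(config$out_dir, name)

.need_artifact <- function(config, name, producer) {
  p <- .artifact(config, name)
  fail_if(!file.exists(p),
          paste0("missing artifact ", p, "; run stage '", producer, "' first"))
  p
}

.append_manifest <- function(config, stage, params, outputs) {
  path <- .artifact(config, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else list()
  manifest[[stage]] <- list(stage = stage, params = params, outputs = outputs,
                            seed = config$seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic reads + truth), `demux`, `cluster`,
#' `fractions`, `vtrflp`, `washout`, `heatmap`, and `run-all`. Each stage
#' reads its inputs from, and writes its artifacts to, `config$out_dir`,
#' checking that upstream artifacts exist (a missing dependency names the
#' file and the stage that produces it) and appending a run manifest entry.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return invisible list of artifact paths written by the stage.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "demux", "cluster", "fractions", "vtrflp",
              "washout", "heatmap", "run-all")
  fail_if(!stage %in% stages,
          paste0("unknown stage '", stage, "'; known: ",
                 paste(stages, collapse = ", ")))
  if (stage == "run-all") {
    outs <- lapply(setdiff(stages, "run-all"), function(s) {
      if (s == "washout" && (is.null(config$washout_otu) ||
                             is.null(config$washout_t0))) return(NULL)
      run_stage(s, config)
    })
    return(invisible(unlist(outs)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  enz <- restriction_enzymes()[[config$enzyme]]
  out <- switch(stage,
    simulate = {
      sc <- default_scenario(n_taxa = config$n_taxa,
                             reads_per_sample = config$reads_per_sample,
                             horizon = config$horizon,
                             n_sampling_points = config$n_sampling_points,
                             error_rate = config$error_rate,
                             seed = config$seed)
      truth <- simulate_dynamics(sc$dynamics, sc$reactor, config$horizon,
                                 sampling_days = sc$sampling_days)
      sim <- sample_reads(truth, sc$taxa, sc$sequencing, sc$primers,
                          dir = config$out_dir)
      write_reactor_config(sc$reactor, .artifact(config, "reactor.cfg"))
      write_fasta(setNames(sc$taxa$sequence, sc$taxa$taxon_id),
                  .artifact(config, "references.fasta"))
      c("reads.fasta", "truth.tsv", "mapping.tsv", "reactor.cfg",
        "references.fasta")
    },
    demux = {
      reads <- read_fasta(.need_artifact(config, "reads.fasta", "simulate"))
      barcodes <- read_barcode_map(.need_artifact(config, "mapping.tsv", "simulate"))
      primers <- barcoded_primer_set(barcodes)
      dm <- demultiplex(reads, primers)
      write.table(dm$assigned, .artifact(config, "demuxed_reads.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_demux_report(dm, .artifact(config, "demux_report.tsv"))
      c("demuxed_reads.tsv", "demux_report.tsv")
    },
    cluster = {
      dm <- read.delim(.need_artifact(config, "demuxed_reads.tsv", "demux"),
                       stringsAsFactors = FALSE)
      tab <- cluster_greedy(dm, threshold = config$clustering_threshold)
      write_otu_table(tab, .artifact(config, "otu_table.tsv"))
      write_fasta(tab$rep_seqs, .artifact(config, "rep_seqs.fasta"))
      c("otu_table.tsv", "rep_seqs.fasta")
    },
    fractions = {
      tab <- read_otu_table(.need_artifact(config, "otu_table.tsv", "cluster"))
      series <- compute_fractions(tab, level = config$ci_level)
      write_fraction_series(series, .artifact(config, "fractions.tsv"))
      writeLines(select_major_otus(series, config$major_threshold),
                 .artifact(config, "major_otus.txt"))
      c("fractions.tsv", "major_otus.txt")
    },
    vtrflp = {
      dm <- read.delim(.need_artifact(config, "demuxed_reads.tsv", "demux"),
                       stringsAsFactors = FALSE)
      barcodes <- read_barcode_map(.need_artifact(config, "mapping.tsv", "simulate"))
      primers <- barcoded_primer_set(barcodes)
      rows <- lapply(sort(unique(dm$sample_id)), function(s) {
        prof <- build_virtual_profile(dm, primers, enz, sample_id = s)
        if (length(prof$sizes) == 0) return(NULL)
        data.frame(sample_id = s, size = prof$sizes, count = prof$counts,
                   n_excluded = prof$n_excluded)
      })
      df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      write.table(df, .artifact(config, "virtual_trflp.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      "virtual_trflp.tsv"
    },
    washout = {
      fail_if(is.null(config$washout_otu) || is.null(config$washout_t0),
              "washout stage needs washout_otu and washout_t0 in the config")
      series <- read_fraction_series(.need_artifact(config, "fractions.tsv",
                                                    "fractions"))
      reactor <- read_reactor_config(.need_artifact(config, "reactor.cfg",
                                                    "simulate"))
      call <- detect_selective_recession(series, config$washout_otu,
                                         config$washout_t0, reactor)
      if (!is.null(call$evidence)) {
        write.table(call$evidence, .artifact(config, "recession_report.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      writeLines(c(paste0("otu=", call$otu), paste0("t0=", call$t0),
                   paste0("verdict=", call$verdict)),
                 .artifact(config, "recession_summary.txt"))
      c("recession_report.tsv", "recession_summary.txt")
    },
    heatmap = {
      series <- read_fraction_series(.need_artifact(config, "fractions.tsv",
                                                    "fractions"))
      reps <- read_fasta(.need_artifact(config, "rep_seqs.fasta", "cluster"))
      major <- select_major_otus(series, config$major_threshold)
      out_files <- "heatmap_matrix.tsv"
      if (length(major) >= 3) {
        tree <- neighbor_joining(identity_distances(reps[major]))
        write_newick(tree, .artifact(config, "major_otus.nwk"))
        ord <- leaf_order(tree, ladderize = TRUE)
        out_files <- c(out_files, "major_otus.nwk", "heatmap.png")
      } else {
        ord <- major
      }
      hm <- build_heatmap(series, major, ord)
      write.table(cbind(otu = rownames(hm), as.data.frame(unclass(hm))),
                  .artifact(config, "heatmap_matrix.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(major) >= 3) {
        render_heatmap(hm, .artifact(config, "heatmap.png"))
      }
      out_files
    })
  .append_manifest(config, stage,
                   params = config[setdiff(names(config), "out_dir")],
                   outputs = out)
  invisible(file.path(config$out_dir, out))
}

#' Run the full pipeline
#'
#' Equivalent to `run_stage("run-all", config)`: simulate, demultiplex,
#' cluster, fractions, virtual T-RFLP, washout (when configured) and heatmap.
#'
#' @param config a [pipeline_config()].
#' @return invisible vector of artifact paths.
#' @export
run_pipeline <- function(config) run_stage("run-all", config)
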