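# Virtual T-RFLP: in-silico restriction digestion of demultiplexed reads and
# tolerance-based comparison with experimental electropherogram peak tables.

#' Restriction enzyme definition
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (labeled strand).
#' @param cut_offset bases from the recognition-site start to the cut point
#'   on the labeled strand (RsaI: GT^AC, offset 2).
#' @return object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme()  # RsaI
#' @export
restriction_enzyme <- function(name = "RsaI", recognition = "GTAC",
                               cut_offset = 2L) {
  fail_if(cut_offset < 0 || cut_offset > nchar(recognition),
          "cut_offset must lie within the recognition sequence")
  structure(list(name = name, recognition = toupper(recognition),
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Built-in enzyme registry
#' @return named list of [restriction_enzyme()] objects.
#' @export
restriction_enzymes <- function() {
  list(RsaI = restriction_enzyme("RsaI", "GTAC", 2L))
}

#' Terminal restriction fragment length of demultiplexed reads
#'
#' Each read's amplicon is reconstituted as forward primer + insert (+ the
#' reverse primer's reverse complement when the downstream primer region was
#' detected at demultiplexing), since the fluorescent label sits on the
#' 5' end of the forward primer and the primer was trimmed at demux. The
#' T-RF is the distance from that labeled 5' end to the enzyme's cut point at
#' the first occurrence of the recognition site. Reads without a site yield
#' the full reconstituted amplicon length when `had_reverse_primer` is true
#' (the template demonstrably ran to the downstream primer) and are excluded
#' otherwise (the true fragment length is unknowable from a truncated read).
#'
#' @param insert character vector of insert sequences (forward orientation,
#'   primers trimmed), or a `demux_result` / assigned-reads data.frame (then
#'   `had_reverse_primer` is taken from it).
#' @param had_reverse_primer logical vector (recycled).
#' @param primers a [barcoded_primer_set()].
#' @param enzyme a [restriction_enzyme()] (default RsaI).
#' @param include_barcode add the 8-base barcode length to the fragment
#'   (default FALSE: the experimental digestion uses unbarcoded primers).
#' @return data.frame with columns `trf` (integer bp, NA when excluded) and
#'   `status` (`"cut"`, `"full_length"`, `"excluded"`).
#' @export
trf_length <- function(insert, had_reverse_primer = FALSE, primers,
                       enzyme = restriction_enzyme(), include_barcode = FALSE) {
  if (inherits(insert, "demux_result")) insert <- insert$assigned
  if (is.data.frame(insert)) {
    had_reverse_primer <- insert$had_reverse_primer
    insert <- insert$insert
  }
  stopifnot(inherits(primers, "barcoded_primer_set"),
            inherits(enzyme, "restriction_enzyme"))
  had <- rep_len(had_reverse_primer, length(insert))
  prefix <- if (include_barcode) 8L else 0L
  full <- paste0(primers$forward, toupper(insert),
                 ifelse(had, revcomp(primers$reverse), ""))
  pos <- if (grepl("^[ACGT]+$", enzyme$recognition)) {
    as.integer(regexpr(enzyme$recognition, full, fixed = TRUE))
  } else {
    vapply(full, function(s) {
      hit <- match_iupac(enzyme$recognition, s, 0L)
      if (is.null(hit)) -1L else hit$position
    }, integer(1), USE.NAMES = FALSE)
  }
  trf <- ifelse(pos > 0L, prefix + pos - 1L + enzyme$cut_offset,
                ifelse(had, prefix + nchar(full), NA_integer_))
  status <- ifelse(pos > 0L, "cut", ifelse(had, "full_length", "excluded"))
  data.frame(trf = as.integer(trf), status = status, stringsAsFactors = FALSE)
}

#' Virtual T-RFLP profile for one sample
#'
#' Counts reads by predicted terminal restriction fragment size. Reads with
#' neither a restriction site nor a detected downstream primer are excluded
#' and counted in `n_excluded`; `sum(counts) + n_excluded` always equals the
#' number of reads examined.
#'
#' @param reads a `demux_result`, or an assigned-reads data.frame (columns
#'   `insert`, `had_reverse_primer`, optionally `sample_id`).
#' @param primers a [barcoded_primer_set()].
#' @param enzyme a [restriction_enzyme()].
#' @param sample_id restrict to (and label the profile with) this sample.
#' @param include_barcode see [trf_length()].
#' @return object of class `virtual_profile`: list with `sample_id`, `sizes`
#'   (sorted integer bp), `counts`, `n_excluded`, `n_reads`.
#' @export
build_virtual_profile <- function(reads, primers, enzyme = restriction_enzyme(),
                                  sample_id = NULL, include_barcode = FALSE) {
  if (inherits(reads, "demux_result")) reads <- reads$assigned
  if (!is.null(sample_id)) {
    reads <- reads[reads$sample_id == sample_id, , drop = FALSE]
  } else if ("sample_id" %in% names(reads)) {
    u <- unique(reads$sample_id)
    fail_if(length(u) > 1,
            "reads span multiple samples; pass sample_id to select one")
    sample_id <- if (length(u)) u else NA_character_
  }
  res <- trf_length(reads$insert, reads$had_reverse_primer, primers, enzyme,
                    include_barcode = include_barcode)
  kept <- res$trf[res$status != "excluded"]
  tab <- table(kept)
  structure(list(sample_id = sample_id,
                 sizes = as.integer(names(tab)),
                 counts = as.integer(tab),
                 n_excluded = sum(res$status == "excluded"),
                 n_reads = nrow(reads)),
            class = "virtual_profile")
}

#' @export
print.virtual_profile <- function(x, ...) {
  cat("Virtual T-RFLP profile", if (!is.null(x$sample_id)) paste0("(", x$sample_id, ")"),
      ":", length(x$sizes), "fragment sizes,", sum(x$counts), "reads counted,",
      x$n_excluded, "excluded\n")
  invisible(x)
}

#' Experimental T-RFLP peak table
#'
#' @param sizes peak sizes in bp (strictly increasing).
#' @param intensities non-negative peak intensities.
#' @param sample_id optional label.
#' @return object of class `experimental_profile`.
#' @export
experimental_profile <- function(sizes, intensities, sample_id = NULL) {
  fail_if(length(sizes) != length(intensities), "sizes/intensities length mismatch")
  fail_if(is.unsorted(sizes, strictly = TRUE), "peak sizes must be strictly increasing")
  fail_if(any(intensities < 0), "intensities must be non-negative")
  structure(list(sample_id = sample_id, sizes = as.numeric(sizes),
                 intensities = as.numeric(intensities)),
            class = "experimental_profile")
}

#' Read / write two-column peak tables (size, intensity)
#'
#' @param path delimited text file with columns `size` and `intensity`.
#' @param sample_id optional label.
#' @return an `experimental_profile` (read) or `path` (write).
#' @export
read_peak_table <- function(path, sample_id = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  fail_if(!all(c("size", "intensity") %in% names(df)),
          "peak table needs columns size and intensity")
  experimental_profile(df$size, df$intensity, sample_id)
}

#' @rdname read_peak_table
#' @param profile a `virtual_profile` or `experimental_profile`.
#' @export
write_peak_table <- function(profile, path) {
  df <- if (inherits(profile, "virtual_profile")) {
    data.frame(size = profile$sizes, intensity = profile$counts)
  } else {
    data.frame(size = profile$sizes, intensity = profile$intensities)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare a virtual profile with an experimental peak table
#'
#' Peaks are matched greedily by nearest size within `tolerance_bp` (each
#' peak used at most once; capillary sizing is a few bp off from the true
#' sequence length, hence the default tolerance). The similarity score is
#' the cosine similarity of the two weight vectors — each profile normalized
#' to sum 1 — over the union of matched pairs and unmatched peaks.
#'
#' @param virtual a `virtual_profile`.
#' @param experimental an `experimental_profile`.
#' @param tolerance_bp matching tolerance in bp (default 5, non-negative).
#' @return list with `matches` (data.frame: virtual_size, experimental_size,
#'   virtual_weight, experimental_weight), `score` in `[0, 1]`,
#'   `n_virtual_unmatched`, `n_experimental_unmatched`.
#' @export
compare_profiles <- function(virtual, experimental, tolerance_bp = 5) {
  stopifnot(inherits(virtual, "virtual_profile"),
            inherits(experimental, "experimental_profile"))
  fail_if(tolerance_bp < 0, "tolerance must be non-negative")
  empty <- data.frame(virtual_size = numeric(0), experimental_size = numeric(0),
                      virtual_weight = numeric(0), experimental_weight = numeric(0))
  if (length(virtual$sizes) == 0 || length(experimental$sizes) == 0 ||
      sum(virtual$counts) == 0 || sum(experimental$intensities) == 0) {
    return(list(matches = empty, score = 0,
                n_virtual_unmatched = length(virtual$sizes),
                n_experimental_unmatched = length(experimental$sizes)))
  }
  vw <- virtual$counts / sum(virtual$counts)
  ew <- experimental$intensities / sum(experimental$intensities)
  cand <- expand.grid(v = seq_along(virtual$sizes), e = seq_along(experimental$sizes))
  cand$delta <- abs(virtual$sizes[cand$v] - experimental$sizes[cand$e])
  cand <- cand[cand$delta <= tolerance_bp, , drop = FALSE]
  cand <- cand[order(cand$delta, virtual$sizes[cand$v]), , drop = FALSE]
  used_v <- logical(length(virtual$sizes)); used_e <- logical(length(experimental$sizes))
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    v <- cand$v[i]; e <- cand$e[i]
    if (used_v[v] || used_e[e]) next
    used_v[v] <- TRUE; used_e[e] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(v, e)
  }
  # cosine similarity over union coordinates: matched pairs share an axis,
  # unmatched peaks contribute only to their own profile's norm
  dot <- 0
  match_df <- empty
  for (p in pairs) {
    dot <- dot + vw[p[1]] * ew[p[2]]
    match_df <- rbind(match_df, data.frame(
      virtual_size = virtual$sizes[p[1]], experimental_size = experimental$sizes[p[2]],
      virtual_weight = vw[p[1]], experimental_weight = ew[p[2]]))
  }
  score <- dot / (sqrt(sum(vw^2)) * sqrt(sum(ew^2)))
  list(matches = match_df, score = score,
       n_virtual_unmatched = sum(!used_v),
       n_experimental_unmatched = sum(!used_e))
}

#' Mirrored plot of virtual vs experimental T-RFLP profiles
#'
#' Renders the virtual profile (read counts) upward and the experimental
#' profile (intensities) downward on a shared fragment-size axis, each
#' normalized to its maximum.
#'
#' @param virtual a `virtual_profile`.
#' @param experimental an `experimental_profile`.
#' @param file optional PNG path; when NULL, draws on the active device.
#' @param main plot title.
#' @return `file` (or NULL), invisibly.
#' @export
plot_profile_comparison <- function(virtual, experimental, file = NULL,
                                    main = "Virtual vs experimental T-RFLP") {
  if (!is.null(file)) {
    png(file, width = 900, height = 500)
    on.exit(dev.off())
  }
  vs <- virtual$sizes; vc <- virtual$counts / max(1, max(virtual$counts))
  es <- experimental$sizes
  ei <- experimental$intensities / max(1e-12, max(experimental$intensities))
  xlim <- range(c(vs, es)) + c(-10, 10)
  plot(NA, xlim = xlim, ylim = c(-1.1, 1.1), xlab = "fragment size (bp)",
       ylab = "relative weight", main = main)
  abline(h = 0, col = "grey40")
  if (length(vs)) segments(vs, 0, vs, vc, lwd = 3, col = "steelblue")
  if (length(es)) segments(es, 0, es, -ei, lwd = 3, col = "tomato")
  legend("topright", legend = c("virtual (reads)", "experimental (peaks)"),
         col = c("steelblue", "tomato"), lwd = 3, bty = "n")
  invisible(file)
}
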