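# FASTA I/O, IUPAC primer matching and demultiplexing of barcoded reads.

#' Read a FASTA file into a named character vector
#'
#' Sequences are normalized to uppercase. An empty file yields a length-zero
#' vector.
#'
#' @param path path to a FASTA file.
#' @return named character vector (names = record ids, first whitespace token).
#' @export
read_fasta <- function(path) {
  fail_if(!file.exists(path), paste0("FASTA file not found: ", path))
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrapping width (bases per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  fail_if(is.null(names(seqs)) && length(seqs) > 0, "sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Match an IUPAC-ambiguous pattern inside a window
#'
#' A window base matches a pattern symbol iff it belongs to the symbol's IUPAC
#' set (M = \{A,C\}, K = \{G,T\}, W = \{A,T\}, ...). Characters in the window
#' that are not A/C/G/T count as mismatches unless the pattern symbol's set
#' happens to contain them. Returns the leftmost placement whose mismatch
#' count does not exceed `max_mismatches`.
#'
#' @param pattern IUPAC nucleotide string (non-empty).
#' @param window nucleotide string to search in.
#' @param max_mismatches maximum tolerated mismatches (default 0).
#' @return `list(position=, mismatches=)` with 1-based start position, or
#'   `NULL` when no placement qualifies.
#' @examples
#' match_iupac("CM", "CA")          # M covers A -> match at 1
#' match_iupac("CM", "CG")          # NULL
#' match_iupac("CM", "CG", 1)       # match with 1 mismatch
#' @export
match_iupac <- function(pattern, window, max_mismatches = 0L) {
  fail_if(!nzchar(pattern), "pattern must be non-empty")
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  fail_if(!all(p %in% names(IUPAC_SETS)), "unknown IUPAC symbol in pattern")
  w <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  np <- length(p); nw <- length(w)
  if (nw < np) return(NULL)
  for (s in 0:(nw - np)) {
    mm <- 0L
    for (i in seq_len(np)) {
      if (!(w[s + i] %in% IUPAC_SETS[[p[i]]])) {
        mm <- mm + 1L
        if (mm > max_mismatches) break
      }
    }
    if (mm <= max_mismatches) return(list(position = s + 1L, mismatches = mm))
  }
  NULL
}

# Rightmost qualifying placement; used to locate the downstream primer region
# near the 3' end of an insert.
match_iupac_last <- function(pattern, window, max_mismatches = 0L) {
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  w <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  np <- length(p); nw <- length(w)
  if (nw < np) return(NULL)
  for (s in (nw - np):0) {
    mm <- 0L
    for (i in seq_len(np)) {
      if (!(w[s + i] %in% IUPAC_SETS[[p[i]]])) {
        mm <- mm + 1L
        if (mm > max_mismatches) break
      }
    }
    if (mm <= max_mismatches) return(list(position = s + 1L, mismatches = mm))
  }
  NULL
}

# Vectorized mismatch count of an IUPAC pattern placed at a fixed position of
# many strings. Returns NA for strings too short to hold the pattern there.
iupac_mismatches_at <- function(pattern, strings, at = 1L) {
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  np <- length(p)
  sub <- substr(strings, at, at + np - 1L)
  ok <- nchar(sub) == np
  mm <- rep(NA_integer_, length(strings))
  if (!any(ok)) return(mm)
  m <- matrix(unlist(strsplit(toupper(sub[ok]), "", fixed = TRUE)), nrow = np)
  cnt <- integer(sum(ok))
  for (i in seq_len(np)) cnt <- cnt + !(m[i, ] %in% IUPAC_SETS[[p[i]]])
  mm[ok] <- as.integer(cnt)
  mm
}

#' Barcoded primer set
#'
#' Bundles the amplification primers (IUPAC notation) with the sample-to-
#' barcode map and the demultiplexing mismatch tolerances. Defaults are the
#' 27f/519r bacterial 16S primers with 8-base barcodes.
#'
#' @param barcodes named character vector: `sample_id -> 8-base barcode`.
#'   All barcodes must be distinct and 8 bases long.
#' @param forward forward (labeled) primer, IUPAC string. Default 27f.
#' @param reverse reverse primer, IUPAC string. Default 519r.
#' @param max_barcode_mismatches tolerated barcode mismatches (default 1).
#' @param max_primer_mismatches tolerated primer mismatches (default 2).
#' @return an object of class `barcoded_primer_set`.
#' @export
barcoded_primer_set <- function(barcodes,
                                forward = "AGAGTTTGATCMTGGCTCAG",
                                reverse = "GWATTACCGCGGCKGCTG",
                                max_barcode_mismatches = 1L,
                                max_primer_mismatches = 2L) {
  fail_if(!nzchar(forward) || !nzchar(reverse), "primers must be non-empty")
  fail_if(length(barcodes) == 0, "barcode map must be non-empty")
  fail_if(is.null(names(barcodes)) || any(!nzchar(names(barcodes))),
          "barcodes must be named by sample id")
  fail_if(any(nchar(barcodes) != 8L), "all barcodes must be 8 bases long")
  fail_if(anyDuplicated(barcodes) > 0, "barcode map must be injective")
  fail_if(anyDuplicated(names(barcodes)) > 0, "sample ids must be unique")
  structure(list(
    forward = toupper(forward),
    reverse = toupper(reverse),
    barcodes = toupper(setNames(as.character(barcodes), names(barcodes))),
    max_barcode_mismatches = as.integer(max_barcode_mismatches),
    max_primer_mismatches = as.integer(max_primer_mismatches)
  ), class = "barcoded_primer_set")
}

#' @export
print.barcoded_primer_set <- function(x, ...) {
  cat("Barcoded primer set\n")
  cat("  forward:", x$forward, "\n  reverse:", x$reverse, "\n")
  cat("  samples:", length(x$barcodes),
      " (tolerances: barcode", x$max_barcode_mismatches,
      "/ primer", x$max_primer_mismatches, "mismatches)\n")
  invisible(x)
}

# Evaluate one orientation for all reads: barcode at positions 1-8, forward
# primer anchored immediately after. Returns per-read best sample, mismatch
# totals, and tie/primer flags.
.demux_orient <- function(strs, primers) {
  bcs <- primers$barcodes
  nb <- length(bcs)
  bc_mm <- matrix(NA_integer_, length(strs), nb,
                  dimnames = list(NULL, names(bcs)))
  for (j in seq_len(nb)) bc_mm[, j] <- iupac_mismatches_at(bcs[[j]], strs, at = 1L)
  best <- apply(bc_mm, 1L, function(r) if (all(is.na(r))) NA_integer_ else min(r, na.rm = TRUE))
  nbest <- vapply(seq_along(strs), function(i) {
    if (is.na(best[i])) 0L else sum(bc_mm[i, ] == best[i], na.rm = TRUE)
  }, integer(1))
  which_best <- vapply(seq_along(strs), function(i) {
    if (is.na(best[i])) NA_integer_ else which(bc_mm[i, ] == best[i])[1L]
  }, integer(1))
  primer_mm <- iupac_mismatches_at(primers$forward, strs, at = 9L)
  list(
    bc_mm = best, n_tied = nbest, sample = names(bcs)[which_best],
    primer_mm = primer_mm,
    bc_ok = !is.na(best) & best <= primers$max_barcode_mismatches,
    primer_ok = !is.na(primer_mm) & primer_mm <= primers$max_primer_mismatches
  )
}

#' Demultiplex barcoded amplicon reads
#'
#' A read is assigned to a sample when its 8-base barcode plus the forward
#' primer are found (within the tolerances of `primers`) at the 5' end of the
#' read (forward orientation), or at the 5' end of its reverse complement
#' (reverse orientation). Reverse-orientation reads are stored
#' reverse-complemented, so all inserts share the forward orientation.
#' Assigned reads are trimmed of barcode and forward primer; when the reverse
#' primer's reverse complement is found near the 3' end it is trimmed as well
#' and `had_reverse_primer` is set. Reads whose best barcode is tied between
#' two samples are never force-assigned: they land in the unassigned bin with
#' reason `ambiguous_barcode`. Forward orientation is tried first; the
#' reverse complement is only consulted when the forward end does not qualify.
#'
#' @param reads named character vector of reads, or path to a FASTA file.
#' @param primers a [barcoded_primer_set()].
#' @param trim_reverse_primer search for and trim the downstream primer region
#'   (default TRUE).
#' @return an object of class `demux_result`: list with `assigned`
#'   (data.frame: read_id, sample_id, orientation, insert,
#'   had_reverse_primer), `unassigned` (data.frame: read_id, reason) and
#'   `per_sample` (named integer vector of assigned counts).
#' @export
demultiplex <- function(reads, primers, trim_reverse_primer = TRUE) {
  stopifnot(inherits(primers, "barcoded_primer_set"))
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    reads <- read_fasta(reads)
  }
  if (length(reads) == 0) {
    return(structure(list(
      assigned = data.frame(read_id = character(0), sample_id = character(0),
                            orientation = character(0), insert = character(0),
                            had_reverse_primer = logical(0)),
      unassigned = data.frame(read_id = character(0), reason = character(0)),
      per_sample = setNames(integer(length(primers$barcodes)), names(primers$barcodes))
    ), class = "demux_result"))
  }
  fail_if(is.null(names(reads)), "reads must be named (read ids)")
  fail_if(anyDuplicated(names(reads)) > 0, "duplicate read ids in input")
  reads <- toupper(reads)
  fwd <- .demux_orient(unname(reads), primers)
  rc <- revcomp(unname(reads))
  rev <- .demux_orient(rc, primers)

  n <- length(reads)
  plen <- nchar(primers$forward)
  rc_rev_primer <- revcomp(primers$reverse)
  sample_id <- character(n); orientation <- character(n)
  insert <- character(n); had_rp <- logical(n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    use <- NULL
    if (fwd$bc_ok[i] && fwd$primer_ok[i]) {
      if (fwd$n_tied[i] > 1L) { reason[i] <- "ambiguous_barcode"; next }
      use <- "forward"
    } else if (rev$bc_ok[i] && rev$primer_ok[i]) {
      if (rev$n_tied[i] > 1L) { reason[i] <- "ambiguous_barcode"; next }
      use <- "reverse"
    } else {
      reason[i] <- if (fwd$bc_ok[i] || rev$bc_ok[i]) "primer_mismatch" else "unknown_barcode"
      next
    }
    o <- if (use == "forward") fwd else rev
    s <- if (use == "forward") reads[[i]] else rc[[i]]
    ins <- substr(s, 9L + plen, nchar(s))
    hrp <- FALSE
    if (trim_reverse_primer && nzchar(ins)) {
      tail_len <- min(nchar(ins), nchar(rc_rev_primer) + 10L)
      tail_start <- nchar(ins) - tail_len + 1L
      hit <- match_iupac_last(rc_rev_primer, substr(ins, tail_start, nchar(ins)),
                              primers$max_primer_mismatches)
      if (!is.null(hit)) {
        ins <- substr(ins, 1L, tail_start + hit$position - 2L)
        hrp <- TRUE
      }
    }
    sample_id[i] <- o$sample[i]
    orientation[i] <- use
    insert[i] <- ins
    had_rp[i] <- hrp
  }

  ok <- is.na(reason)
  assigned <- data.frame(
    read_id = names(reads)[ok], sample_id = sample_id[ok],
    orientation = orientation[ok], insert = insert[ok],
    had_reverse_primer = had_rp[ok], stringsAsFactors = FALSE
  )
  unassigned <- data.frame(read_id = names(reads)[!ok], reason = reason[!ok],
                           stringsAsFactors = FALSE)
  per_sample <- table(factor(assigned$sample_id, levels = names(primers$barcodes)))
  structure(list(assigned = assigned, unassigned = unassigned,
                 per_sample = setNames(as.integer(per_sample), names(primers$barcodes))),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("Demultiplexing result:", nrow(x$assigned), "assigned /",
      nrow(x$unassigned), "unassigned\n")
  if (nrow(x$unassigned)) print(table(x$unassigned$reason))
  invisible(x)
}

#' Write a demultiplexing report
#'
#' Tab-delimited: one row per sample with assigned counts, then one row per
#' unassignment reason.
#'
#' @param x a `demux_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_demux_report <- function(x, path) {
  stopifnot(inherits(x, "demux_result"))
  rows <- data.frame(category = names(x$per_sample),
                     type = "assigned",
                     count = as.integer(x$per_sample))
  if (nrow(x$unassigned)) {
    tab <- table(x$unassigned$reason)
    rows <- rbind(rows, data.frame(category = names(tab),
                                   type = "unassigned",
                                   count = as.integer(tab)))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a sample-to-barcode mapping file
#'
#' Tab-delimited with columns `sample_id` and `barcode`.
#'
#' @param path file path.
#' @return named character vector (`sample_id -> barcode`).
#' @export
read_barcode_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  fail_if(!all(c("sample_id", "barcode") %in% names(df)),
          "mapping file needs columns sample_id and barcode")
  setNames(df$barcode, df$sample_id)
}

#' @rdname read_barcode_map
#' @param barcodes named character vector (`sample_id -> barcode`).
#' @export
write_barcode_map <- function(barcodes, path) {
  write.table(data.frame(sample_id = names(barcodes), barcode = unname(barcodes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
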