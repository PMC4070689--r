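# Greedy-centroid OTU clustering at an identity threshold, plus the OTU
# count-table container.

.otudyn_env <- new.env(parent = emptyenv())

.nuc_mat <- function() {
  if (is.null(.otudyn_env$submat)) {
    .otudyn_env$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
  }
  .otudyn_env$submat
}

#' Pairwise identity of two nucleotide sequences
#'
#' Global alignment with free end gaps (ends-free Needleman-Wunsch; match +1,
#' mismatch -1, gap -2). Identity is the number of matched columns divided by
#' the alignment length (columns spanned by both sequences; terminal
#' overhangs are free and excluded from the denominator, so reads of unequal
#' length — e.g. 3' truncations — are not penalized for length alone).
#'
#' A coverage condition guards the ends-free denominator: when the aligned
#' region covers less than `min_coverage` of the shorter sequence the pair is
#' not meaningfully homologous (the maximum-score alignment of two unrelated
#' sequences can be a short, spuriously identical dovetail overlap) and the
#' identity is 0. Arguments are ordered canonically before aligning, so the
#' result is exactly symmetric.
#'
#' @param a,b nucleotide strings (A/C/G/T, non-empty).
#' @param min_coverage minimum aligned fraction of the shorter sequence for
#'   a non-zero identity (default 0.5).
#' @return identity in `[0, 1]`; `identity(a, a) == 1`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")  # 1
#' pairwise_identity("AAAA", "TTTT")          # 0
#' @export
pairwise_identity <- function(a, b, min_coverage = 0.5) {
  fail_if(!nzchar(a) || !nzchar(b), "sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  if (a == b) return(1)
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = .nuc_mat(),
    gapOpening = 0, gapExtension = 2)
  len <- nchar(as.character(Biostrings::pattern(aln)))
  if (len == 0) return(0)
  pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
  span <- if (nchar(a) <= nchar(b)) {
    Biostrings::end(pat) - Biostrings::start(pat) + 1L
  } else {
    Biostrings::end(sub) - Biostrings::start(sub) + 1L
  }
  if (span < min_coverage * min(nchar(a), nchar(b))) return(0)
  Biostrings::nmatch(aln) / len
}

# Positional k-mers of a string (with duplicates).
.kmers <- function(s, k = 8L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# Conservative q-gram screen: can sequences a and b (lengths la, lb) possibly
# reach `threshold` identity? Based on the q-gram lemma (e edits destroy at
# most k q-grams each): a pair within e_allow edits shares at least
# (min_len - k + 1) - k * e_allow positional k-mers. e_allow is padded by the
# length difference to stay conservative under free end gaps.
.kmer_can_reach <- function(shared, la, lb, threshold, k = 8L) {
  e_allow <- ceiling((1 - threshold) * max(la, lb)) + abs(la - lb)
  shared >= (min(la, lb) - k + 1L) - k * e_allow
}

#' Cluster reads into OTUs with a deterministic greedy-centroid algorithm
#'
#' Reads are dereplicated into unique insert sequences and processed in order
#' of decreasing duplicate abundance (ties broken lexicographically by
#' sequence), so the result does not depend on input file order. Each unique
#' sequence joins the first existing centroid (in founding order) whose
#' [pairwise_identity()] to it is at least `threshold`; otherwise it founds a
#' new OTU with itself as centroid (representative sequence). OTUs are
#' finally relabeled `OTU1, OTU2, ...` by decreasing total read count (ties
#' by founding order).
#'
#' An optional k-mer prescreen (`prefilter`) skips centroid comparisons that
#' provably cannot reach the threshold; it never changes the clustering
#' (checked against exhaustive comparison in the test suite).
#'
#' @param reads a `demux_result`, or a data.frame with columns `read_id`,
#'   `sample_id`, `insert`.
#' @param threshold identity threshold in (0, 1]; default 0.97.
#' @param prefilter use the shared-k-mer prescreen (default TRUE).
#' @return an [otu_count_table()]; its `membership` element maps each
#'   `read_id` to its OTU.
#' @export
cluster_greedy <- function(reads, threshold = 0.97, prefilter = TRUE) {
  fail_if(!(threshold > 0 && threshold <= 1), "threshold must be in (0, 1]")
  if (inherits(reads, "demux_result")) reads <- reads$assigned
  if (nrow(reads) == 0) {
    return(otu_count_table(matrix(0L, 0, 0), rep_seqs = character(0)))
  }
  fail_if(!all(c("sample_id", "insert") %in% names(reads)),
          "reads need columns sample_id and insert")
  fail_if(any(!nzchar(reads$insert)), "empty insert sequence in input")

  # dereplicate: per-unique-sequence abundance and per-sample counts
  seqs <- reads$insert
  tab <- table(seqs)
  uniq <- names(tab)
  ab <- as.integer(tab)
  ord <- order(-ab, uniq, method = "radix")
  uniq <- uniq[ord]; ab <- ab[ord]
  lens <- nchar(uniq)

  kmer_sets <- if (prefilter) lapply(uniq, function(s) unique(.kmers(s))) else NULL
  kmer_pos <- if (prefilter) lapply(uniq, .kmers) else NULL

  centroid_idx <- integer(0)   # indices into uniq
  assign_to <- integer(length(uniq))
  for (u in seq_along(uniq)) {
    hit <- 0L
    for (ci in seq_along(centroid_idx)) {
      c_u <- centroid_idx[ci]
      if (prefilter) {
        shared <- sum(kmer_pos[[u]] %in% kmer_sets[[c_u]])
        if (!.kmer_can_reach(shared, lens[u], lens[c_u], threshold)) next
      }
      if (pairwise_identity(uniq[u], uniq[c_u]) >= threshold) { hit <- ci; break }
    }
    if (hit == 0L) {
      centroid_idx <- c(centroid_idx, u)
      hit <- length(centroid_idx)
    }
    assign_to[u] <- hit
  }

  # counts per (sample, cluster)
  cluster_of_seq <- setNames(assign_to, uniq)
  cl <- cluster_of_seq[seqs]
  samples <- sort(unique(reads$sample_id))
  counts <- table(factor(reads$sample_id, levels = samples),
                  factor(cl, levels = seq_along(centroid_idx)))
  counts <- matrix(as.integer(counts), nrow = length(samples),
                   dimnames = list(sample = samples, otu = NULL))

  # relabel by decreasing total abundance, ties by founding order
  totals <- colSums(counts)
  relab <- order(-totals, seq_along(totals), method = "radix")
  counts <- counts[, relab, drop = FALSE]
  otu_ids <- paste0("OTU", seq_along(relab))
  colnames(counts) <- otu_ids
  reps <- setNames(uniq[centroid_idx][relab], otu_ids)
  out <- otu_count_table(counts, rep_seqs = reps)
  if ("read_id" %in% names(reads)) {
    new_label <- setNames(otu_ids, as.character(relab))
    out$membership <- data.frame(read_id = reads$read_id,
                                 otu = unname(new_label[as.character(cl)]),
                                 stringsAsFactors = FALSE)
  }
  out
}

#' OTU count table
#'
#' The central abundance container: an integer matrix of read counts
#' \eqn{C_{i,j}} with samples as rows and OTUs as columns, plus one
#' representative sequence per OTU and optional taxonomy labels and sampling
#' days.
#'
#' @param counts integer matrix, samples x OTUs, with dimnames.
#' @param rep_seqs named character vector of representative sequences (one
#'   per OTU), or NULL when representatives are not available (e.g. count-
#'   level simulations).
#' @param taxonomy optional named character vector of taxonomy labels.
#' @param days optional named numeric vector of sampling days (per sample).
#' @return an object of class `otu_count_table`.
#' @export
otu_count_table <- function(counts, rep_seqs = NULL, taxonomy = NULL, days = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- unname(dimnames(counts))
  fail_if(any(counts < 0), "counts must be non-negative")
  if (ncol(counts) > 0) {
    fail_if(is.null(colnames(counts)), "counts must have OTU column names")
  }
  if (!is.null(rep_seqs) && ncol(counts) > 0) {
    fail_if(!all(colnames(counts) %in% names(rep_seqs)),
            "every OTU needs a representative sequence")
    rep_seqs <- rep_seqs[colnames(counts)]
  }
  if (!is.null(days)) {
    fail_if(!all(rownames(counts) %in% names(days)),
            "every sample needs a day when days are given")
    days <- days[rownames(counts)]
  }
  structure(list(counts = counts, rep_seqs = rep_seqs,
                 taxonomy = taxonomy, days = days),
            class = "otu_count_table")
}

#' @export
print.otu_count_table <- function(x, ...) {
  cat("OTU count table:", nrow(x$counts), "samples x", ncol(x$counts),
      "OTUs;", sum(x$counts), "reads\n")
  invisible(x)
}

#' Write / read an OTU count table as tab-delimited text
#'
#' Samples are rows, OTUs are columns; the first column holds the sample id
#' and, when available, a `day` column follows it.
#'
#' @param x an `otu_count_table`.
#' @param path file path.
#' @return `path` (write) or an `otu_count_table` (read).
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_count_table"))
  df <- data.frame(sample_id = rownames(x$counts), check.names = FALSE)
  if (!is.null(x$days)) df$day <- unname(x$days)
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fail_if(!"sample_id" %in% names(df), "missing sample_id column")
  days <- NULL
  meta <- "sample_id"
  if ("day" %in% names(df)) {
    days <- setNames(df$day, df$sample_id)
    meta <- c(meta, "day")
  }
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(m) <- df$sample_id
  otu_count_table(m, days = days)
}

#' Sparse triplet view of an OTU count table
#'
#' @param x an `otu_count_table`.
#' @return data.frame with columns `sample_id`, `otu`, `count` (non-zero
#'   cells only).
#' @export
otu_table_triplets <- function(x) {
  stopifnot(inherits(x, "otu_count_table"))
  idx <- which(x$counts > 0, arr.ind = TRUE)
  data.frame(sample_id = rownames(x$counts)[idx[, 1]],
             otu = colnames(x$counts)[idx[, 2]],
             count = x$counts[idx],
             stringsAsFactors = FALSE)
}
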