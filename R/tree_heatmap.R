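# Neighbor-joining trees, newick I/O, and tree-ordered abundance heatmaps.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou–Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined (ties broken deterministically by the lowest index
#' pair in current node order) with the standard branch-length formulas; the
#' final three nodes are resolved with the three-point formulas, giving an
#' unrooted tree. Negative branch lengths (possible for non-additive input)
#' are clamped to zero with a warning.
#'
#' @param d symmetric numeric matrix with zero diagonal and non-negative
#'   entries, labeled rows/columns, size >= 3 (a `dist` is accepted).
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  fail_if(!is.matrix(d) || nrow(d) != ncol(d), "d must be a square matrix")
  n <- nrow(d)
  fail_if(n < 3, "need at least 3 taxa")
  fail_if(any(d < 0), "distances must be non-negative")
  fail_if(max(abs(d - t(d))) > 1e-8, "distance matrix must be symmetric")
  fail_if(any(abs(diag(d)) > 1e-12), "diagonal must be zero")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  fail_if(anyDuplicated(labels) > 0, "duplicate taxon labels")

  # working set of node "newick fragments"; leaves start as their labels
  frag <- labels
  D <- d
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.10g", x)
  }
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (i, j) pair among the minima, scanning in current node order
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  # three-point formulas for the final unrooted trifurcation
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb), ",",
                frag[3], ":", fmt(lc), ");")
  if (clamped) warning("negative branch length(s) clamped to 0")
  ape::read.tree(text = txt)
}

#' Identity-based distance matrix for representative sequences
#'
#' Distances are `1 - pairwise identity` (see [pairwise_identity()]), with an
#' optional Jukes–Cantor correction
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3} p)}.
#'
#' @param seqs named character vector of sequences.
#' @param model `"raw"` (default) or `"JC69"`.
#' @return symmetric distance matrix.
#' @export
identity_distances <- function(seqs, model = c("raw", "JC69")) {
  model <- match.arg(model)
  fail_if(is.null(names(seqs)), "sequences must be named")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- 1 - pairwise_identity(seqs[[i]], seqs[[j]])
      v <- if (model == "JC69") {
        if (p >= 0.745) 3 else -0.75 * log1p(-4 * p / 3)
      } else p
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Parse / write newick trees
#'
#' Thin, validating wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Parsing rejects unbalanced parentheses (reporting the offending position)
#' and duplicate leaf labels; trees without branch lengths keep them absent
#' rather than zero.
#'
#' @param x newick text, or a path to a newick file.
#' @return an [ape::phylo] (parse) or newick string (write).
#' @export
parse_newick <- function(x) {
  text <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x), collapse = "")
  } else x
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    fail_if(depth < 0, paste0("unbalanced ')' at position ", i))
  }
  fail_if(depth != 0, paste0("unbalanced '(' (", depth, " unclosed)"))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  fail_if(is.null(tree), "newick parse error")
  fail_if(anyDuplicated(tree$tip.label) > 0, "duplicate leaf labels")
  tree
}

#' @rdname parse_newick
#' @param tree an [ape::phylo].
#' @param file optional output path; when NULL the newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(file)) }
  txt
}

#' Leaf order of a tree
#'
#' Depth-first (cladewise) leaf sequence; with `ladderize = TRUE` children
#' are first rotated by subtree size ([ape::ladderize()]) for a stable,
#' display-friendly order.
#'
#' @param tree an [ape::phylo].
#' @param ladderize rotate nodes by clade size first (default FALSE).
#' @return character vector: all leaf labels, in display order.
#' @export
leaf_order <- function(tree, ladderize = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (ladderize) tree <- ape::ladderize(tree, right = FALSE)
  tree <- stats::reorder(tree, "cladewise")
  tips <- tree$edge[, 2][tree$edge[, 2] <= ape::Ntip(tree)]
  tree$tip.label[tips]
}

#' Assemble a tree-ordered heatmap matrix
#'
#' Rows are the selected OTUs in the supplied (tree leaf) order; columns are
#' samples ordered by sampling day; cells are fractions in percent.
#'
#' @param series a `fraction_series`.
#' @param otus OTUs to include (subset of the series' OTUs).
#' @param order row order covering `otus` (e.g. from [leaf_order()]); extra
#'   ids in `order` are ignored.
#' @return object of class `heatmap_matrix`: the numeric matrix with
#'   attribute `days` (column days).
#' @export
build_heatmap <- function(series, otus, order = otus) {
  stopifnot(inherits(series, "fraction_series"))
  missing <- setdiff(otus, colnames(series$fractions))
  fail_if(length(missing) > 0,
          paste0("OTUs absent from series: ", paste(missing, collapse = ", ")))
  not_ordered <- setdiff(otus, order)
  fail_if(length(not_ordered) > 0,
          paste0("order does not cover: ", paste(not_ordered, collapse = ", ")))
  rows <- order[order %in% otus]
  col_ord <- if (is.null(series$day)) seq_len(nrow(series$fractions)) else
    base::order(series$day)
  m <- t(series$fractions[col_ord, rows, drop = FALSE])
  attr(m, "days") <- if (is.null(series$day)) NULL else series$day[col_ord]
  class(m) <- c("heatmap_matrix", class(m))
  m
}

#' Render a heatmap matrix to an image file
#'
#' @param m a `heatmap_matrix` (or plain matrix).
#' @param file output image path (`.png`); required.
#' @param scale `"linear"` (default) maps percent directly;
#'   `"log10"` maps `log10(x + 0.1)` so rare OTUs stay visible.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return `file`, invisibly.
#' @export
render_heatmap <- function(m, file, scale = c("linear", "log10"), ...) {
  scale <- match.arg(scale)
  x <- unclass(m)
  attr(x, "days") <- NULL
  if (scale == "log10") x <- log10(x + 0.1)
  pheatmap::pheatmap(x, cluster_rows = FALSE, cluster_cols = FALSE,
                     filename = file, silent = TRUE, ...)
  invisible(file)
}
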