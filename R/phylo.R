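#' Gap-threshold trimming of a protein alignment
#'
#' Keeps a column iff the fraction of rows without a gap in that column is at
#' least \code{gapThreshold} (inclusive boundary: at the default 0.5, a
#' column with exactly half its rows gapped is kept). Row order is preserved
#' and trimming is idempotent. Gap symbols are \code{-} and \code{.}.
#'
#' @param aln an \code{AAStringSet} of equal-width aligned rows.
#' @param gapThreshold minimum non-gap fraction per kept column.
#' @return list with \code{alignment} (trimmed \code{AAStringSet}) and
#'   \code{mask} (logical kept-column mask of the original width). An empty
#'   result (all columns removed) is a warning, not an error.
#' @export
trimAlignment <- function(aln, gapThreshold = 0.5) {
  if (!is(aln, "AAStringSet")) aln <- Biostrings::AAStringSet(aln)
  if (!length(aln)) stop("empty alignment")
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("alignment rows must have equal length")
  M <- do.call(rbind, strsplit(as.character(aln), ""))
  cov <- colMeans(M != "-" & M != ".")
  mask <- cov >= gapThreshold
  if (!any(mask)) {
    warning("all columns removed at gap threshold ", gapThreshold)
    out <- Biostrings::AAStringSet(rep("", length(aln)))
  } else {
    out <- Biostrings::AAStringSet(
      apply(M[, mask, drop = FALSE], 1, paste, collapse = ""))
  }
  names(out) <- names(aln)
  list(alignment = out, mask = mask)
}

#' Pairwise distances from a protein alignment
#'
#' For each pair, columns gapped (or \code{X}) in either member are ignored;
#' \code{p} is the mismatch proportion over the remaining columns, reported
#' either raw (\code{p_distance}) or Poisson-corrected
#' (\code{-log(1 - p)}).
#'
#' @param aln aligned \code{AAStringSet}.
#' @param method "p_distance" or "poisson_corrected".
#' @return a \code{dist} object.
#' @export
alignmentDistances <- function(aln, method = c("p_distance",
                                               "poisson_corrected")) {
  method <- match.arg(method)
  if (!is(aln, "AAStringSet")) aln <- Biostrings::AAStringSet(aln)
  M <- do.call(rbind, strsplit(as.character(aln), ""))
  bad <- M == "-" | M == "." | M == "X"
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !bad[i, ] & !bad[j, ]
      if (!any(ok))
        stop("no comparable columns between ", names(aln)[i], " and ",
             names(aln)[j])
      p <- mean(M[i, ok] != M[j, ok])
      d <- if (method == "p_distance") p else {
        if (p >= 1) stop("saturated pair: ", names(aln)[i], " / ",
                         names(aln)[j])
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  stats::as.dist(D)
}

#' Neighbor-joining distance tree from an alignment
#'
#' Built-in stand-in for external maximum-likelihood inference: pairwise
#' distances (see \code{\link{alignmentDistances}}) followed by
#' neighbor-joining agglomeration. Rows are sorted lexicographically by label
#' before NJ so the result is deterministic under input permutation.
#'
#' @param aln aligned \code{AAStringSet} of at least 3 sequences, or a
#'   precomputed \code{dist} object with labels.
#' @param method distance method (ignored for \code{dist} input).
#' @return an \pkg{ape} \code{phylo} tree (non-negative branch lengths).
#' @export
buildDistanceTree <- function(aln, method = c("p_distance",
                                              "poisson_corrected")) {
  if (inherits(aln, "dist")) {
    m <- as.matrix(aln)
    if (nrow(m) < 3L) stop("at least 3 sequences are required")
    ord <- order(rownames(m))
    d <- stats::as.dist(m[ord, ord])
  } else {
    if (!is(aln, "AAStringSet")) aln <- Biostrings::AAStringSet(aln)
    if (length(aln) < 3L) stop("at least 3 sequences are required")
    aln <- aln[order(names(aln))]
    d <- alignmentDistances(aln, match.arg(method))
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Test whether a leaf subset is monophyletic in an unrooted tree
#'
#' True iff the bipartition (subset | complement) appears among the tree's
#' edges; singleton subsets and the full leaf set are monophyletic by
#' convention.
#'
#' @param tree an \pkg{ape} \code{phylo}.
#' @param leaves character vector of leaf labels.
#' @return list with \code{monophyletic} (logical) and
#'   \code{bipartition} (the subset's side of the supporting split, or
#'   \code{NULL}).
#' @export
checkMonophyly <- function(tree, leaves) {
  tips <- tree$tip.label
  unknown <- setdiff(leaves, tips)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  leaves <- unique(leaves)
  if (length(leaves) <= 1L || length(leaves) == length(tips))
    return(list(monophyletic = TRUE, bipartition = leaves))
  parts <- ape::prop.part(tree)
  target <- sort(match(leaves, tips))
  comp <- sort(setdiff(seq_along(tips), target))
  for (p in parts) {
    ps <- sort(p)
    if (identical(ps, target) || identical(ps, comp))
      return(list(monophyletic = TRUE, bipartition = leaves))
  }
  list(monophyletic = FALSE, bipartition = NULL)
}

#' Export a tree with leaf annotations
#'
#' Writes valid Newick (round-trips through \code{ape::read.tree}) and a
#' companion plain-text annotation table mapping each leaf to its family,
#' architecture and taxon class, suitable for tree-decoration tools.
#'
#' @param tree an \pkg{ape} \code{phylo} with unique leaf labels.
#' @param annotations data.frame keyed by a \code{label} column; remaining
#'   columns are copied to the dataset. Unknown labels are rejected.
#' @param newick,dataset output paths.
#' @return invisibly, the paths.
#' @export
exportAnnotatedTree <- function(tree, annotations, newick, dataset) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels")
  unknown <- setdiff(annotations$label, tree$tip.label)
  if (length(unknown))
    stop("annotation refers to unknown leaves: ",
         paste(unknown, collapse = ", "))
  ape::write.tree(tree, newick)
  utils::write.table(annotations, dataset, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(newick = newick, dataset = dataset))
}
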