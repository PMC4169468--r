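#' Read a rooted strain phylogeny from newick text or a file
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree is the source
#' of the shared-ancestry matrix used by the phylogenetic mixed model, so the
#' reader enforces the properties that model assumes: a rooted tree, branch
#' lengths on every edge, unique and non-empty tip labels, and non-negative
#' branch lengths. Polytomies are accepted (treated as hard polytomies).
#'
#' @param text A newick string (terminated by `;`). Exactly one of `text` and
#'   `file` must be given.
#' @param file Path to a newick file.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @examples
#' tr <- read_newick("((a:1,b:1):1,c:2);")
#' tr$tip.label
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed newick: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("malformed newick: parser returned no tree")
  validate_phylogeny(tree)
  tree
}

# Pre-scan for the errors ape reports poorly, naming the character offset.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed newick: unbalanced ')' at offset %d", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf(
      "malformed newick: %d unclosed '(' at end of input (length %d)",
      depth, length(chars)
    ))
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf(
      "malformed newick: missing terminating ';' at offset %d", nchar(text)
    ))
  }
  invisible(TRUE)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dups, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("all branch lengths must be finite and >= 0")
  }
  # a newick string always defines a single root node; a basal multifurcation
  # is treated as a rooted hard polytomy (a star phylogeny is legitimate:
  # it means no shared ancestry)
  invisible(tree)
}

#' Write a phylogeny to newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, or `file` (invisibly) when writing.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Shared-ancestry matrix of an ultrametric phylogeny
#'
#' For strains \eqn{j} and \eqn{k}, the entry \eqn{a_{jk}} is the proportion
#' of time since the root that the two lineages were a single lineage: the
#' root-to-MRCA depth divided by the root-to-tip depth. Under Brownian trait
#' evolution the phylogenetic covariance between strain effects is
#' proportional to this matrix, so \eqn{a_{jj} = 1} and the magnitude of the
#' phylogenetic variance is carried entirely by the trait-level covariance
#' matrix it is Kronecker-multiplied with.
#'
#' Contemporaneous tips are assumed: the tree must be ultrametric to within
#' `tol` (relative spread of root-to-tip depths). Tips joined by zero-length
#' terminal branches give \eqn{a_{jk} = 1} and make the matrix singular (PSD
#' but not PD); this is allowed and reported via a warning so that downstream
#' samplers know to jitter.
#'
#' @param tree A rooted ultrametric `"phylo"` object with >= 2 leaves.
#' @param tol Relative tolerance on the spread of root-to-leaf depths.
#' @return A symmetric PSD matrix with unit diagonal, leaf labels as
#'   dimnames, in `tree$tip.label` order.
#' @examples
#' A <- shared_ancestry_matrix(read_newick("((a:1,b:1):1,c:2);"))
#' A["a", "b"] # 0.5: the a,b ancestor sits at half the root-to-tip depth
#' @export
shared_ancestry_matrix <- function(tree, tol = 1e-6) {
  validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need >= 2 leaves")
  depths <- ape::node.depth.edgelength(tree) # distance from root, all nodes
  tip_depths <- depths[seq_len(ntip)]
  total <- max(tip_depths)
  if (total <= 0) stop("degenerate tree: zero total depth")
  spread <- (max(tip_depths) - min(tip_depths)) / total
  if (spread > tol) {
    stop(sprintf(
      "tree is not ultrametric: relative leaf-depth spread %.3g exceeds %g",
      spread, tol
    ))
  }
  mrca <- ape::mrca(tree) # ntip x ntip node numbers, tip.label dimnames
  A <- matrix(depths[mrca], ntip, ntip) / total
  diag(A) <- 1
  dimnames(A) <- list(tree$tip.label, tree$tip.label)
  off <- A[upper.tri(A)]
  if (any(off >= 1 - 1e-12)) {
    warning(
      "tips with zero divergence share a_jk = 1; ",
      "the shared-ancestry matrix is singular (PSD, not PD)"
    )
  }
  A
}

#' Brownian phylogenetic covariance for one trait
#'
#' Scales the shared-ancestry matrix by a per-trait phylogenetic variance:
#' `sigma2 * A`. The multi-trait generalisation (the Kronecker product with a
#' trait covariance matrix) lives in the comparative model itself.
#'
#' @param A A shared-ancestry matrix from [shared_ancestry_matrix()].
#' @param sigma2 Phylogenetic variance, >= 0.
#' @return `sigma2 * A`.
#' @export
brownian_covariance <- function(A, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 < 0) {
    stop("`sigma2` must be a single finite number >= 0")
  }
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("`A` must be square")
  sigma2 * A
}

#' Write / read a labelled matrix as TSV
#'
#' Plain-text round-trip for shared-ancestry (or any labelled square)
#' matrices: labels in the header row and first column.
#'
#' @param A Matrix with dimnames.
#' @param file Path.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` returns
#'   `file` invisibly.
#' @export
write_matrix_tsv <- function(A, file) {
  df <- data.frame(label = rownames(A), A, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  A
}
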