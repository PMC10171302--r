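#' Gene-content clustering of genomes
#'
#' Genomes are clustered by their binary gene-content vectors with UPGMA
#' (average linkage) over Jaccard or simple-matching distances, reproducing
#' the structure of per-category presence/absence heatmaps. The resulting
#' `anf_tree` is ultrametric: node height is half the merge distance, so
#' cophenetic distances reproduce the merge distances exactly.
#'
#' @name gene_content_clustering
NULL

is_leaf <- function(node) is.null(node$children)
tree_height <- function(node) node$height

#' Binary distance between two presence vectors
#'
#' `jaccard` is 1 minus intersection over union of the 1-positions (defined as
#' 0 when both vectors are all-zero — two genomes sharing no screened genes at
#' all are treated as indistinguishable, not maximally distant);
#' `simple_matching` is the fraction of disagreeing positions. Jaccard ignores
#' shared absences, which suits sparse gene-content data.
#'
#' @param u,v binary vectors of equal length >= 1.
#' @param metric `"jaccard"` or `"simple_matching"`.
#' @return a distance in `[0, 1]`.
#' @export
#' @examples
#' binary_distance(c(1, 0, 1), c(0, 1, 1), "jaccard")
binary_distance <- function(u, v, metric = c("jaccard", "simple_matching")) {
  metric <- match.arg(metric)
  if (length(u) != length(v)) rlang::abort("vectors differ in length")
  if (!length(u)) rlang::abort("vectors must have length >= 1")
  u <- as.integer(u != 0); v <- as.integer(v != 0)
  if (metric == "jaccard") {
    uni <- sum(u | v)
    if (uni == 0) return(0)
    1 - sum(u & v) / uni
  } else {
    mean(u != v)
  }
}

#' Pairwise genome distance matrix from a presence matrix
#'
#' @param matrix a [presence_matrix] with >= 2 genomes.
#' @param metric `"jaccard"` or `"simple_matching"`.
#' @param categories optional character vector restricting the feature columns
#'   to the given ANF categories (e.g. to cluster on dispensable phytase genes
#'   only); selecting zero features is an error.
#' @return symmetric base matrix with zero diagonal and genome ids as
#'   dimnames.
#' @export
distance_matrix <- function(matrix, metric = c("jaccard", "simple_matching"),
                            categories = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "presence_matrix"))
  if (nrow(matrix$cells) < 2L) rlang::abort("need >= 2 genomes to build distances")
  cells <- matrix$cells
  if (!is.null(categories)) {
    keep <- matrix$feature_category$feature_id[
      matrix$feature_category$category_id %in% categories]
    cells <- cells[, keep, drop = FALSE]
  }
  if (ncol(cells) == 0L) rlang::abort("feature subset selects no columns")
  n <- nrow(cells)
  D <- matrix(0, n, n, dimnames = list(rownames(cells), rownames(cells)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- binary_distance(cells[i, ], cells[j, ], metric)
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration: at each step the pair of clusters at minimal
#' average distance is merged at height `distance / 2`; ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled by
#' its smallest leaf). The tree is ultrametric and its cophenetic distances
#' equal the merge distances.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param labels leaf labels; defaults to `rownames(D)`.
#' @return an `anf_tree`: a list with the recursive `$root` node (leaves carry
#'   `label`; internal nodes `height` and two `children`) and `$labels`.
#' @export
#' @examples
#' D <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' leaf_order(upgma(D))
upgma <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  if (is.null(labels)) rlang::abort("labels required (or rownames on D)")
  n <- length(labels)
  if (n < 2L) rlang::abort("need >= 2 labels")
  if (nrow(D) != n || ncol(D) != n) rlang::abort("D dimensions do not match labels")
  if (any(abs(D - t(D)) > 1e-12)) rlang::abort("D must be symmetric")
  if (any(diag(D) != 0)) rlang::abort("D must have a zero diagonal")
  if (any(D < 0)) rlang::abort("D must be non-negative")
  if (anyDuplicated(labels)) rlang::abort("labels must be unique")

  nodes <- lapply(labels, function(l) list(label = l, height = 0, size = 1L,
                                           min_leaf = l))
  active <- seq_len(n)
  dimnames(D) <- NULL
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_len(length(active) - 1L)) {
      for (jj in seq((ii + 1L), length(active))) {
        i <- active[ii]; j <- active[jj]
        d <- D[i, j]
        li <- nodes[[i]]$min_leaf; lj <- nodes[[j]]$min_leaf
        key <- sort(c(li, lj))
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    ni <- nodes[[i]]; nj <- nodes[[j]]
    kids <- if (ni$min_leaf <= nj$min_leaf) list(ni, nj) else list(nj, ni)
    kids <- lapply(kids, function(k) k[setdiff(names(k), c("size", "min_leaf"))])
    merged <- list(height = best$d / 2, children = kids,
                   size = ni$size + nj$size, min_leaf = min(ni$min_leaf, nj$min_leaf))
    # weighted average keeps d(new, k) equal to the mean over all leaf pairs
    for (k in setdiff(active, c(i, j))) {
      dk <- (ni$size * D[i, k] + nj$size * D[j, k]) / (ni$size + nj$size)
      D[i, k] <- dk; D[k, i] <- dk
    }
    nodes[[i]] <- merged
    active <- setdiff(active, j)
  }
  root <- nodes[[active]]
  root <- root[setdiff(names(root), c("size", "min_leaf"))]
  structure(list(root = root, labels = sort(labels)), class = "anf_tree")
}

#' @export
print.anf_tree <- function(x, ...) {
  cat(sprintf("<anf_tree: %d leaves, root height %g>\n",
              length(x$labels), tree_height(x$root)))
  invisible(x)
}

#' Deterministic left-to-right leaf order of a tree
#'
#' At each internal node the child whose smallest leaf label sorts first comes
#' first, so heatmap row order is stable across runs and label permutations.
#'
#' @param tree an `anf_tree`.
#' @return character vector of leaf labels.
#' @export
leaf_order <- function(tree) {
  stopifnot(inherits(tree, "anf_tree"))
  walk <- function(node) {
    if (is_leaf(node)) return(node$label)
    parts <- lapply(node$children, walk)
    mins <- vapply(parts, min, character(1))
    unlist(parts[order(mins)])
  }
  walk(tree$root)
}

#' Cophenetic distance matrix of an `anf_tree`
#'
#' The distance between two leaves is twice the height of their lowest common
#' ancestor; for UPGMA trees this reproduces the merge distances.
#'
#' @param tree an `anf_tree`.
#' @return symmetric matrix over `tree$labels`.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "anf_tree"))
  labs <- tree$labels
  M <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  fill <- function(node) {
    if (is_leaf(node)) return(node$label)
    parts <- lapply(node$children, fill)
    for (a in seq_len(length(parts) - 1L)) {
      for (b in seq((a + 1L), length(parts))) {
        M[parts[[a]], parts[[b]]] <<- 2 * node$height
        M[parts[[b]], parts[[a]]] <<- 2 * node$height
      }
    }
    unlist(parts)
  }
  fill(tree$root)
  M
}

#' Tidy an `anf_tree` into a node/edge tibble
#'
#' @param x an `anf_tree`.
#' @param ... unused.
#' @return tibble with one row per node: `node`, `parent`, `height`, `label`
#'   (`NA` for internal nodes).
#' @method tidy anf_tree
#' @export
tidy.anf_tree <- function(x, ...) {
  rows <- list()
  nid <- 0L
  walk <- function(node, parent) {
    nid <<- nid + 1L
    id <- nid
    rows[[id]] <<- tibble::tibble(
      node = id, parent = parent, height = tree_height(node),
      label = if (is_leaf(node)) node$label else NA_character_)
    if (!is_leaf(node)) for (ch in node$children) walk(ch, id)
  }
  walk(x$root, NA_integer_)
  dplyr::bind_rows(rows)
}
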