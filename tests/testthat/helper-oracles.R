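# Independent brute-force oracles: each recomputes from first principles,
# sharing no code path with the implementation it checks.

# Average-linkage cophenetic matrix, recomputing every cluster-pair distance
# from the ORIGINAL matrix at every step (mean over all leaf pairs), with the
# same tie rule (smallest lexicographic pair of cluster-minimum labels).
oracle_upgma_cophenetic <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(labs)
  coph <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq((i + 1L), length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]]) {
      coph[a, b] <- best$d; coph[b, a] <- best$d
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# union-find over an explicit edge list
oracle_components <- function(vertices, edges_from, edges_to) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(edges_from)) {
    ra <- find(edges_from[k]); rb <- find(edges_to[k])
    if (ra != rb) parent[[rb]] <- ra
  }
  vapply(vertices, find, character(1))
}

# enumerate all size-k subsets; return best objective value(s) and argmaxes
oracle_best_subsets <- function(cells, k, objective = c("genes", "lex"),
                                feature_category = NULL) {
  objective <- match.arg(objective)
  ids <- sort(rownames(cells))
  subsets <- utils::combn(ids, k, simplify = FALSE)
  score <- function(s) {
    u <- as.integer(colSums(cells[s, , drop = FALSE]) > 0)
    if (objective == "genes") sum(u) else {
      cats <- unique(feature_category$category_id[u == 1L])
      c(length(cats), sum(u))
    }
  }
  vals <- lapply(subsets, score)
  keys <- vapply(vals, paste, character(1), collapse = "/")
  ord <- do.call(order, c(as.data.frame(do.call(rbind, vals)),
                          list(decreasing = TRUE)))
  best <- vals[[ord[1]]]
  argmax <- subsets[vapply(vals, identical, logical(1), y = best)]
  list(best = best, argmax = argmax)
}
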