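#' Euclidean distances between accessions
#'
#' Pairwise Euclidean distances on the rows of a parameter matrix.  By
#' default raw parameter values are used (so dendrogram heights are in
#' raw-parameter units); `standardize = TRUE` z-scores each column first.
#'
#' @param m a [parameter_matrix()] or plain numeric matrix (rownames =
#'   labels).
#' @param standardize z-score columns before computing distances.
#' @return a `stats::dist` object.
#' @export
euclidean_distances <- function(m, standardize = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 accessions")
  if (anyNA(m)) stop("missing values in parameter matrix")
  if (standardize) m <- scale(m)
  dist(m, method = "euclidean")
}

as_distance_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(m < 0)) stop("distances must be nonnegative")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("L", seq_len(nrow(m)))
  m
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Unweighted pair-group agglomeration: at each step the two clusters at
#' minimal average inter-cluster distance merge at a height equal to that
#' average.  Ties are broken deterministically by merging the pair whose
#' (lexicographically smallest member) labels compare smallest, so results
#' are platform-independent.  The returned object has the `hclust`
#' structure, so [stats::cophenetic()], [stats::cutree()] and
#' [ape::as.phylo()] apply directly; UPGMA guarantees monotone merge
#' heights and ultrametric cophenetic distances.
#'
#' @param d a `dist` object or symmetric distance matrix with labels.
#' @return an object of class `c("upgma", "hclust")`.
#' @export
upgma <- function(d) {
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 labels")
  labels <- rownames(dm)
  code <- -seq_len(n)          # hclust convention: singletons are negative
  size <- rep(1L, n)
  minlab <- labels             # lexicographic representative per cluster
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (aj in (ai + 1L):length(active)) {
        i <- active[ai]; j <- active[aj]
        dij <- dm[i, j]
        key <- sort(c(minlab[i], minlab[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = dij, i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best$d
    # unweighted average: new distances weighted by cluster sizes
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      dm[i, others] <- (size[i] * dm[i, others] + size[j] * dm[j, others]) /
        (size[i] + size[j])
      dm[others, i] <- dm[i, others]
    }
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    code[i] <- step
    active <- setdiff(active, j)
  }
  leaf_order <- function(k) {
    unlist(lapply(merge[k, ], function(v) if (v < 0) -v else leaf_order(v)))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L), labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "euclidean"),
            class = c("upgma", "hclust"))
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the n(n-1)/2 original distances and the
#' cophenetic distances implied by the tree (the merge height at which each
#' pair first joins).  Values near 1 mean the tree faithfully represents
#' the distance structure.
#'
#' @param tree an `hclust`-structured tree (e.g. from [upgma()]).
#' @param d the original `dist` object or distance matrix.
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, d) {
  dm <- as_distance_matrix(d)
  if (!setequal(tree$labels, rownames(dm)))
    stop("tree leaves and distance labels differ")
  cm <- as.matrix(cophenetic(tree))[rownames(dm), rownames(dm)]
  lower <- lower.tri(dm)
  if (sd(dm[lower]) == 0)
    stop("degenerate input: all pairwise distances equal")
  cor(dm[lower], cm[lower])
}

#' Cut a dendrogram into clusters at a height
#'
#' @param tree an `hclust`-structured tree.
#' @param height cut height (>= 0); merges at exactly this height are kept
#'   together.
#' @return named integer vector of cluster memberships (clusters numbered
#'   in leaf order).
#' @export
cut_clusters <- function(tree, height) {
  if (height < 0) stop("cut height must be >= 0")
  cutree(tree, h = height)
}

#' Gower similarity over quantitative parameters
#'
#' S(i, j) = mean over columns k of 1 - |x_ik - x_jk| / range_k.  Columns
#' with zero range carry no information and contribute similarity 1.
#'
#' @param m a [parameter_matrix()] or numeric matrix.
#' @return symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @export
gower_similarity <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 accessions")
  if (anyNA(m)) stop("missing values in parameter matrix")
  rng <- apply(m, 2, function(v) diff(range(v)))
  n <- nrow(m)
  S <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      contrib <- ifelse(rng > 0, 1 - abs(m[i, ] - m[j, ]) / rng, 1)
      S[i, j] <- S[j, i] <- mean(contrib)
    }
  }
  S
}

#' Principal coordinate analysis
#'
#' Metric MDS by eigendecomposition of the Gower-centered matrix
#' -D^2/2.  Similarities are converted to distances with d = 1 - S
#' (default) or the metric-preserving d = sqrt(1 - S).  Axes with positive
#' eigenvalues are retained; the per-axis variance share divides by the sum
#' of absolute eigenvalues by default (`denominator = "absolute"`, the
#' convention of the classical paleontological-statistics software, which
#' accounts for negative eigenvalues of non-embeddable distances), or by
#' the sum of positive eigenvalues only.
#'
#' @param x similarity matrix (unit diagonal, e.g. [gower_similarity()]),
#'   or a `dist`/distance matrix used as-is.
#' @param transform similarity-to-distance transform: `"linear"` (1 - S,
#'   default) or `"sqrt"` (sqrt(1 - S)).
#' @param denominator variance-share denominator: `"absolute"` (default)
#'   or `"positive"`.
#' @return object of class `karyo_pcoa`: list with `points` (labels x
#'   axes), `eigenvalues` (all, descending), `percent` and
#'   `cumulative_percent` (retained axes), `negative_eigenvalues`.
#' @export
karyo_pcoa <- function(x, transform = c("linear", "sqrt"),
                       denominator = c("absolute", "positive")) {
  transform <- match.arg(transform)
  denominator <- match.arg(denominator)
  if (inherits(x, "dist")) {
    D <- as_distance_matrix(x)
  } else {
    m <- as.matrix(x)
    if (all(abs(diag(m) - 1) < 1e-9)) {              # similarity input
      D <- if (transform == "sqrt") sqrt(pmax(1 - m, 0)) else 1 - m
      diag(D) <- 0
      dimnames(D) <- dimnames(m)
      D <- as_distance_matrix(D)
    } else {
      D <- as_distance_matrix(m)
    }
  }
  n <- nrow(D)
  J <- diag(n) - 1 / n
  G <- J %*% (-D^2 / 2) %*% J
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- eig$values
  tol <- 1e-9 * max(abs(ev), 1e-12)
  pos <- which(ev > tol)
  if (!length(pos))
    stop("degenerate input: no positive eigenvalues (all rows identical?)")
  denom <- if (denominator == "absolute") sum(abs(ev)) else sum(ev[pos])
  pts <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  dimnames(pts) <- list(rownames(D), paste0("Axis", seq_along(pos)))
  pct <- 100 * ev[pos] / denom
  structure(list(points = pts, eigenvalues = ev, percent = pct,
                 cumulative_percent = cumsum(pct),
                 negative_eigenvalues = ev[ev < -tol],
                 transform = transform, denominator = denominator),
            class = "karyo_pcoa")
}

#' @export
print.karyo_pcoa <- function(x, ...) {
  cat(sprintf("<karyo_pcoa> %d points, %d positive axes (%s distance, %s denominator)\n",
              nrow(x$points), ncol(x$points), x$transform, x$denominator))
  k <- min(4L, ncol(x$points))
  cat(sprintf("  axis %d: %.2f%% (cumulative %.2f%%)\n",
              seq_len(k), x$percent[seq_len(k)],
              x$cumulative_percent[seq_len(k)]), sep = "")
  invisible(x)
}

#' Asymmetry scatter specification (CV_CL vs M_CA)
#'
#' One labeled point per accession, interchromosomal asymmetry (CV_CL) on
#' the x axis and intrachromosomal asymmetry (M_CA) on the y axis.
#'
#' @param x karyotype summary data frame ([summarize_cohort()] /
#'   [daucus_karyotypes()] schema with `cv_cl`, `m_ca` columns) or a
#'   [parameter_matrix()].
#' @return object of class `scatter_spec`: list with `points` (data frame
#'   `label`, `x`, `y`), `xlab`, `ylab`.  Empty input gives an empty spec.
#' @export
asymmetry_scatter <- function(x) {
  pts <- if (inherits(x, "parameter_matrix")) {
    data.frame(label = rownames(x), x = x[, "CV_CL"], y = x[, "M_CA"],
               stringsAsFactors = FALSE)
  } else {
    x <- as.data.frame(x, check.names = FALSE)
    data.frame(label = if ("accession" %in% names(x)) x$accession else rownames(x),
               x = x$cv_cl, y = x$m_ca, stringsAsFactors = FALSE)
  }
  rownames(pts) <- NULL
  structure(list(points = pts, xlab = "CV_CL", ylab = "M_CA"),
            class = "scatter_spec")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from merge heights (each leaf-to-root path spans
#' half the cophenetic distance, the usual ultrametric convention).
#'
#' @param tree an `hclust`-structured tree.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to `path`.
#' @export
as_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
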