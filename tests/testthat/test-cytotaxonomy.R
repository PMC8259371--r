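test_that("Euclidean distances match a double-loop oracle", {
  m <- matrix(c(0, 0, 0, 3, 4, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(as.vector(euclidean_distances(m)), 5)

  pm <- daucus_parameter_matrix()
  d <- as.matrix(euclidean_distances(pm))
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16)
    oracle[i, j] <- sqrt(sum((pm[i, ] - pm[j, ])^2))
  expect_equal(unname(d), oracle, tolerance = 1e-12)

  expect_equal(as.vector(euclidean_distances(rbind(pm[1, ], pm[1, ]))), 0)
  pm2 <- pm; pm2[1, 1] <- NA
  expect_error(euclidean_distances(unclass(pm2)), "missing")
  # standardized variant: columns z-scored first
  ds <- as.matrix(euclidean_distances(pm, standardize = TRUE))
  expect_equal(unname(ds), unname(as.matrix(dist(scale(pm)))), tolerance = 1e-12)
})

test_that("UPGMA: hand example, hclust oracle, ultrametricity", {
  dm <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(dm)
  expect_equal(tree$height, c(2, 5))          # (A,B) at 2, then C at (4+6)/2

  two <- upgma(matrix(c(0, 3, 3, 0), 2, 2,
                      dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(two$height, 3)

  set.seed(42)
  for (n in c(4, 6, 8)) {
    for (rep in 1:4) {
      pts <- matrix(rnorm(n * 3), n)
      rownames(pts) <- paste0("s", seq_len(n))
      d <- dist(pts)
      tree <- upgma(d)
      ref <- hclust(d, method = "average")
      expect_equal(sort(tree$height), sort(ref$height), tolerance = 1e-9)
      # cophenetic distances identical to the independent oracle...
      cm <- as.matrix(cophenetic(tree))
      expect_equal(cm, brute_cophenetic(tree)[rownames(cm), rownames(cm)],
                   tolerance = 1e-12)
      # ...and to hclust's
      ref_cm <- as.matrix(cophenetic(ref))[rownames(cm), rownames(cm)]
      expect_equal(cm, ref_cm, tolerance = 1e-9)
      # ultrametric: max over any path dominates
      for (i in 1:(n - 1)) for (j in (i + 1):n) for (k in seq_len(n))
        expect_lte(cm[i, j], max(cm[i, k], cm[k, j]) + 1e-12)
      expect_true(all(diff(tree$height) >= -1e-12))   # monotone heights
    }
  }
})

test_that("UPGMA ties break lexicographically", {
  # equilateral: all three merges tie at 1; (A, B) must merge first
  dm <- matrix(1, 3, 3, dimnames = list(c("B", "C", "A"), c("B", "C", "A")))
  diag(dm) <- 0
  tree <- upgma(dm)
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("A", "B"))
})

test_that("cophenetic correlation: exact trees, fixture value, degeneracy", {
  # ultrametric input is represented exactly -> correlation 1
  dm <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tree <- upgma(dm)
  expect_equal(cophenetic_correlation(tree, dm), 1, tolerance = 1e-12)

  eq <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(eq) <- 0
  expect_error(cophenetic_correlation(upgma(eq), eq), "degenerate")

  # agreement with a direct pairwise computation on random input
  set.seed(7)
  pts <- matrix(rnorm(14), 7)
  rownames(pts) <- letters[1:7]
  d <- dist(pts)
  tree <- upgma(d)
  dm2 <- as.matrix(d)
  cm <- brute_cophenetic(tree)[rownames(dm2), rownames(dm2)]
  lower <- lower.tri(dm2)
  expect_equal(cophenetic_correlation(tree, d),
               cor(dm2[lower], cm[lower]), tolerance = 1e-12)
})

test_that("cut_clusters: limits and monotone cluster counts", {
  set.seed(13)
  pts <- matrix(rnorm(12), 6)
  rownames(pts) <- paste0("s", 1:6)
  tree <- upgma(dist(pts))
  expect_equal(length(unique(cut_clusters(tree, 0))), 6)
  expect_equal(length(unique(cut_clusters(tree, max(tree$height) + 1))), 1)
  heights <- seq(0, max(tree$height) + 0.5, length.out = 12)
  counts <- vapply(heights, function(h) length(unique(cut_clusters(tree, h))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(cut_clusters(tree, -1), ">= 0")
})

test_that("Gower similarity: limits, hand values, constant columns", {
  m <- matrix(c(1, 10, 3, 30, 2, 20), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  S <- gower_similarity(m)
  expect_equal(diag(S), setNames(rep(1, 3), rownames(S)))
  expect_equal(S["a", "b"], 0)               # extremes of every column
  expect_equal(S["a", "c"], mean(c(1 - 1 / 2, 1 - 10 / 20)))
  expect_equal(S["b", "c"], 0.5)
  expect_true(all(S >= 0 & S <= 1))

  mc <- cbind(m, 5)                          # constant column -> similarity 1
  Sc <- gower_similarity(mc)
  expect_equal(Sc["a", "b"], mean(c(0, 0, 1)))
})

test_that("PCoA: symmetric cases, reconstruction, sign-invariant oracle", {
  # 3 points, equilateral distances: two equal axes at 50% each
  eq <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(eq) <- 0
  ord <- karyo_pcoa(as.dist(eq))
  expect_equal(ord$percent[1], ord$percent[2], tolerance = 1e-9)
  expect_equal(ord$cumulative_percent[2], 100, tolerance = 1e-6)

  # collinear points: first axis carries everything
  line <- dist(matrix(c(0, 1, 3), dimnames = list(c("p", "q", "r"), NULL)))
  ordl <- karyo_pcoa(line)
  expect_equal(ordl$percent[1], 100, tolerance = 1e-6)

  # Euclidean-embeddable input: distances reproduced to 1e-9,
  # coordinates match cmdscale up to axis sign
  set.seed(5)
  pts <- matrix(rnorm(24), 8)
  rownames(pts) <- paste0("s", 1:8)
  d <- dist(pts)
  ord2 <- karyo_pcoa(d)
  expect_equal(unname(as.matrix(dist(ord2$points))), unname(as.matrix(d)),
               tolerance = 1e-9)
  ref <- cmdscale(d, k = ncol(ord2$points), eig = TRUE)
  for (ax in seq_len(ncol(ord2$points))) {
    expect_true(isTRUE(all.equal(ord2$points[, ax], ref$points[, ax],
                                 tolerance = 1e-6)) ||
                isTRUE(all.equal(ord2$points[, ax], -ref$points[, ax],
                                 tolerance = 1e-6)))
  }

  expect_error(karyo_pcoa(as.dist(matrix(0, 3, 3))), "degenerate")
})

test_that("sqrt Gower distance is Euclidean-embeddable on the fixture", {
  S <- gower_similarity(daucus_parameter_matrix())
  ord <- karyo_pcoa(S, transform = "sqrt")
  expect_lt(abs(min(c(ord$eigenvalues, 0))), 1e-9)
  # linear transform is allowed negative eigenvalues; they are reported
  ordl <- karyo_pcoa(S, transform = "linear")
  expect_true(length(ordl$negative_eigenvalues) > 0)
  # positive-only denominator makes retained shares sum to 100
  ordp <- karyo_pcoa(S, denominator = "positive")
  expect_equal(sum(ordp$percent), 100, tolerance = 1e-9)
})

test_that("asymmetry scatter: labeled points and the outgroup extremes", {
  tab <- daucus_karyotypes()
  spec <- asymmetry_scatter(tab)
  expect_equal(nrow(spec$points), 16)
  expect_equal(spec$points$label, tab$accession)
  orl <- spec$points[spec$points$label == "orl", ]
  expect_equal(orl$x, max(spec$points$x))    # max interchromosomal asymmetry
  expect_equal(orl$y, min(spec$points$y))    # min intrachromosomal asymmetry

  empty <- asymmetry_scatter(tab[0, ])
  expect_equal(nrow(empty$points), 0)
  svg <- render_scatter(empty)
  expect_match(svg[1], "^<svg ")
  expect_equal(svg[length(svg)], "</svg>")
})

test_that("Newick export round-trips through ape", {
  pm <- daucus_parameter_matrix()
  tree <- upgma(euclidean_distances(pm))
  nwk <- as_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(pm))
  # leaf-to-leaf patristic distances equal cophenetic distances
  pat <- ape::cophenetic.phylo(phy)[rownames(pm), rownames(pm)]
  cm <- as.matrix(cophenetic(tree))[rownames(pm), rownames(pm)]
  expect_equal(pat, cm, tolerance = 1e-9)
})
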