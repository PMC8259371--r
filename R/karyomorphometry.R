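#' Classify centromere position from the arm ratio (Levan)
#'
#' Chromosomes are classed by the arm ratio r = q/p into metacentric (m,
#' r in 1.0-1.7), submetacentric (sm, 1.7-3.0), subtelocentric (st,
#' 3.0-7.0) and telocentric-range (t, r > 7.0).  A ratio falling exactly on
#' a boundary is assigned to the less asymmetric class (r = 1.7 is m,
#' r = 3 is sm, r = 7 is st), making the classification a total function.
#'
#' @param r numeric vector of arm ratios, all >= 1.
#' @return character vector of class labels among `"m"`, `"sm"`, `"st"`,
#'   `"t"`.
#' @examples
#' classify_levan(c(1, 1.7, 2.5, 7.0001))
#' @export
classify_levan <- function(r) {
  if (any(!is.finite(r)) || any(r < 1))
    stop("arm ratio must be finite and >= 1")
  as.character(cut(r, breaks = c(0, 1.7, 3, 7, Inf),
                   labels = c("m", "sm", "st", "t"), right = TRUE))
}

#' Per-chromosome statistics from arm lengths
#'
#' For canonicalized arms 0 < p <= q: total length CL = p + q, centromeric
#' index CI = 100 p / (p + q) (short-arm convention, so CI <= 50), arm
#' ratio r = q/p, and the Levan class.
#'
#' @param p,q short- and long-arm lengths (um); vectors recycle as usual.
#' @return data frame with columns `p`, `q`, `cl`, `ci`, `r`, `levan`.
#' @examples
#' chromosome_stats(c(2, 1), c(2, 3))
#' @export
chromosome_stats <- function(p, q) {
  if (any(p <= 0)) stop("short arm p must be > 0")
  if (any(p > q)) stop("p > q: canonicalize arms so the short arm is p")
  cl <- p + q
  data.frame(p = p, q = q, cl = cl, ci = 100 * p / cl, r = q / p,
             levan = classify_levan(q / p), stringsAsFactors = FALSE)
}

# Pairing cost between chromosomes i and j of one plate: relative length
# difference plus centromeric-index difference scaled to its 0-50 range.
pair_cost_matrix <- function(stats) {
  mcl <- mean(stats$cl)
  abs(outer(stats$cl, stats$cl, "-")) / mcl +
    abs(outer(stats$ci, stats$ci, "-")) / 50
}

# All perfect matchings are infeasible beyond small n, so pairing is greedy
# on decreasing length with 2-opt partner-swap refinement; tests check it
# against exhaustive minimum-cost matching at n <= 5.
match_pairs <- function(cost, order_by) {
  n2 <- nrow(cost)
  ord <- order(order_by, decreasing = TRUE)
  unpaired <- ord
  pairs <- matrix(0L, nrow = n2 / 2, ncol = 2)
  k <- 0L
  while (length(unpaired) > 1L) {
    i <- unpaired[1]
    rest <- unpaired[-1]
    j <- rest[which.min(cost[i, rest])]
    k <- k + 1L
    pairs[k, ] <- c(i, j)
    unpaired <- setdiff(unpaired, c(i, j))
  }
  repeat {
    improved <- FALSE
    np <- nrow(pairs)
    if (np < 2L) break
    for (a in seq_len(np - 1L)) for (b in (a + 1L):np) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k1 <- pairs[b, 1]; l <- pairs[b, 2]
      base <- cost[i, j] + cost[k1, l]
      alt1 <- cost[i, k1] + cost[j, l]
      alt2 <- cost[i, l] + cost[j, k1]
      if (alt1 < base - 1e-12 && alt1 <= alt2) {
        pairs[a, ] <- c(i, k1); pairs[b, ] <- c(j, l); improved <- TRUE
      } else if (alt2 < base - 1e-12) {
        pairs[a, ] <- c(i, l); pairs[b, ] <- c(j, k1); improved <- TRUE
      }
    }
    if (!improved) break
  }
  pairs
}

#' Pair homologs within a metaphase plate
#'
#' Collapses the 2n measured chromosomes of one plate to a haploid
#' complement of n chromosomes by pairing putative homologs and averaging
#' each pair arm-wise.  The default `"matched"` mode minimizes a pairing
#' cost combining relative length difference and centromeric-index
#' difference (|dCL|/mean CL + |dCI|/50), so same-length chromosomes with
#' different centromere positions are not mixed; `"sorted"` simply pairs
#' consecutive chromosomes after sorting by decreasing length.
#'
#' @param plate data frame with columns `p`, `q` (2n rows, canonicalized),
#'   e.g. one element of `accession_dataset$plates`.
#' @param method `"matched"` (default) or `"sorted"`.
#' @return haploid complement: data frame of n rows (mean `p`, `q` plus
#'   [chromosome_stats()] columns), sorted by decreasing `cl`.
#' @export
pair_homologs <- function(plate, method = c("matched", "sorted")) {
  method <- match.arg(method)
  n2 <- nrow(plate)
  if (n2 %% 2L != 0L)
    stop("odd chromosome count (", n2, "); cannot pair homologs")
  stats <- chromosome_stats(plate$p, plate$q)
  pairs <- if (method == "matched") {
    match_pairs(pair_cost_matrix(stats), stats$cl)
  } else {
    ord <- order(stats$cl, decreasing = TRUE)
    matrix(ord, ncol = 2, byrow = TRUE)
  }
  p <- (stats$p[pairs[, 1]] + stats$p[pairs[, 2]]) / 2
  q <- (stats$q[pairs[, 1]] + stats$q[pairs[, 2]]) / 2
  out <- chromosome_stats(p, q)
  out <- out[order(out$cl, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Aligns a plate's sorted haploid complement to a reference complement:
# starts from the rank (identity) assignment and applies 2-opt swaps on the
# homolog-pairing cost, so chromosomes of near-equal length but different
# centromere position are matched to their like across plates instead of
# by rank alone.  Reduces to pure rank alignment when no swap lowers cost
# (in particular for noiseless plates).
align_complement <- function(h, ref) {
  n <- nrow(ref)
  cost <- abs(outer(ref$cl, h$cl, "-")) / mean(ref$cl) +
    abs(outer(ref$ci, h$ci, "-")) / 50
  assign <- seq_len(n)
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      base <- cost[i, assign[i]] + cost[j, assign[j]]
      alt <- cost[i, assign[j]] + cost[j, assign[i]]
      if (alt < base - 1e-12) {
        assign[c(i, j)] <- assign[c(j, i)]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  h[assign, , drop = FALSE]
}

#' Mean haploid karyotype of an accession
#'
#' Per plate, homologs are paired ([pair_homologs()]) and the haploid
#' complement sorted by decreasing length; across plates, chromosomes are
#' then averaged position-wise, longest with longest, with a local
#' refinement that aligns near-equal-length chromosomes across plates by
#' centromere position as well as length (see Details).  With
#' `averaging = "relative"` each plate's lengths are first expressed
#' relative to that plate's haploid total and rescaled by the mean total,
#' discounting condensation differences between plates; the default
#' `"absolute"` averages raw micrometre values.
#'
#' @details Cross-plate alignment starts from the per-plate rank order and
#' refines it with pairwise swaps minimizing the homolog-pairing cost
#' against the provisional rank-wise average.  Without the refinement,
#' measurement noise lets chromosomes of near-identical length but
#' different centromere position trade ranks between plates, mixing their
#' centromeric indices and biasing the CV of CI downward.
#'
#' @param dataset an [accession_dataset()].
#' @param pairing passed to [pair_homologs()].
#' @param averaging `"absolute"` (default) or `"relative"`.
#' @return object of class `mean_karyotype`: data frame with columns
#'   `position`, `p`, `q`, `cl`, `ci`, `r`, `levan`, ordered by decreasing
#'   `cl`, with attributes `accession_id`, `two_n`, `n_plates`.
#' @export
mean_karyotype <- function(dataset, pairing = c("matched", "sorted"),
                           averaging = c("absolute", "relative")) {
  pairing <- match.arg(pairing)
  averaging <- match.arg(averaging)
  if (!inherits(dataset, "accession_dataset")) stop("need an accession_dataset")
  if (!length(dataset$plates)) stop("empty dataset: no plates")
  haploids <- lapply(dataset$plates, pair_homologs, method = pairing)
  if (averaging == "relative") {
    totals <- vapply(haploids, function(h) sum(h$cl), numeric(1))
    mt <- mean(totals)
    haploids <- lapply(seq_along(haploids), function(i) {
      h <- haploids[[i]]
      chromosome_stats(h$p / totals[i] * mt, h$q / totals[i] * mt)
    })
  }
  n <- nrow(haploids[[1]])
  rank_mean <- function(hs) {
    pm <- matrix(vapply(hs, function(h) h$p, numeric(n)), nrow = n)
    qm <- matrix(vapply(hs, function(h) h$q, numeric(n)), nrow = n)
    chromosome_stats(rowMeans(pm), rowMeans(qm))
  }
  ref <- rank_mean(haploids)                # provisional rank-wise average
  haploids <- lapply(haploids, align_complement, ref = ref)
  out <- rank_mean(haploids)
  out <- out[order(out$cl, decreasing = TRUE), , drop = FALSE]
  out <- cbind(position = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("mean_karyotype", "data.frame"),
            accession_id = dataset$accession_id, two_n = dataset$two_n,
            n_plates = length(dataset$plates))
}

as_karyotype_df <- function(x) {
  if (!all(c("cl", "ci", "r") %in% names(x)))
    stop("expected a mean_karyotype-like data frame with cl/ci/r columns")
  x
}

#' Haploid karyotype formula
#'
#' Counts of Levan classes over the haploid complement, rendered as e.g.
#' `"2m + 8sm"` (classes listed m, sm, st, t; zero counts omitted).
#'
#' @param karyotype a [mean_karyotype()] (or data frame with a `levan`
#'   column).
#' @return list with `counts` (named integer vector m/sm/st/t) and `text`.
#' @export
karyotype_formula <- function(karyotype) {
  lv <- factor(karyotype$levan, levels = c("m", "sm", "st", "t"))
  counts <- setNames(as.integer(table(lv)), levels(lv))
  list(counts = counts, text = format_kf(counts))
}

#' Total haploid chromosome length and chromosome length range
#'
#' `thcl()` is the sum of mean chromosome lengths over the haploid
#' complement (um); `clr()` the (shortest, longest) mean chromosome length.
#'
#' @param karyotype a [mean_karyotype()].
#' @return `thcl()`: numeric scalar; `clr()`: named numeric `c(min, max)`.
#' @export
thcl <- function(karyotype) sum(as_karyotype_df(karyotype)$cl)

#' @rdname thcl
#' @export
clr <- function(karyotype) {
  cl <- as_karyotype_df(karyotype)$cl
  c(min = min(cl), max = max(cl))
}

cv_percent <- function(v, sd_type) {
  if (length(v) < 2L) stop("coefficient of variation needs n >= 2 chromosomes")
  s <- sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  100 * s / mean(v)
}

#' Karyotype asymmetry indices
#'
#' Interchromosomal asymmetry `cv_cl()` is the coefficient of variation of
#' chromosome length, 100 * SD(CL)/mean(CL); `cv_ci()` the CV of the
#' centromeric index (centromere-position heterogeneity); and `m_ca()` the
#' mean centromeric asymmetry, 100 * mean((q - p)/(q + p)), a pure
#' intrachromosomal measure.  The CVs use the sample (n - 1) standard
#' deviation by default; `sd_type = "population"` switches convention.
#'
#' All three are invariant under global rescaling of arm lengths.
#'
#' @param karyotype a [mean_karyotype()].
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return percent value (dimensionless x100).
#' @export
cv_cl <- function(karyotype, sd_type = c("sample", "population")) {
  cv_percent(as_karyotype_df(karyotype)$cl, match.arg(sd_type))
}

#' @rdname cv_cl
#' @export
cv_ci <- function(karyotype, sd_type = c("sample", "population")) {
  cv_percent(as_karyotype_df(karyotype)$ci, match.arg(sd_type))
}

#' @rdname cv_cl
#' @export
m_ca <- function(karyotype) {
  k <- as_karyotype_df(karyotype)
  100 * mean((k$q - k$p) / (k$q + k$p))
}

#' Stebbins karyotype symmetry class
#'
#' The quali-quantitative symmetry grid: the letter reflects the ratio of
#' the largest to the smallest chromosome (A < 2:1, B 2:1-4:1, C > 4:1) and
#' the row the proportion of chromosomes with arm ratio > 2:1 (1: 0.00,
#' 2: 0.01-0.50, 3: 0.51-0.99, 4: 1.00).  Printed range endpoints are read
#' as inclusive; the proportion is computed on the mean haploid complement.
#'
#' @param karyotype a [mean_karyotype()].
#' @return class token such as `"3A"`.
#' @seealso [stebbins_token()] for the raw grid lookup.
#' @export
stebbins_class <- function(karyotype) {
  k <- as_karyotype_df(karyotype)
  stebbins_token(max(k$cl) / min(k$cl), mean(k$r > 2))
}

#' @rdname stebbins_class
#' @param size_ratio largest/smallest chromosome length ratio (>= 1).
#' @param prop_gt2 proportion of chromosomes with arm ratio > 2:1, in
#'   `[0, 1]`.
#' @export
stebbins_token <- function(size_ratio, prop_gt2) {
  if (size_ratio < 1 || prop_gt2 < 0 || prop_gt2 > 1)
    stop("size_ratio must be >= 1 and prop_gt2 in [0, 1]")
  letter <- if (size_ratio < 2) "A" else if (size_ratio <= 4) "B" else "C"
  row <- if (prop_gt2 == 0) "1" else if (prop_gt2 <= 0.5) "2"
         else if (prop_gt2 < 1) "3" else "4"
  paste0(row, letter)
}

#' Summarize an accession into one karyotype-table row
#'
#' Builds the mean haploid karyotype and composes the full descriptor row:
#' karyotype formula, THCL, CLR, CV\eqn{_{CL}}, CV\eqn{_{CI}},
#' M\eqn{_{CA}} and the Stebbins class.
#'
#' @inheritParams mean_karyotype
#' @param sd_type CV convention, see [cv_cl()].
#' @return one-row data frame of class `karyotype_summary` with columns
#'   `accession`, `taxon`, `x`, `2n`, `kf`, `thcl`, `clr_min`, `clr_max`,
#'   `cv_cl`, `cv_ci`, `m_ca`, `stebbins`, `n_plates`.
#' @export
summarize_accession <- function(dataset, pairing = c("matched", "sorted"),
                                averaging = c("absolute", "relative"),
                                sd_type = c("sample", "population")) {
  mk <- mean_karyotype(dataset, pairing = match.arg(pairing),
                       averaging = match.arg(averaging))
  sd_type <- match.arg(sd_type)
  range <- clr(mk)
  out <- data.frame(accession = dataset$accession_id, taxon = dataset$taxon,
                    x = dataset$two_n %/% dataset$ploidy, `2n` = dataset$two_n,
                    kf = karyotype_formula(mk)$text, thcl = thcl(mk),
                    clr_min = range[["min"]], clr_max = range[["max"]],
                    cv_cl = cv_cl(mk, sd_type), cv_ci = cv_ci(mk, sd_type),
                    m_ca = m_ca(mk), stebbins = stebbins_class(mk),
                    n_plates = length(dataset$plates),
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("karyotype_summary", "data.frame")
  out
}

#' Summarize a cohort of accessions
#'
#' @param datasets list of [accession_dataset()] objects.
#' @param ... passed to [summarize_accession()].
#' @return data frame with one [summarize_accession()] row per dataset.
#' @export
summarize_cohort <- function(datasets, ...) {
  if (!length(datasets)) stop("no accessions")
  out <- do.call(rbind, lapply(datasets, summarize_accession, ...))
  rownames(out) <- NULL
  out
}

#' Parameter matrix from karyotype summaries
#'
#' @param summaries data frame as produced by [summarize_cohort()].
#' @return a [parameter_matrix()] (x, 2n, THCL, M_CA, CV_CL, CV_CI).
#' @export
summary_parameter_matrix <- function(summaries) {
  m <- cbind(x = summaries$x, `2n` = summaries$`2n`, THCL = summaries$thcl,
             M_CA = summaries$m_ca, CV_CL = summaries$cv_cl,
             CV_CI = summaries$cv_ci)
  rownames(m) <- summaries$accession
  parameter_matrix(m)
}
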