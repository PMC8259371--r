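#' Specification for a synthetic accession
#'
#' Describes the ground truth and noise regime of a simulated accession:
#' a haploid karyotype with a target karyotype formula and THCL, measured
#' over several metaphase plates that differ by a multiplicative
#' condensation factor, with multiplicative measurement noise on each arm.
#' Defaults mirror the structure of real karyomorphometric studies: 8
#' plates per accession (within the usual 4-10 range), 10% between-plate
#' condensation spread, 3% per-arm measurement noise, 17% chromosome
#' length spread.
#'
#' @param accession_id accession label.
#' @param two_n somatic chromosome number (positive even).
#' @param kf target haploid karyotype formula: a string like `"6m + 3sm"`
#'   or a named count vector; counts must sum to `two_n / 2`.
#' @param thcl target total haploid chromosome length, um (> 0).
#' @param length_spread target coefficient of variation of chromosome
#'   lengths, percent.
#' @param n_plates number of metaphase plates.
#' @param condensation_sd SD (log scale) of the per-plate condensation
#'   factor.
#' @param noise_sd SD (log scale) of per-arm measurement noise.
#' @param seed RNG seed; everything downstream is deterministic given it.
#' @return object of class `accession_spec`.
#' @export
accession_spec <- function(accession_id, two_n, kf, thcl, length_spread = 17,
                           n_plates = 8, condensation_sd = 0.1,
                           noise_sd = 0.03, seed = 1) {
  if (is.character(kf)) kf <- parse_kf(kf)[1, ]
  classes <- c("m", "sm", "st", "t")
  counts <- setNames(rep(0L, 4), classes)
  counts[names(kf)] <- as.integer(kf)
  two_n <- as.integer(two_n)
  if (two_n <= 0L || two_n %% 2L != 0L) stop("two_n must be positive and even")
  if (sum(counts) != two_n %/% 2L)
    stop("kf counts sum to ", sum(counts), ", expected n = ", two_n %/% 2L)
  if (thcl <= 0) stop("target thcl must be > 0")
  if (length_spread < 0 || condensation_sd < 0 || noise_sd < 0)
    stop("spread and noise parameters must be >= 0")
  if (n_plates < 1) stop("need at least one plate")
  structure(list(accession_id = accession_id, two_n = two_n, kf = counts,
                 thcl = thcl, length_spread = length_spread,
                 n_plates = as.integer(n_plates),
                 condensation_sd = condensation_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "accession_spec")
}

# Arm-ratio intervals per Levan class, trimmed 0.1 away from the class
# boundaries so noisy re-classification cannot flip a true chromosome.
levan_r_interval <- function(class) {
  switch(class,
         m  = c(1.0, 1.6),
         sm = c(1.8, 2.9),
         st = c(3.1, 6.9),
         t  = c(7.1, 10))
}

# Draws the true haploid karyotype for a spec; assumes the RNG is already
# seeded by the caller.
draw_truth <- function(spec) {
  n <- spec$two_n %/% 2L
  cv <- spec$length_spread / 100
  w <- if (cv == 0 || n == 1L) {
    rep(1 / n, n)
  } else {
    # symmetric Dirichlet via gamma draws; concentration set so the
    # component CV matches the target spread: CV^2 = (n-1)/(alpha*n + 1)
    alpha <- ((n - 1) / cv^2 - 1) / n
    if (alpha <= 0) stop("length_spread too large for n = ", n)
    g <- rgamma(n, shape = alpha)
    g / sum(g)
  }
  cl <- sort(w * spec$thcl, decreasing = TRUE)
  cl <- cl * (spec$thcl / sum(cl))               # sum constraint, exact
  classes <- rep(names(spec$kf), times = spec$kf)
  r <- vapply(classes, function(cls) {
    iv <- levan_r_interval(cls)
    runif(1, iv[1], iv[2])
  }, numeric(1))
  p <- cl / (1 + r)
  out <- chromosome_stats(p, cl - p)
  out <- cbind(position = seq_len(n), out)
  structure(out, class = c("mean_karyotype", "data.frame"),
            accession_id = spec$accession_id, two_n = spec$two_n,
            n_plates = NA_integer_)
}

#' Generate the ground-truth haploid karyotype of a spec
#'
#' Chromosome lengths are drawn from a symmetric Dirichlet scaled to the
#' target THCL (the sum constraint holds exactly) with concentration tuned
#' to the target length spread; each chromosome's arm ratio is drawn
#' uniformly within its assigned Levan class interval, at least 0.1 from
#' the class boundaries, so [classify_levan()] reproduces the target
#' formula exactly.  Deterministic given `spec$seed`.
#'
#' @param spec an [accession_spec()].
#' @return a `mean_karyotype` holding the truth.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "accession_spec"))
  with_seed(spec$seed, draw_truth(spec))
}

#' Generate a synthetic measurement dataset
#'
#' Per plate, a condensation factor s ~ lognormal(0, condensation_sd) is
#' drawn; each true chromosome is emitted twice (the homolog pair) with
#' both arms multiplied by s and by independent lognormal(0, noise_sd)
#' measurement factors, then rows are shuffled within the plate.  The
#' ground truth is attached as `attr(dataset, "truth")`.
#'
#' @param spec an [accession_spec()].
#' @return an [accession_dataset()] with a `truth` attribute.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "accession_spec"))
  with_seed(spec$seed, {
    truth <- draw_truth(spec)
    n <- nrow(truth)
    plates <- lapply(seq_len(spec$n_plates), function(b) {
      s <- rlnorm(1, 0, spec$condensation_sd)
      p <- rep(truth$p, each = 2) * s * rlnorm(2 * n, 0, spec$noise_sd)
      q <- rep(truth$q, each = 2) * s * rlnorm(2 * n, 0, spec$noise_sd)
      d <- data.frame(chromosome = paste0("chr", rep(seq_len(n), each = 2),
                                          c("a", "b")),
                      p = pmin(p, q), q = pmax(p, q),
                      stringsAsFactors = FALSE)
      d <- d[sample.int(nrow(d)), , drop = FALSE]
      rownames(d) <- NULL
      d
    })
    names(plates) <- sprintf("plate%02d", seq_len(spec$n_plates))
    ds <- accession_dataset(spec$accession_id, spec$two_n, plates)
    attr(ds, "truth") <- truth
    ds
  })
}

#' Generate a cohort of synthetic datasets
#'
#' @param specs list of [accession_spec()] objects (possibly empty).
#' @return named list of datasets, one per spec.
#' @export
generate_cohort <- function(specs) {
  out <- lapply(specs, generate_dataset)
  names(out) <- vapply(specs, `[[`, character(1), "accession_id")
  out
}

#' Accession specs styled on the packaged Daucus karyotype table
#'
#' One spec per fixture row, taking 2n, the karyotype formula, THCL and
#' the length spread (CV_CL) from the table, so a synthetic cohort
#' emulates the real study's structure end-to-end.
#'
#' @param n_plates,condensation_sd,noise_sd shared noise regime, see
#'   [accession_spec()].
#' @param seed base seed; row i uses `seed + i`.
#' @return list of [accession_spec()] objects (16 entries).
#' @export
daucus_cohort_specs <- function(n_plates = 8, condensation_sd = 0.1,
                                noise_sd = 0.03, seed = 1) {
  tab <- daucus_karyotypes()
  lapply(seq_len(nrow(tab)), function(i) {
    accession_spec(tab$accession[i], tab$`2n`[i], tab$kf[i], tab$thcl[i],
                   length_spread = tab$cv_cl[i], n_plates = n_plates,
                   condensation_sd = condensation_sd, noise_sd = noise_sd,
                   seed = seed + i)
  })
}

#' Write the sidecar truth table of a synthetic dataset
#'
#' @param truth the `truth` attribute of [generate_dataset()] output.
#' @param path output CSV path.
#' @param seed seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, list(op = "write_truth")), con)
  write.csv(cbind(accession = attr(truth, "accession_id"),
                  as.data.frame(truth)), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
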