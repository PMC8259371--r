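#' Construct an accession dataset of metaphase-plate measurements
#'
#' An `accession_dataset` bundles all measured metaphase plates of one
#' accession.  Each plate is a data frame with columns `chromosome`, `p`
#' (short arm, um) and `q` (long arm, um), canonicalized so that `p <= q`
#' on every row.  Every plate must contain exactly `two_n` chromosomes.
#'
#' @param accession_id accession label.
#' @param two_n somatic chromosome number (positive even integer).
#' @param plates named list of plate data frames (columns `chromosome`,
#'   `p`, `q`).
#' @param taxon optional taxon name.
#' @param ploidy ploidy level; the base number is `x = two_n / ploidy`.
#' @return an object of class `accession_dataset`.
#' @export
accession_dataset <- function(accession_id, two_n, plates,
                              taxon = NA_character_, ploidy = 2L) {
  two_n <- as.integer(two_n)
  ploidy <- as.integer(ploidy)
  if (two_n <= 0L || two_n %% 2L != 0L)
    stop("two_n must be a positive even integer, got ", two_n)
  if (ploidy <= 0L || two_n %% ploidy != 0L)
    stop("base number x = two_n/ploidy must be a positive integer")
  if (is.null(names(plates)) || anyDuplicated(names(plates)))
    stop("plates must be a uniquely named list")
  for (pl in names(plates)) {
    d <- plates[[pl]]
    if (!all(c("chromosome", "p", "q") %in% names(d)))
      stop("plate '", pl, "' lacks chromosome/p/q columns")
    if (any(d$p <= 0) || any(d$q <= 0))
      stop("plate '", pl, "' has nonpositive arm lengths")
    if (any(d$p > d$q))
      stop("plate '", pl, "' is not canonicalized (p > q)")
    if (nrow(d) != two_n)
      stop("plate '", pl, "' has ", nrow(d),
           " chromosomes, expected 2n = ", two_n)
  }
  structure(list(accession_id = accession_id, taxon = taxon,
                 two_n = two_n, ploidy = ploidy, plates = plates),
            class = "accession_dataset")
}

#' @export
print.accession_dataset <- function(x, ...) {
  cat(sprintf("<accession_dataset> %s (2n = %d, x = %d): %d plate(s)\n",
              x$accession_id, x$two_n, x$two_n %/% x$ploidy,
              length(x$plates)))
  invisible(x)
}

#' Read per-chromosome arm measurements
#'
#' Reads a comma-separated measurement table (one row per chromosome per
#' metaphase plate) with columns `accession`, `plate`, `chromosome`,
#' `short_arm_um`, `long_arm_um`.  Arms are canonicalized on ingest so the
#' short arm is always `p` (the file's column order is not trusted).  The
#' somatic number 2n of each accession is either declared via `two_n` or
#' inferred as the modal per-plate chromosome count; plates whose count
#' disagrees are dropped with a warning (or rejected when `strict = TRUE`).
#'
#' Lines starting with `#` (provenance headers) are ignored.
#'
#' @param path CSV file path.
#' @param two_n optional declared 2n: a single value or a named vector by
#'   accession.
#' @param ploidy ploidy level applied to all accessions (default 2).
#' @param strict if TRUE, a plate count mismatch is an error instead of a
#'   warning + exclusion.
#' @return named list of [accession_dataset()] objects.
#' @export
read_measurements <- function(path, two_n = NULL, ploidy = 2L, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  required <- c("accession", "plate", "chromosome", "short_arm_um", "long_arm_um")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) stop("no measurement rows in ", path)
  for (col in c("short_arm_um", "long_arm_um")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", col, " at row(s) ", paste(bad, collapse = ", "))
    raw[[col]] <- v
  }
  bad <- which(raw$short_arm_um <= 0 | raw$long_arm_um <= 0)
  if (length(bad))
    stop("nonpositive arm length at row(s) ", paste(bad, collapse = ", "))
  p <- pmin(raw$short_arm_um, raw$long_arm_um)
  q <- pmax(raw$short_arm_um, raw$long_arm_um)
  rows <- data.frame(accession = as.character(raw$accession),
                     plate = as.character(raw$plate),
                     chromosome = as.character(raw$chromosome),
                     p = p, q = q, stringsAsFactors = FALSE)

  out <- list()
  for (acc in unique(rows$accession)) {
    sub <- rows[rows$accession == acc, , drop = FALSE]
    plates <- split(sub[c("chromosome", "p", "q")], sub$plate)
    plates <- lapply(plates, function(d) { rownames(d) <- NULL; d })
    counts <- vapply(plates, nrow, integer(1))
    tn <- if (is.null(two_n)) {
      tab <- table(counts)
      as.integer(names(tab)[which.max(tab)])       # modal plate count
    } else if (!is.null(names(two_n))) {
      if (!acc %in% names(two_n)) stop("no declared two_n for accession ", acc)
      as.integer(two_n[[acc]])
    } else as.integer(two_n)
    off <- names(plates)[counts != tn]
    if (length(off)) {
      msg <- sprintf("accession %s: plate(s) %s have counts differing from 2n = %d",
                     acc, paste(off, collapse = ", "), tn)
      if (strict) stop(msg)
      warning(msg, "; excluded", call. = FALSE)
      plates <- plates[counts == tn]
    }
    if (!length(plates)) stop("accession ", acc, ": no plates left after count validation")
    out[[acc]] <- accession_dataset(acc, tn, plates, ploidy = ploidy)
  }
  out
}

#' Write measurement datasets to the standard measurement CSV
#'
#' Inverse of [read_measurements()]: one row per chromosome per plate, with
#' a provenance header.
#'
#' @param datasets list of [accession_dataset()] objects (or a single one).
#' @param path output CSV path.
#' @param seed seed recorded in the provenance header.
#' @param digits rounding applied to arm lengths on output (default full
#'   precision).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(datasets, path, seed = NA, digits = NULL) {
  if (inherits(datasets, "accession_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("no datasets to write")
  rows <- do.call(rbind, lapply(datasets, function(ds) {
    do.call(rbind, lapply(names(ds$plates), function(pl) {
      d <- ds$plates[[pl]]
      data.frame(accession = ds$accession_id, plate = pl,
                 chromosome = d$chromosome,
                 short_arm_um = if (is.null(digits)) d$p else round(d$p, digits),
                 long_arm_um = if (is.null(digits)) d$q else round(d$q, digits),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, list(op = "write_measurements")), con)
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an accession-level karyotype parameter table
#'
#' Reads a CSV with (at least) columns `accession`, `2n`, `thcl`, `m_ca`,
#' `cv_cl`, `cv_ci`; `x` is optional and derived as `2n / ploidy` when
#' absent (column `ploidy` optional, default 2).  Returns the fixed-order
#' quantitative matrix used for distance-based comparison, with any extra
#' columns (`kf`, `clr_min`, `clr_max`, `stebbins`, `taxon`, ...) kept in
#' `attr(, "extra")`.
#'
#' @param path CSV file path.
#' @return a `parameter_matrix`: numeric matrix, rows = accessions, columns
#'   `x`, `2n`, `THCL`, `M_CA`, `CV_CL`, `CV_CI` in that order.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no accessions in ", path)
  required <- c("accession", "2n", "thcl", "m_ca", "cv_cl", "cv_ci")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  num_cols <- c("2n", "thcl", "m_ca", "cv_cl", "cv_ci",
                intersect(c("x", "ploidy"), names(raw)))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row(s) ",
           paste(bad, collapse = ", "))
    raw[[col]] <- v
  }
  x <- if ("x" %in% names(raw)) raw$x else {
    ploidy <- if ("ploidy" %in% names(raw)) raw$ploidy else 2
    raw$`2n` / ploidy
  }
  m <- cbind(x = x, `2n` = raw$`2n`, THCL = raw$thcl, M_CA = raw$m_ca,
             CV_CL = raw$cv_cl, CV_CI = raw$cv_ci)
  rownames(m) <- raw$accession
  extra <- raw[setdiff(names(raw), c(required, "x", "ploidy"))]
  parameter_matrix(m, extra = extra)
}

#' Construct a parameter matrix
#'
#' The six quantitative karyotype parameters used for cytotaxonomic
#' comparison, in fixed column order: base number `x`, somatic number `2n`,
#' total haploid chromosome length `THCL`, mean centromeric asymmetry
#' `M_CA`, and the coefficients of variation `CV_CL` and `CV_CI`.
#'
#' @param m numeric matrix or data frame with the six columns (any order;
#'   reordered), rownames = accession ids.
#' @param extra optional data frame of non-quantitative companion columns.
#' @return a `parameter_matrix`.
#' @export
parameter_matrix <- function(m, extra = NULL) {
  cols <- c("x", "2n", "THCL", "M_CA", "CV_CL", "CV_CI")
  m <- as.matrix(as.data.frame(m, check.names = FALSE)[cols])
  if (anyNA(m)) stop("parameter matrix has missing values")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("parameter matrix needs unique accession rownames")
  structure(m, extra = extra, class = c("parameter_matrix", class(m)))
}

#' The packaged Daucus karyotype table
#'
#' The karyotype features of the 16 karyotyped accessions (15 *Daucus*
#' accessions plus the outgroup *Orlaya daucoides*): 2n, haploid karyotype
#' formula, THCL, chromosome length range, CV\eqn{_{CL}}, CV\eqn{_{CI}},
#' M\eqn{_{CA}} and the Stebbins symmetry class.
#'
#' @return `daucus_karyotypes()` returns the full fixture data frame;
#'   `daucus_parameter_matrix()` the corresponding 16 x 6
#'   [parameter_matrix()].
#' @export
daucus_karyotypes <- function() {
  path <- system.file("extdata", "daucus_karyotypes.csv", package = "karyomorph",
                      mustWork = TRUE)
  read.csv(path, comment.char = "#", check.names = FALSE,
           stringsAsFactors = FALSE)
}

#' @rdname daucus_karyotypes
#' @export
daucus_parameter_matrix <- function() {
  read_parameter_table(system.file("extdata", "daucus_karyotypes.csv",
                                   package = "karyomorph", mustWork = TRUE))
}

#' Write karyotype summaries as a parameter table
#'
#' Writes summaries (rows of [summarize_accession()] output) in the schema
#' read back by [read_parameter_table()].  Numeric values are rounded to
#' `digits` decimal places on output (full precision is kept in memory);
#' the write/read round trip is lossless at that precision.
#'
#' @param summaries data frame of karyotype summaries (see
#'   [summarize_cohort()]), or a single summary row.
#' @param path output CSV path.
#' @param digits decimal places on output (default 2).
#' @param seed seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path, digits = 2, seed = NA) {
  summaries <- as.data.frame(summaries, check.names = FALSE)
  if (nrow(summaries) == 0L) stop("no summaries to write")
  num <- vapply(summaries, is.numeric, logical(1))
  summaries[num] <- lapply(summaries[num], round, digits = digits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, list(op = "write_summary_table")), con)
  write.csv(summaries, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse and render haploid karyotype formulae
#'
#' A karyotype formula (KF) tallies the haploid complement by Levan class,
#' e.g. `"6m + 3sm"`.  `parse_kf()` converts formula strings to class
#' counts; `format_kf()` renders counts back to text, listing classes in
#' the order m, sm, st, t and omitting zero counts.
#'
#' @param x character vector of formula strings.
#' @return `parse_kf()`: integer matrix with one row per formula and
#'   columns `m`, `sm`, `st`, `t`.
#' @examples
#' parse_kf("2m + 8sm")
#' format_kf(c(m = 6, sm = 3))
#' @export
parse_kf <- function(x) {
  classes <- c("m", "sm", "st", "t")
  out <- matrix(0L, nrow = length(x), ncol = 4,
                dimnames = list(x, classes))
  for (i in seq_along(x)) {
    terms <- strsplit(x[[i]], "\\+")[[1]]
    for (term in terms) {
      term <- gsub("\\s", "", term)
      if (!grepl("^[0-9]+(m|sm|st|t)$", term))
        stop("malformed karyotype formula term: '", term, "'")
      cls <- gsub("^[0-9]+", "", term)
      out[i, cls] <- out[i, cls] + as.integer(gsub("[a-z]+$", "", term))
    }
  }
  out
}

#' @rdname parse_kf
#' @param counts named numeric vector of class counts (names among m, sm,
#'   st, t).
#' @export
format_kf <- function(counts) {
  classes <- c("m", "sm", "st", "t")
  full <- setNames(rep(0L, 4), classes)
  full[names(counts)] <- as.integer(counts)
  keep <- full > 0
  if (!any(keep)) stop("empty karyotype formula")
  paste(paste0(full[keep], classes[keep]), collapse = " + ")
}
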