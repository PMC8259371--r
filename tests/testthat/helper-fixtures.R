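# In-code fixtures shared across test files.

# A plate data frame from haploid arm vectors: each chromosome duplicated
# (exact homologs), optionally jittered multiplicatively.
make_plate <- function(p, q, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- rep(p, each = 2)
  qq <- rep(q, each = 2)
  if (jitter > 0) {
    pp <- pp * exp(rnorm(length(pp), 0, jitter))
    qq <- qq * exp(rnorm(length(qq), 0, jitter))
  }
  data.frame(chromosome = paste0("c", seq_along(pp)),
             p = pmin(pp, qq), q = pmax(pp, qq), stringsAsFactors = FALSE)
}

make_dataset <- function(p, q, n_plates = 1, scales = rep(1, n_plates),
                         id = "acc1") {
  plates <- lapply(seq_len(n_plates), function(i) {
    pl <- make_plate(p * scales[i], q * scales[i])
    pl
  })
  names(plates) <- paste0("pl", seq_len(n_plates))
  accession_dataset(id, 2L * length(p), plates)
}

# Writes a measurement CSV from long-format vectors; returns the path.
write_measurement_file <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

measurement_rows <- function(dataset) {
  do.call(rbind, lapply(names(dataset$plates), function(pl) {
    d <- dataset$plates[[pl]]
    data.frame(accession = dataset$accession_id, plate = pl,
               chromosome = d$chromosome, short_arm_um = d$p,
               long_arm_um = d$q, stringsAsFactors = FALSE)
  }))
}
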