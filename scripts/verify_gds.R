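#!/usr/bin/env Rscript
# Dataset-statistic verification against the four GEO GDS accessions.
#
# Requires the SOFT files (downloaded separately, e.g. from
# https://ftp.ncbi.nlm.nih.gov/geo/datasets/) in a directory passed as the
# first argument; files may be gzipped.  For each accession it parses the
# dataset table, counts genes with at least one missing value, and
# compares with the published counts (the per-accession "missing rate"
# percentages published alongside them are not internally consistent with
# these counts, so the gene counts are the verification surface).
#
#   Rscript scripts/verify_gds.R /path/to/soft-files
suppressPackageStartupMessages(library(spectralimpute))

expected <- data.frame(
  accession  = c("GDS1761", "GDS5232", "GDS2735", "GDS1210"),
  n_genes    = c(9706L, 32878L, 22575L, 7129L),
  n_samples  = c(64L, 50L, 46L, 30L),
  incomplete = c(857L, 16059L, 1731L, 7L),
  complete   = c(8849L, 16819L, 20844L, 7122L)
)

dir <- commandArgs(trailingOnly = TRUE)[1]
if (is.na(dir)) stop("usage: Rscript scripts/verify_gds.R <soft-dir>")

ok_all <- TRUE
for (r in seq_len(nrow(expected))) {
  acc <- expected$accession[r]
  hits <- list.files(dir, pattern = paste0("^", acc, "\\.soft(\\.gz)?$"),
                     full.names = TRUE)
  if (length(hits) == 0) {
    cat(sprintf("%s: file not found, skipped\n", acc))
    next
  }
  em <- read_gds_soft(hits[1])
  s <- split_complete_incomplete(em)
  got <- c(nrow(em$values), ncol(em$values),
           length(s$incomplete), length(s$complete))
  want <- unlist(expected[r, 2:5])
  status <- if (all(got == want)) "OK" else "MISMATCH"
  if (status != "OK") ok_all <- FALSE
  cat(sprintf("%s: %d x %d, incomplete %d, complete %d  [%s; expected %s]\n",
              acc, got[1], got[2], got[3], got[4], status,
              paste(want, collapse = "/")))
}
quit(status = if (ok_all) 0 else 1)
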