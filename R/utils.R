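`%||%` <- function(a, b) if (is.null(a)) b else a

# write a data.frame as TSV with full double precision (lossless round-trip)
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# site key used to join tables across stages
siteKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

DNA_BASES <- c("A", "C", "G", "T")

complementBase <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}
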