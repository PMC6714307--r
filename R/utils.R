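# Internal helpers: seeded evaluation, sub-seed derivation, reproducible TSV.

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific sub-seed from the master seed; stays in 32-bit range.
sub_seed <- function(seed, stage) {
  (abs(as.numeric(seed)) + 7919 * as.numeric(stage)) %% 2147483647
}

# Fixed 6-significant-digit numeric formatting so TSV outputs diff cleanly.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

# Write a data.frame as TSV with LF endings and fixed float formatting.
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !all(df2[[j]] == round(df2[[j]]), na.rm = TRUE))
      df2[[j]] <- format_num(df2[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df2, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
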