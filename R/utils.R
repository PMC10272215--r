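# Internal helpers shared across modules.

#' @useDynLib semwalk, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a new 31-bit seed from a base seed and a stream label, so that
# independent stages of a run consume independent streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((abs(seed) * 2654435.0 + h * 97.0 + 1) %% 2147483629)
}

# TSV writer with a commented header line, the on-disk convention for all
# package artifacts.
write_tsv_commented <- function(df, path, header_fields, extra_comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (cm in extra_comments) writeLines(paste0("# ", cm), con)
  writeLines(paste0("# ", paste(header_fields, collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_commented <- function(path, col_names, colClasses = NA) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    df <- as.data.frame(matrix(character(0), ncol = length(col_names)),
                        stringsAsFactors = FALSE)
    names(df) <- col_names
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = colClasses, fill = FALSE)
  if (ncol(df) < length(col_names)) {
    stop(sprintf("expected at least %d tab-separated columns in '%s', found %d",
                 length(col_names), path, ncol(df)))
  }
  names(df)[seq_along(col_names)] <- col_names
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
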