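#' Read and write JSON-lines files
#'
#' One JSON object per line; data.frame rows map to objects. Timestamps are
#' written as "%Y-%m-%d %H:%M:%S" strings (UTC).
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `read_jsonl` returns a data.frame; `write_jsonl` returns `path`
#'   invisibly.
#' @export
write_jsonl <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (inherits(df2[[j]], "POSIXct")) {
      df2[[j]] <- format(df2[[j]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    } else if (inherits(df2[[j]], "Date")) {
      df2[[j]] <- format(df2[[j]])
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(df2))) {
    writeLines(jsonlite::toJSON(as.list(df2[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
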