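`%||%` <- function(a, b) if (is.null(a)) b else a

## run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## file readers: delimiter from extension, comma for .csv, tab otherwise
delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.table(path, header = TRUE, sep = sep %||% delim_for(path),
             stringsAsFactors = FALSE, check.names = FALSE,
             comment.char = "", quote = "\"")
}

write_delim_table <- function(df, path, sep = NULL) {
  write.table(df, path, sep = sep %||% delim_for(path),
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

stop_ <- function(...) stop(..., call. = FALSE)
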