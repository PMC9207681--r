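# Table artifacts: CSV tables with a '#'-prefixed provenance header
# (command, seed, config hash, package version).  Bodies are written with
# full-precision numerics so artifacts round-trip losslessly and identical
# (config, seed) runs reproduce byte-identical files.

#' Create a table artifact
#' @param df data frame payload.
#' @param command label of the producing command.
#' @param seed RNG seed used (or NA).
#' @param config the `memfield_config` in force (or NULL).
#' @return object of class `table_artifact`.
#' @export
table_artifact <- function(df, command = "memfield", seed = NA, config = NULL) {
  structure(list(
    data = as.data.frame(df),
    provenance = list(
      command = command,
      seed = seed,
      config_hash = if (is.null(config)) "none" else config_hash(config),
      version = as.character(utils::packageVersion("memfield"))
    )
  ), class = "table_artifact")
}

#' Write a table artifact as provenance-stamped CSV
#' @param x a [table_artifact()] (or plain data frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_artifact <- function(x, path) {
  if (!inherits(x, "table_artifact")) x <- table_artifact(x)
  df <- x$data
  fmt <- function(col) {
    if (is.double(col)) sprintf("%.17g", col)
    else as.character(col)
  }
  types <- vapply(df, function(c) class(c)[1], character(1))
  hdr <- c(
    sprintf("# command: %s", x$provenance$command),
    sprintf("# seed: %s", x$provenance$seed),
    sprintf("# config_hash: %s", x$provenance$config_hash),
    sprintf("# version: %s", x$provenance$version),
    sprintf("# coltypes: %s", paste(types, collapse = ","))
  )
  body <- do.call(cbind, lapply(df, fmt))
  lines <- c(paste(names(df), collapse = ","),
             apply(matrix(body, nrow = nrow(df)), 1, paste, collapse = ","))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a provenance-stamped CSV back into a table artifact
#' @param path file written by [write_table_artifact()].
#' @return a [table_artifact()].
#' @export
read_table_artifact <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  meta <- list()
  for (l in hdr) {
    k <- sub("^# ([^:]+):.*$", "\\1", l)
    v <- trimws(sub("^# [^:]+:", "", l))
    meta[[k]] <- v
  }
  df <- read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!is.null(meta$coltypes)) {
    types <- strsplit(meta$coltypes, ",")[[1]]
    for (i in seq_along(df)) {
      df[[i]] <- switch(types[i],
                        numeric = as.numeric(df[[i]]),
                        integer = as.integer(df[[i]]),
                        logical = as.logical(df[[i]]),
                        df[[i]])
    }
  }
  out <- table_artifact(df, command = meta$command %||% "unknown",
                        seed = meta$seed %||% NA)
  out$provenance$config_hash <- meta$config_hash %||% "none"
  out$provenance$version <- meta$version %||% "unknown"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
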