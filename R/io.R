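# Delimited-text I/O: trait matrices (id column + one column per trait),
# long-format observed datasets, flat key=value run configs. Parsers
# report the offending line number on malformed input.

#' Read a trait matrix from delimited text
#'
#' Expected layout: a header line `accession<sep>trait1<sep>...`, then one
#' line per accession with a unique id followed by numeric values.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a [trait_matrix()].
#' @export
read_trait_matrix <- function(path, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("file ", path, " has fewer than 2 data rows")
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1L]]
  p <- length(header) - 1L
  if (p < 1L) stop("header must contain an id column plus at least 1 trait")
  n <- length(cells) - 1L
  vals <- matrix(NA_real_, n, p)
  ids <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != p + 1L) {
      stop("line ", i + 1L, ": expected ", p + 1L, " fields, found ",
           length(row))
    }
    ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("line ", i + 1L, ": non-numeric value '", row[bad + 1L],
           "' in column ", header[bad + 1L])
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate accession id '", dup, "' (line ",
         which(ids == dup)[2L] + 1L, ")")
  }
  trait_matrix(vals, accession_ids = ids, trait_names = header[-1L])
}

#' @rdname read_trait_matrix
#' @param matrix a [trait_matrix()] to write.
#' @export
write_trait_matrix <- function(matrix, path, sep = "\t") {
  df <- data.frame(accession = accessions(matrix),
                   unclass(matrix), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a long-format observed dataset
#'
#' Columns: environment, replication, row, column, accession, trait,
#' value. Each (environment, replication, row, column) cell may hold at
#' most one accession.
#'
#' @param path file path.
#' @param sep field separator.
#' @return an `observed_dataset`.
#' @export
read_observed <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("environment", "replication", "row", "column", "accession",
              "trait", "value")
  if (!all(needed %in% names(df))) {
    stop("observed file must have columns: ", paste(needed, collapse = ", "))
  }
  one_trait <- df[df$trait == df$trait[1L], ]
  cellkey <- paste(one_trait$environment, one_trait$replication,
                   one_trait$row, one_trait$column)
  if (anyDuplicated(cellkey)) {
    stop("field cell occupied twice: ", cellkey[duplicated(cellkey)][1L])
  }
  structure(list(records = df[needed],
                 layout_dim = c(rows = max(df$row), columns = max(df$column)),
                 donors = NULL),
            class = "observed_dataset")
}

#' @rdname read_observed
#' @param observed an `observed_dataset` to write.
#' @export
write_observed <- function(observed, path, sep = "\t") {
  rec <- observed$records
  cols <- c("environment", "replication", "row", "column", "accession",
            "trait", "value")
  utils::write.table(rec[cols], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a flat key=value run configuration
#'
#' Numeric-looking scalars are converted; comma-separated values become
#' vectors; everything else stays character. Round-trips losslessly for
#' configurations written by [write_run_config()].
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("config line ", i, " is not key=value: ",
                              lines[i])
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_run_config
#' @param config named list of scalars / vectors.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
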