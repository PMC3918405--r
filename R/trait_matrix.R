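# The central data container: a numeric accessions x traits matrix of
# genotypic values, with unique accession ids as rownames and trait names
# as colnames. Represented as a plain matrix (class "trait_matrix") so all
# of base R's matrix machinery applies.

#' Construct a trait matrix
#'
#' A trait matrix holds genotypic (or adjusted) values for a germplasm
#' collection: one row per accession, one column per quantitative trait.
#'
#' @param values numeric matrix (or object coercible to one), accessions in
#'   rows, traits in columns.
#' @param accession_ids optional character vector of unique accession ids;
#'   defaults to existing rownames or `ACC001...`.
#' @param trait_names optional character vector of unique trait names;
#'   defaults to existing colnames or `trait01...`.
#' @return a numeric matrix of class `trait_matrix`.
#' @examples
#' m <- trait_matrix(matrix(rnorm(12), 4, 3))
#' accessions(m)
#' @export
trait_matrix <- function(values, accession_ids = NULL, trait_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("a trait matrix needs at least 2 accessions")
  if (ncol(values) < 1L) stop("a trait matrix needs at least 1 trait")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("trait matrix values must be finite and non-missing")
  }
  ids <- accession_ids %||% rownames(values) %||%
    sprintf("ACC%03d", seq_len(nrow(values)))
  trs <- trait_names %||% colnames(values) %||%
    sprintf("trait%02d", seq_len(ncol(values)))
  if (anyDuplicated(ids)) stop("accession ids must be unique")
  if (anyDuplicated(trs)) stop("trait names must be unique")
  if (length(ids) != nrow(values)) stop("accession_ids length != nrow")
  if (length(trs) != ncol(values)) stop("trait_names length != ncol")
  dimnames(values) <- list(as.character(ids), as.character(trs))
  class(values) <- c("trait_matrix", "matrix", "array")
  values
}

#' @rdname trait_matrix
#' @param x a `trait_matrix`.
#' @export
accessions <- function(x) rownames(x)

#' @rdname trait_matrix
#' @export
traits <- function(x) colnames(x)

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d accessions x %d traits\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 4L))
  if (nrow(x) > 4L) cat("... (", nrow(x) - 4L, " more accessions)\n", sep = "")
  invisible(x)
}

#' @export
`[.trait_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && nrow(out) >= 2L) {
    class(out) <- c("trait_matrix", "matrix", "array")
  }
  out
}

# Internal: validate a subset of accession ids against a trait matrix.
check_core_ids <- function(matrix, core_ids) {
  core_ids <- as.character(core_ids)
  missing <- setdiff(core_ids, accessions(matrix))
  if (length(missing)) {
    stop("core ids not in the collection: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (anyDuplicated(core_ids)) stop("core ids contain duplicates")
  if (length(core_ids) < 2L) stop("a core needs at least 2 accessions")
  core_ids
}
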