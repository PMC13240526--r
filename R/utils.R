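#' Evaluate code with a temporary RNG state
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so generators are pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Canonicalize gene symbols for cross-species comparison
#'
#' Symbols are compared case-insensitively after whitespace stripping
#' (mouse symbols are capitalized differently, e.g. Ccn1 vs CCN1); display
#' case is preserved elsewhere.
#'
#' @param x character vector of gene symbols.
#' @return canonical (uppercase, trimmed) symbols.
#' @export
norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited gene-set format: term, description, then member
#' genes, one set per line.
#'
#' @param path path to a .gmt file.
#' @return named list of character vectors; names are term labels, the
#'   \code{"description"} attribute on each element holds the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    attr(genes, "description") <- f[2]
    genes
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    paste(c(names(sets)[i], desc, as.character(sets[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
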