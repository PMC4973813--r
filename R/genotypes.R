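CALL_LEVELS <- c("AA", "AB", "BB", "NC")

#' Construct a genotype matrix
#'
#' Lines x markers matrix of biallelic KASP calls, each in
#' `{AA, AB, BB, NC}` (NC = no call).
#'
#' @param calls character matrix with line ids as rownames and marker
#'   ids as colnames.
#' @return object of class `genotype_matrix` (the validated matrix).
#' @export
genotype_matrix <- function(calls) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    abort("calls must have line rownames and marker colnames")
  bad <- !calls %in% CALL_LEVELS
  if (any(bad))
    abort("invalid call '%s' (allowed: %s)", calls[bad][1L],
          paste(CALL_LEVELS, collapse = ", "))
  structure(calls, class = c("genotype_matrix", "matrix"))
}

#' Read a genotype CSV (first column = line id, header = marker ids)
#' @param path CSV file path.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  genotype_matrix(m)
}

#' Write a genotype CSV
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @export
write_genotypes <- function(gm, path) {
  df <- data.frame(line = rownames(gm), unclass(gm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %.1f%% no-calls\n",
              nrow(x), ncol(x), 100 * mean(x == "NC")))
  invisible(x)
}
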