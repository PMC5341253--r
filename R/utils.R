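#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Write a table as TSV with '#'-prefixed header lines
#'
#' All tabular outputs use this format: optional comment lines
#' starting with '#', then a header row, then tab-separated values.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param comments character vector of comment lines (written with a
#'   leading `"# "`).
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_output()]
#'
#' @param path file path; lines starting with '#' are skipped.
#' @return data.frame.
#' @export
read_tsv_input <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

pl_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
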