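#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate binomial coef complete.cases glm pchisq plogis
#'   pnorm qlogis qnorm rbeta rnorm runif setNames vcov
#' @importFrom utils read.delim write.table
NULL

## Run code with a temporarily seeded RNG, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Round half away from zero (round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Format a p-value for report tables
#'
#' Three decimals down to 0.001; scientific notation with two significant
#' digits below that. `NA` renders as "NA".
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
#' @examples
#' format_pval(c(0.263, 0.0004, NA))
format_pval <- function(p) {
  out <- ifelse(is.na(p), "NA",
    ifelse(p >= 0.001, formatC(p, digits = 3, format = "f"),
      formatC(p, digits = 1, format = "e")))
  as.character(out)
}

#' Format minor/total allele counts as "n/N"
#'
#' @param n minor-allele counts.
#' @param N total chromosome counts.
#' @return character vector like "16/265".
#' @export
format_nN <- function(n, N) paste0(n, "/", N)

## Deterministic TSV writer used by the pipeline (no quoting, "." for NA).
write_tsv <- function(df, path) {
  df[] <- lapply(df, function(x) {
    if (is.numeric(x)) x <- as.character(x)
    x[is.na(x)] <- "."
    x
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}

stop_ctx <- function(...) stop(sprintf(...), call. = FALSE)
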