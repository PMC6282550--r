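#' Write a result table as CSV with an embedded scenario header
#'
#' Output files are self-describing: the fully resolved scenario (rates,
#' elapsed time, richness, and any extra metadata) is embedded as `#`
#' comment lines ahead of the column header.
#'
#' @param x A data frame (e.g. from [trajectory_summary()],
#'   [observed_rate_curve()], [crown_timing_table()]).
#' @param path Output file path.
#' @param meta Named list of metadata written as header comments; defaults
#'   to the `"scenario"` attribute of `x`, if any.
#' @return `path`, invisibly.
#' @export
write_bd_csv <- function(x, path, meta = NULL) {
  stopifnot(is.data.frame(x))
  if (is.null(meta)) meta <- .meta_of(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a result as JSON with a metadata header
#'
#' JSON mirror of [write_bd_csv()]: the payload is written under `data`,
#' the resolved scenario and package version under `meta`. Requires the
#' `jsonlite` package.
#'
#' @inheritParams write_bd_csv
#' @return `path`, invisibly.
#' @export
write_bd_json <- function(x, path, meta = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required for JSON output")
  if (is.null(meta)) meta <- .meta_of(x)
  obj <- list(meta = meta, data = if (is.data.frame(x)) as.data.frame(x) else x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

.meta_of <- function(x) {
  scn <- attr(x, "scenario")
  prm <- if (!is.null(scn)) scn$params else attr(x, "params")
  meta <- list(package = "pushpast",
               version = as.character(utils::packageVersion("pushpast")))
  if (!is.null(prm)) meta <- c(meta, list(lambda = prm$lambda, mu = prm$mu))
  if (!is.null(scn)) meta <- c(meta, list(T_myr = scn$T, nT = scn$nT))
  meta
}
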