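# Classed error conditions so callers and tests can distinguish user errors
# (bad configuration, degenerate data) from internal failures.

fpic_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fpicce_error"), call = call))
}

stop_config <- function(msg) fpic_error(msg, "fpicce_config_error")
stop_domain <- function(msg) fpic_error(msg, "fpicce_domain_error")
stop_identification <- function(msg) fpic_error(msg, "fpicce_identification_error")
stop_sample <- function(msg) fpic_error(msg, "fpicce_sample_error")
stop_calibration <- function(msg) fpic_error(msg, "fpicce_calibration_error")
stop_state <- function(msg) fpic_error(msg, "fpicce_state_error")
stop_consistency <- function(msg) fpic_error(msg, "fpicce_consistency_error")
stop_dependency <- function(msg) fpic_error(msg, "fpicce_dependency_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}

#' Write a delimited table with a provenance header
#'
#' All pipeline artifacts are tab-separated text files whose first lines are
#' `#`-prefixed comments recording the package version, the random seed of the
#' run and a hash of the generating configuration, so that any output file can
#' be traced back to the run that produced it.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param seed integer seed recorded in the header (may be `NA`).
#' @param config_hash character hash recorded in the header (may be `NA`).
#' @return `path`, invisibly.
#' @seealso [read_table_headered()]
#' @export
write_table_headered <- function(x, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("fpicce"))
  writeLines(sprintf("# fpicce %s", version), con)
  writeLines(sprintf("# seed: %s", seed), con)
  writeLines(sprintf("# config_hash: %s", config_hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a delimited table written by [write_table_headered()]
#'
#' `#`-prefixed header lines are skipped.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_table_headered <- function(path) {
  if (!file.exists(path)) {
    stop_dependency(sprintf("input file '%s' does not exist", path))
  }
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

# Stable hash of an R object via its serialized form (used only for
# provenance headers, not for security).
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

# Path to a configuration file shipped with the package.
fpic_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fpicce")
  if (!nzchar(path)) stop_dependency(sprintf("shipped data file '%s' not found", file))
  path
}
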