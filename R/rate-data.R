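#' Read and write initial-rate datasets
#'
#' Initial-rate tables are plain CSV with columns `S_uM` and `rate_mU_mg`,
#' plus optional `I_uM` (inhibitor), `effector_uM` and `replicate`.
#'
#' @param path CSV path.
#' @param data a data frame with at least `S_uM` and `rate_mU_mg`.
#' @return `read_rate_data()` a validated tibble; `write_rate_data()` the
#'   path, invisibly.
#' @export
read_rate_data <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  missing_cols <- setdiff(c("S_uM", "rate_mU_mg"), names(d))
  if (length(missing_cols)) {
    stop("rate dataset is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(d$S_uM <= 0)) stop("substrate concentrations must be > 0", call. = FALSE)
  d
}

#' @rdname read_rate_data
#' @export
write_rate_data <- function(data, path) {
  stopifnot(all(c("S_uM", "rate_mU_mg") %in% names(data)))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
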