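#' Multi-analyte reaction time courses
#'
#' A time course is a tibble with one row per sampling time and columns
#' `time_min` (strictly increasing, starting at 0), `substrate_uM`
#' (nonincreasing within tolerance), `adpr_uM` (free ADP-ribosyl-type
#' product), `cyclic_uM` (cyclic product), zero or more base-exchange
#' product columns named `x_<base>_uM` (e.g. `x_AcPyrAD_uM`), and `base_uM`
#' (released pyridine base). Product series start at 0. Assay metadata —
#' protein concentration (ug/mL), starting substrate `S0` (uM) and any free
#' base supplied at t = 0 (uM, named) — travels as attributes and, on disk,
#' as '#'-prefixed header lines of the CSV.
#'
#' @param data a data frame with the columns above.
#' @param protein_conc_ug_ml protein concentration in the assay (ug/mL).
#' @param S0 starting substrate concentration (uM); defaults to the first
#'   substrate value.
#' @param free_base_supplied named numeric vector of free base
#'   concentrations supplied at t = 0 (uM), or NULL.
#' @param tol slack allowed on the "substrate nonincreasing" check, as a
#'   fraction of S0 (measurement noise tolerance).
#' @return a tibble of class `time_course`.
#' @export
time_course <- function(data, protein_conc_ug_ml = NA_real_, S0 = NULL,
                        free_base_supplied = NULL, tol = 0.02) {
  data <- tibble::as_tibble(data)
  req <- c("time_min", "substrate_uM", "adpr_uM", "cyclic_uM", "base_uM")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("time course is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  t <- data$time_min
  if (t[1] != 0 || any(diff(t) <= 0)) {
    stop("`time_min` must be strictly increasing and start at 0", call. = FALSE)
  }
  if (is.null(S0)) S0 <- data$substrate_uM[1]
  conc_cols <- setdiff(names(data), "time_min")
  for (cc in conc_cols) check_nonneg_vec(data[[cc]], cc)
  for (pc in product_columns(data)) {
    if (data[[pc]][1] != 0) {
      stop(sprintf("product series `%s` must start at 0", pc), call. = FALSE)
    }
  }
  if (any(diff(data$substrate_uM) > tol * S0)) {
    stop("substrate series must be nonincreasing (within tolerance)", call. = FALSE)
  }
  structure(data,
            class = c("time_course", class(data)),
            protein_conc_ug_ml = protein_conc_ug_ml,
            S0 = S0,
            free_base_supplied = free_base_supplied)
}

product_columns <- function(tc) {
  nm <- names(tc)
  c("adpr_uM", "cyclic_uM", nm[grepl("^x_.+_uM$", nm)])
}

exchange_columns <- function(tc) names(tc)[grepl("^x_.+_uM$", names(tc))]

#' @rdname time_course
#' @param path CSV path.
#' @param tc a `time_course` object.
#' @export
write_time_course <- function(tc, path) {
  meta <- list(protein_conc_ug_ml = attr(tc, "protein_conc_ug_ml"),
               S0 = attr(tc, "S0"))
  fb <- attr(tc, "free_base_supplied")
  if (!is.null(fb)) meta$free_base_supplied <- as.list(fb)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  utils::write.csv(as.data.frame(tc), con, row.names = FALSE)
  invisible(path)
}

#' @rdname time_course
#' @export
read_time_course <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  if (any(hdr)) {
    meta <- jsonlite::fromJSON(sub("^#\\s*", "", lines[hdr][1]))
  }
  data <- utils::read.csv(text = lines[!hdr], check.names = FALSE)
  fb <- NULL
  if (!is.null(meta$free_base_supplied)) fb <- unlist(meta$free_base_supplied)
  time_course(data,
              protein_conc_ug_ml = meta$protein_conc_ug_ml %||% NA_real_,
              S0 = meta$S0,
              free_base_supplied = fb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
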