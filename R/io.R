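#' Read a worker-cohort CSV
#'
#' Strict CSV dialect: comma separated, period decimal point, UTF-8, header
#' mandatory; lines starting with `#` (provenance headers written by this
#' package) are skipped. Known numeric columns are validated cell by cell;
#' a malformed cell is reported with its row and column, and locale-style
#' comma decimals are rejected with an explicit message. Unknown columns are
#' preserved untouched.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector renaming file columns to
#'   canonical names, e.g. `c(t_dry = "Ta")`.
#' @param required Canonical columns that must be present after mapping
#'   (default the six index variables; use `character(0)` to disable).
#' @return Data frame.
#' @export
read_cohort <- function(path, column_map = NULL, required = ehsra_vars) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop(sprintf("mapped column '%s' (for '%s') absent", src, canon),
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- intersect(
    c(ehsra_vars, "tympanic", "heart_rate", "age", "time"), names(raw))
  for (col in numeric_cols) {
    x <- trimws(raw[[col]])
    comma <- grepl("^-?[0-9]+,[0-9]+$", x)
    if (any(comma)) {
      stop(sprintf(
        "column '%s' row %d: comma decimal '%s' — this reader requires period decimals",
        col, which(comma)[1L], x[which(comma)[1L]]), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(x))
    bad <- is.na(val) & !(x %in% c("", "NA"))
    if (any(bad)) {
      stop(sprintf("column '%s' row %d: malformed numeric cell '%s'",
                   col, which(bad)[1L], x[which(bad)[1L]]), call. = FALSE)
    }
    raw[[col]] <- val
  }
  raw
}

#' Write a CSV with a provenance header
#'
#' Prepends `#`-prefixed comment lines recording the package version, an
#' index-spec content hash and the seed, so every artifact states how it was
#' produced. [read_cohort()] skips these lines.
#'
#' @param data Data frame.
#' @param path Output path.
#' @param spec Optional [ehsra_spec()] whose content hash goes in the header.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, spec = NULL, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("ehsra"))
  writeLines(sprintf("# ehsra %s", ver), con)
  if (!is.null(spec)) {
    writeLines(sprintf("# spec_hash %s", spec_hash(spec)), con)
  }
  if (!is.null(seed)) writeLines(sprintf("# seed %s", seed), con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}

# cheap content hash (djb2 over the serialized spec); avoids a digest dep
spec_hash <- function(spec) {
  bytes <- utf8ToInt(paste(
    format(c(spec$coefficients, spec$norm_min, spec$norm_range,
             spec$scale_factor, spec$skin_temp_threshold,
             spec$bands$lower), digits = 15),
    collapse = "|"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Score a cohort table
#'
#' Convenience wrapper: compute the index score and risk band for every row
#' and append them as `ehsra_score` / `risk_level` columns.
#'
#' @param data Cohort data frame (six index variables required).
#' @param spec An [ehsra_spec()].
#' @param warn_out_of_range,check Passed to [ehsra_score()].
#' @return `data` with two appended columns.
#' @export
score_cohort <- function(data, spec = default_ehsra_spec(),
                         warn_out_of_range = TRUE, check = TRUE) {
  s <- ehsra_score(data, spec, warn_out_of_range = warn_out_of_range,
                   check = check)
  data$ehsra_score <- s
  data$risk_level <- as.character(classify_risk(s, spec))
  data
}

#' Read a square labeled correlation/covariance CSV
#'
#' First column holds row labels; remaining columns must match them.
#'
#' @param path CSV path.
#' @return Named square numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         fileEncoding = "UTF-8")
  labels <- as.character(raw[[1L]])
  M <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric entries in matrix CSV", call. = FALSE)
  if (ncol(M) != length(labels) || !identical(colnames(M), labels)) {
    stop("matrix CSV must be square with matching row/column labels",
         call. = FALSE)
  }
  dimnames(M) <- list(labels, labels)
  M
}

#' Write a matrix as a labeled CSV
#' @param M Named square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  df <- data.frame(variable = rownames(M), as.data.frame(M),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
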