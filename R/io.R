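#' Read and write trajectory files
#'
#' Trajectories travel as plain CSV with header `t_s,x_mm,y_mm` and rows of
#' finite decimals; lines starting with `#` carry `key: value` metadata
#' (arena preset, treatment, colony, seed, ...).  Time must be strictly
#' increasing.  `read_trajectory(write_trajectory(x))` returns the same
#' samples.
#'
#' @param path File path.
#' @returns `read_trajectory()`: a tibble `t_s`, `x_mm`, `y_mm` with any
#'   metadata in `attr(, "metadata")`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(tibble::tibble(t_s = 0:2, x_mm = c(0, 1, 2),
#'                                 y_mm = c(0, 0, 1)), f)
#' read_trajectory(f)
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  meta_lines <- sub("^\\s*#\\s*", "", lines[is_comment])
  metadata <- list()
  for (ml in meta_lines) {
    kv <- regmatches(ml, regexec("^([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(kv) == 3) metadata[[trimws(kv[2])]] <- trimws(kv[3])
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0) abort("empty trajectory: no data lines")
  header <- lines[body_idx[1]]
  if (gsub("\\s", "", header) != "t_s,x_mm,y_mm") {
    abort("expected header `t_s,x_mm,y_mm`")
  }
  data_idx <- body_idx[-1]
  if (length(data_idx) == 0) abort("empty trajectory: header but no samples")
  fields <- strsplit(lines[data_idx], ",", fixed = TRUE)
  bad_n <- which(lengths(fields) != 3)
  if (length(bad_n)) {
    abort(sprintf("malformed row at line %d: expected 3 fields",
                  data_idx[bad_n[1]]))
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 3, byrow = TRUE)
  )
  bad_num <- which(rowSums(!is.finite(mat)) > 0)
  if (length(bad_num)) {
    abort(sprintf("non-numeric or non-finite value at line %d",
                  data_idx[bad_num[1]]))
  }
  non_mono <- which(diff(mat[, 1]) <= 0)
  if (length(non_mono)) {
    abort(sprintf("time not strictly increasing at line %d",
                  data_idx[non_mono[1] + 1]))
  }
  out <- tibble(t_s = mat[, 1], x_mm = mat[, 2], y_mm = mat[, 3])
  attr(out, "metadata") <- metadata
  attr(out, "source") <- "file"
  out
}

#' @rdname read_trajectory
#' @param traj A data frame with `t_s`, `x_mm`, `y_mm`.
#' @param metadata Optional named list written as `# key: value` comment
#'   lines.
#' @export
write_trajectory <- function(traj, path, metadata = NULL) {
  stopifnot(all(c("t_s", "x_mm", "y_mm") %in% names(traj)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    for (k in names(metadata)) {
      writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
    }
  }
  writeLines("t_s,x_mm,y_mm", con)
  writeLines(
    paste(
      format(traj$t_s, trim = TRUE, scientific = FALSE, digits = 15),
      format(traj$x_mm, trim = TRUE, scientific = FALSE, digits = 15),
      format(traj$y_mm, trim = TRUE, scientific = FALSE, digits = 15),
      sep = ","
    ),
    con
  )
  invisible(path)
}
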