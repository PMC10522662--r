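# --- plain-text and image I/O for cross-language reuse

#' Read and write numeric matrices as plain tab-separated tables
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @return `read_matrix_table` returns a numeric matrix;
#'   `write_matrix_table` returns `path` invisibly.
#' @export
write_matrix_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_table
#' @export
read_matrix_table <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Read and write k-space sampling masks as index lists
#'
#' One 1-based linear index per line, with the grid side on a header
#' line (`# side <n>`).
#'
#' @param mask Integer index vector.
#' @param side Grid side length.
#' @param path File path.
#' @return `read_mask` returns a list with `mask` and `side`.
#' @export
write_mask <- function(mask, side, path) {
  writeLines(c(sprintf("# side %d", side), as.character(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  side <- as.integer(sub("# side ", "", lines[1]))
  list(mask = as.integer(lines[-1]), side = side)
}

#' Read and write a machine configuration as a flat key/value file
#'
#' The file is flat YAML whose keys map one-to-one onto the arguments of
#' [cim_config()].
#'
#' @param cfg A `cim_config`.
#' @param path File path.
#' @return `read_cim_config` returns a validated `cim_config`.
#' @export
write_cim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cim_config"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_cim_config
#' @export
read_cim_config <- function(path) {
  do.call(cim_config, yaml::read_yaml(path))
}

#' Write a grayscale image as PNG
#'
#' Values are clipped to \[0, 1\].
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @return `read_image_png` returns a numeric matrix in \[0, 1\]
#'   (grayscale; colour input is averaged).
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Dump the per-step trajectory of a CIM run as a tab-separated table
#'
#' Requires `run_cim(..., trajectory = "full")`. Columns: step, pulse
#' index, normalised amplitude, error gain (CAC models).
#'
#' @param run A `cim_run` with a full amplitude trace.
#' @param path File path.
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "cim_run"), !is.null(run$amplitude_trace))
  tr <- run$amplitude_trace
  df <- data.frame(
    step = rep(seq_len(nrow(tr)), ncol(tr)),
    pulse = rep(seq_len(ncol(tr)), each = nrow(tr)),
    amplitude = as.vector(tr)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
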