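#' Write / read a numeric matrix as CSV
#'
#' Plain unquoted CSV with a header row of column names; values round-trip to
#' full stored precision.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = paste0("c", seq_len(ncol(m))))
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  unname(as.matrix(utils::read.csv(path, header = TRUE)))
}

#' Read a layer stack from a structured config file
#'
#' YAML file with a top-level `layers:` list, bottom level first. Inner
#' levels give `Sigma` and `Theta` (inline nested lists of rows, or a path to
#' a CSV relative to the config file) and optionally `h`; the last entry
#' gives `Sigma` and `v_p`.
#'
#' @param path config file path.
#' @return a [hier_stack].
#' @export
read_stack_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers))
    stop("stack config must contain a 'layers' list", call. = FALSE)
  base <- dirname(path)
  get_mat <- function(x) {
    if (is.character(x)) read_matrix_csv(file.path(base, x))
    else do.call(rbind, x)
  }
  layers <- lapply(cfg$layers, function(l) {
    stopifnot(!is.null(l$Sigma))
    layer_params(Sigma = get_mat(l$Sigma),
                 Theta = if (is.null(l$Theta)) NULL else get_mat(l$Theta),
                 h = if (is.null(l$h)) "identity" else l$h,
                 v_p = if (is.null(l$v_p)) NULL else as.numeric(l$v_p))
  })
  hier_stack(layers)
}
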