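#' Write a shape distribution to a JSON file
#'
#' Serializes the mean SRVF samples, the variances, and the flattened
#' principal directions so sampling, sweeps, and density evaluation can be
#' re-run from the file (e.g. through the command-line interface).
#'
#' @param dist a `shape_distribution` from [shape_covariance()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(dist, path) {
  stopifnot(inherits(dist, "shape_distribution"))
  obj <- list(grid_size = dist$grid_size,
              n_residues = dist$n_residues,
              n = dist$n,
              k = dist$k,
              sigma = dist$sigma,
              mean = as.numeric(dist$mean$values),
              U = lapply(dist$U, as.numeric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an SRVF as a plain-text table
#'
#' Tab-separated columns `t`, `qx`, `qy`, `qz`; mainly useful for
#' debugging and for inspecting SRVFs outside R.
#'
#' @param q an [srvf()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_srvf_table <- function(q, path) {
  stopifnot(inherits(q, "srvf"))
  m <- nrow(q$values)
  df <- data.frame(t = seq(0, 1, length.out = m),
                   qx = q$values[, 1], qy = q$values[, 2], qz = q$values[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SRVF from a plain-text table written by [write_srvf_table()]
#'
#' @param path input file path.
#' @param label label for the resulting object.
#' @return an [srvf()].
#' @export
read_srvf_table <- function(path, label = "srvf") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  srvf(as.matrix(df[, c("qx", "qy", "qz")]), label)
}

#' Read a shape distribution from a JSON file
#'
#' @param path file written by [write_shape_model()].
#' @return a `shape_distribution`.
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.integer(obj$grid_size)
  U <- if (obj$k > 0) {
    if (is.matrix(obj$U)) lapply(seq_len(nrow(obj$U)), function(j) matrix(obj$U[j, ], m, 3))
    else lapply(obj$U, function(u) matrix(u, m, 3))
  } else list()
  structure(list(mean = srvf(matrix(obj$mean, m, 3), "model_mean"),
                 U = U,
                 sigma = as.numeric(obj$sigma),
                 k = as.integer(obj$k),
                 n = as.integer(obj$n),
                 grid_size = m,
                 n_residues = as.integer(obj$n_residues),
                 trace_K = NA_real_),
            class = "shape_distribution")
}
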