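#' BOLD series container
#'
#' A minimal container for one subject's 4D BOLD signal: a numeric
#' `(x, y, z, t)` array plus the repetition time and voxel geometry.
#'
#' @param data Numeric 4D array `(x, y, z, t)` with finite values.
#' @param tr Repetition time in seconds (> 0).
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @return A `bold_series` object (list with `data`, `tr`, `voxel_size`,
#'   and a `provenance` character vector recording applied processing).
#' @examples
#' bs <- bold_series(array(rnorm(2 * 2 * 2 * 5), c(2, 2, 2, 5)), tr = 2)
#' n_volumes(bs)
#' @export
bold_series <- function(data, tr = 2, voxel_size = c(2, 2, 2)) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4D (x, y, z, t) array.")
  }
  if (!all(is.finite(data))) abort("`data` must be finite everywhere.")
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  structure(list(data = data, tr = tr, voxel_size = as.numeric(voxel_size),
                 provenance = character(0)),
            class = "bold_series")
}

#' @rdname bold_series
#' @param x A `bold_series`.
#' @export
n_volumes <- function(x) {
  stopifnot(inherits(x, "bold_series"))
  dim(x$data)[4]
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %s grid, %d volumes, TR = %gs, voxels %s mm\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr,
              paste(signif(x$voxel_size, 3), collapse = "x")))
  if (length(x$provenance)) {
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

# rebuild a series after an operation, appending a provenance step
update_series <- function(x, data, step) {
  x$data <- data
  x$provenance <- c(x$provenance, step)
  x
}
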