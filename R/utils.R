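#' Path to a packaged configuration file
#'
#' @param file File name under `inst/extdata`.
#' @return Absolute path.
#' @keywords internal
hfmos_extdata <- function(file) {
  path <- system.file("extdata", file, package = "hfmos", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may be on a different path
    path <- system.file("inst", "extdata", file, package = "hfmos", mustWork = TRUE)
  }
  path
}

# clip a numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# draw from a truncated normal by rejection (bounds well inside the bulk,
# so rejection is cheap)
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

assert_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
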