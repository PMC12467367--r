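#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor dnorm optimize pnorm pt qnorm rnorm runif sd
#'   t.test uniroot var simulate residuals predict logLik
#' @importFrom utils read.csv write.csv
#' @importFrom graphics plot axis points rect abline
#' @importFrom grDevices png dev.off hcl.colors
NULL

# round half away from zero (commercial rounding); base round() rounds half
# to even, which does not reproduce printed clinical tables
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_rk <- function(msg, class, ...) {
  stop(structure(class = c(class, "raschkey_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_rk(sprintf("'%s' must be a single finite number", name),
            "raschkey_validation_error")
  invisible(x)
}

# canonical JSON writer: fixed key order is the caller's responsibility,
# full precision, scalars unboxed
write_json_canonical <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = 2)
  writeLines(json, path)
  invisible(path)
}

read_json_file <- function(path) {
  if (!file.exists(path))
    stop_rk(sprintf("file not found: %s", path), "raschkey_io_error")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
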