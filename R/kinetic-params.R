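#' Kinetic parameters of the growth/death model
#'
#' Bundles the five kinetic parameters of the coupled growth/resource model
#' (plus an optional Hill exponent for the resource term) and validates them.
#'
#' @param lambda_max Maximal per-capita growth rate, 1/h.
#' @param d Per-capita death rate, 1/h. Death is active in all phases.
#' @param B Resource units consumed per unit of population growth
#'   (normalized resource units per fold-change unit). `1/B` is the resource
#'   utilization efficiency: the attainable fold change per unit resource.
#' @param K_r Resource level of half-effect for growth limitation,
#'   normalized resource units.
#' @param K_qs Population density (fold-change units) at which the
#'   density-dependent growth factor is half-maximal. `Inf` disables the
#'   density term, giving the resource-only model.
#' @param H Hill exponent for the resource factor, dimensionless. `H = 1`
#'   gives the plain Monod form.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params(lambda_max = 1.1, d = 0.05, B = 5e-4, K_r = 0.3, K_qs = 400)
#' @export
kinetic_params <- function(lambda_max, d, B, K_r, K_qs = Inf, H = 1) {
  stopifnot(
    is.numeric(lambda_max), length(lambda_max) == 1L,
    is.numeric(d), length(d) == 1L,
    is.numeric(B), length(B) == 1L,
    is.numeric(K_r), length(K_r) == 1L,
    is.numeric(K_qs), length(K_qs) == 1L,
    is.numeric(H), length(H) == 1L
  )
  if (lambda_max <= 0 || d <= 0 || B <= 0 || K_r < 0)
    stop("lambda_max, d, B must be > 0 and K_r >= 0", call. = FALSE)
  if (K_qs <= 0) stop("K_qs must be > 0 (Inf disables the density term)", call. = FALSE)
  if (H < 0) stop("H must be >= 0", call. = FALSE)
  if (lambda_max <= d)
    warning("lambda_max <= d: the strain never grows", call. = FALSE)
  structure(
    list(lambda_max = lambda_max, d = d, B = B, K_r = K_r, K_qs = K_qs, H = H),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters:\n")
  cat(sprintf("  lambda_max = %.4g 1/h,  d = %.4g 1/h\n", x$lambda_max, x$d))
  cat(sprintf("  B = %.4g (1/B = %.4g),  K_r = %.4g,  K_qs = %.4g,  H = %.3g\n",
              x$B, 1 / x$B, x$K_r, x$K_qs, x$H))
  invisible(x)
}

#' Serialize / deserialize kinetic parameters as JSON
#'
#' @param p A [kinetic_params()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `params_to_json()` returns the JSON string invisibly (and writes the
#'   file when `path` is given); `params_from_json()` returns a
#'   [kinetic_params()] object.
#' @export
params_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "kinetic_params"))
  x <- unclass(p)
  # Inf is not representable in strict JSON; use the string "Inf"
  if (!is.finite(x$K_qs)) x$K_qs <- "Inf"
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname params_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
params_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  x <- jsonlite::fromJSON(json)
  if (identical(x$K_qs, "Inf")) x$K_qs <- Inf
  kinetic_params(x$lambda_max, x$d, x$B, x$K_r, x$K_qs, if (is.null(x$H)) 1 else x$H)
}

# coerce a named list / vector to kinetic_params
as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  x <- as.list(x)
  kinetic_params(x$lambda_max, x$d, x$B, x$K_r,
                 if (is.null(x$K_qs)) Inf else x$K_qs,
                 if (is.null(x$H)) 1 else x$H)
}
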