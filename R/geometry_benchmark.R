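## Method-accuracy benchmark over bond-length tables.
##
## The accuracy metric A% for a method is the mean absolute deviation of its
## computed bond lengths from experiment, expressed as a percentage of the mean
## experimental bond length:
##
##   A% = 100 * mean(|computed_i - experimental_i|) / mean(experimental_i)
##
## A% is zero iff the method reproduces experiment exactly, and is invariant
## to a common rescaling of both columns (e.g. a unit change).

#' Mean absolute deviation percent between computed and experimental lengths
#'
#' @param computed numeric vector of computed bond lengths (angstrom).
#' @param experimental numeric vector of reference (X-ray) lengths (angstrom),
#'   same length as `computed`.
#' @return A% as a single number (dimensionless percent).
#' @export
#' @examples
#' mad_percent(c(1.01, 2.02), c(1, 2))   # uniform +1% scaling -> exactly 1
mad_percent <- function(computed, experimental) {
  if (length(computed) != length(experimental))
    stop_dimension("computed and experimental must have equal length")
  if (length(computed) == 0)
    stop_domain("at least one bond length is required")
  if (any(!is.finite(computed)) || any(!is.finite(experimental)))
    stop_validation("bond lengths must be finite")
  if (any(computed <= 0) || any(experimental <= 0))
    stop_domain("bond lengths must be > 0")
  100 * mean(abs(computed - experimental)) / mean(experimental)
}

#' Rank computational methods by bond-length accuracy
#'
#' Computes [mad_percent()] for every method column of a bond-length table and
#' returns the methods sorted ascending by A% (most accurate first). The sort
#' is stable: ties keep the original column order.
#'
#' @param table a bond-length table as returned by
#'   `load_table(..., "bondlengths")`: a `parameter` column, an `experimental`
#'   column, and one column per method.
#' @return a `data.frame` with columns `method`, `a_percent`, `n_parameters`,
#'   ordered ascending by `a_percent`.
#' @export
#' @examples
#' rank_methods(bundled_fixture("bondlengths_tu"))
rank_methods <- function(table) {
  methods <- setdiff(names(table), c("parameter", "experimental"))
  if (length(methods) < 1)
    stop_schema("table must contain at least one method column")
  a <- vapply(methods, function(m) {
    mad_percent(table[[m]], table$experimental)
  }, numeric(1))
  out <- data.frame(method = methods,
                    a_percent = unname(a),
                    n_parameters = nrow(table),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_percent), , drop = FALSE]   # stable radix/shell sort
  rownames(out) <- NULL
  out
}
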