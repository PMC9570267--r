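## Multilinear-regression QSAR with four IC50 response transforms.
##
## The regression itself is ordinary least squares with an intercept, solved
## through the SVD pseudoinverse so that rank-deficient or underdetermined
## designs (p + 1 >= n, the situation of a 4-compound panel fitted with 5-8
## descriptors) return the well-defined minimum-norm solution and are loudly
## flagged instead of silently interpolating.

.transform_kinds <- c("identity", "reciprocal", "log10_reciprocal", "log10")

#' Transform IC50 activities to a modelling response
#'
#' The four response conventions: the activity itself, its reciprocal, the
#' base-10 log of the reciprocal (pIC50 when IC50 is molar) and the base-10
#' log. `log10_reciprocal` is exactly the pointwise negation of `log10`.
#'
#' @param ic50 activities in uM; must be strictly positive for all kinds
#'   except `identity`.
#' @param kind one of `"identity"`, `"reciprocal"`, `"log10_reciprocal"`,
#'   `"log10"`.
#' @return transformed response vector.
#' @export
#' @examples
#' transform_response(22.80, "log10_reciprocal")   # -log10(22.80)
transform_response <- function(ic50, kind = .transform_kinds) {
  kind <- match.arg(kind)
  if (any(!is.finite(ic50))) stop_validation("ic50 must be finite")
  if (kind != "identity" && any(ic50 <= 0))
    stop_domain(sprintf("ic50 must be > 0 for transform '%s'", kind))
  switch(kind,
    identity = ic50,
    reciprocal = 1 / ic50,
    log10_reciprocal = -log10(ic50),
    log10 = log10(ic50)
  )
}

#' Invert a response transform back to the IC50 scale
#'
#' @param y response values.
#' @param kind transform kind; see [transform_response()].
#' @return activities in uM; strictly positive for the non-identity kinds.
#' @export
inverse_transform_response <- function(y, kind = .transform_kinds) {
  kind <- match.arg(kind)
  switch(kind,
    identity = y,
    reciprocal = 1 / y,
    log10_reciprocal = 10^(-y),
    log10 = 10^y
  )
}

## canonical descriptor sources and aliases
.descriptor_aliases <- c(e_homo = "e_homo_ev", e_lumo = "e_lumo_ev")

#' QSAR model specification
#'
#' @param descriptors ordered, unique character vector of descriptor names.
#'   Quantum names (`e_homo_ev`, `e_lumo_ev`, `i_pot`, `e_aff`, `e_gap`,
#'   `chi`, `eta`, `s_soft`, `v_pot`, `omega`, `n_nuc`; `e_homo`/`e_lumo`
#'   accepted as aliases, resolved in eV) come from the descriptor table;
#'   the rest (`logp`, `mw_da`, `hbd`, `hba`, `n_rotb`, `psa_A2`, `logd74`,
#'   `pol_A3`, `mr_A3`, `vol_A3`, `sag_A2`, `he_kcalmol`) from the
#'   physicochemical table.
#' @param response transform kind; see [transform_response()].
#' @param phase phase of the quantum descriptors, `"gas"` (default) or
#'   `"aqueous"`.
#' @return a `model_spec` object.
#' @export
model_spec <- function(descriptors, response = "identity", phase = "gas") {
  descriptors <- as.character(descriptors)
  if (length(descriptors) == 0 || any(descriptors == ""))
    stop_validation("descriptor names must be non-empty")
  aliased <- ifelse(descriptors %in% names(.descriptor_aliases),
                    .descriptor_aliases[descriptors], descriptors)
  if (anyDuplicated(aliased))
    stop_validation("descriptor names must be unique")
  structure(list(descriptors = unname(aliased),
                 response = match.arg(response, .transform_kinds),
                 phase = match.arg(phase, c("gas", "aqueous"))),
            class = "model_spec")
}

#' Build a QSAR design matrix and response vector
#'
#' Joins the per-compound quantum descriptor table and physicochemical table
#' on compound, restricts to compounds with an observed IC50 in the requested
#' cell line (missing activities are dropped and reported), applies the
#' response transform, and assembles descriptor columns in specification
#' order.
#'
#' @param quantum a descriptor table from [descriptor_table()] (already at the
#'   specification's phase), or a raw quantum table, in which case
#'   [descriptor_table()] is applied with `spec$phase`.
#' @param physchem a physicochemical table; may carry the optional SAR columns.
#' @param spec a [model_spec()].
#' @param activities an activity table.
#' @param cell_line cell-line name, e.g. `"HCT"`.
#' @param i_tce nucleophilicity reference used when `quantum` is raw.
#' @return a list with `x` (matrix, rows = compounds, columns = descriptors),
#'   `y` (transformed response), `compounds`, `dropped` (compounds with
#'   missing activity), and `spec`.
#' @export
build_design_matrix <- function(quantum, physchem, spec, activities,
                                cell_line, i_tce = 4.21) {
  if (!inherits(spec, "model_spec")) stop_config("spec must be a model_spec")
  if (!is.null(quantum) && !"chi" %in% names(quantum)) {
    quantum <- descriptor_table(quantum, spec$phase, i_tce)
  }
  act <- activities[activities$cell_line == cell_line, , drop = FALSE]
  if (nrow(act) == 0)
    stop_lookup(sprintf("no activity records for cell line '%s'", cell_line))
  dropped <- act$compound[is.na(act$ic50_uM)]
  act <- act[!is.na(act$ic50_uM), , drop = FALSE]
  if (nrow(act) == 0)
    stop_domain(sprintf("no observed activities for cell line '%s'", cell_line))

  sources <- Filter(Negate(is.null), list(quantum = quantum, physchem = physchem))
  resolve_col <- function(name) {
    for (src in sources) {
      if (name %in% setdiff(names(src), c("compound", "phase"))) {
        v <- src[[name]][match(act$compound, src$compound)]
        bad <- which(is.na(v))
        if (length(bad) > 0)
          stop_validation(sprintf(
            "descriptor '%s' unavailable for compound %s",
            name, act$compound[bad[1]]))
        return(v)
      }
    }
    valid <- unlist(lapply(sources, function(s)
      setdiff(names(s), c("compound", "phase"))))
    stop_schema(sprintf("unknown descriptor '%s'; valid names: %s",
                        name, paste(sort(unique(valid)), collapse = ", ")))
  }
  x <- vapply(spec$descriptors, resolve_col, numeric(nrow(act)))
  x <- matrix(x, nrow = nrow(act),
              dimnames = list(act$compound, spec$descriptors))
  list(x = x,
       y = transform_response(act$ic50_uM, spec$response),
       compounds = act$compound,
       dropped = dropped,
       spec = spec)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. A constant observed vector has no explainable
#' variance and returns 0 by convention. The value is clamped to `[0, 1]` for
#' reporting; the raw (possibly negative) value is kept in the `"raw"`
#' attribute.
#'
#' @param observed observed response values (length >= 2).
#' @param predicted predicted values, same length.
#' @return clamped r-squared with attribute `raw`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop_dimension("observed and predicted must have equal length")
  if (length(observed) < 2) stop_domain("at least two observations required")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    return(structure(0, raw = 0))
  }
  raw <- 1 - sum((observed - predicted)^2) / ss_tot
  structure(min(max(raw, 0), 1), raw = raw)
}

#' Fit a multilinear regression with intercept
#'
#' Least squares via the SVD pseudoinverse. For full-rank, overdetermined
#' designs this equals the ordinary OLS solution (with standard errors and
#' adjusted r-squared). When the augmented design is rank-deficient or
#' `p + 1 >= n`, the minimum-norm solution is returned, `underdetermined` is
#' set, standard errors and adjusted r-squared are `NA`, and the reported
#' r-squared (computed on the fitted values) will be 1 up to numerical
#' tolerance whenever the fit interpolates exactly.
#'
#' @param x design matrix (n x p, named columns; no intercept column).
#' @param y response vector of length n (>= 1).
#' @return a `deskqsar_fit` object: list with `intercept`, `coefficients`
#'   (named), `r2`, `r2_raw`, `adj_r2`, `n`, `p`, `rank`, `underdetermined`,
#'   `fitted`, `residuals`, `se` (named, `NA` when underdetermined),
#'   `df_residual`.
#' @export
#' @examples
#' x <- cbind(a = rnorm(20), b = rnorm(20))
#' f <- fit_ols(x, 1 + 2 * x[, 1] - 3 * x[, 2])
#' f$coefficients
fit_ols <- function(x, y) {
  x <- as.matrix(x)
  n <- length(y)
  if (n == 0) stop_domain("n must be >= 1")
  if (nrow(x) != n) stop_dimension("nrow(x) must equal length(y)")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_validation("design matrix and response must be finite")
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  x1 <- cbind(`(Intercept)` = 1, x)
  sv <- svd(x1)
  tol <- max(dim(x1)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  rank <- sum(pos)
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  beta <- drop(beta)
  names(beta) <- colnames(x1)
  fitted <- drop(x1 %*% beta)
  resid <- y - fitted
  underdetermined <- (p + 1L >= n) || (rank < p + 1L)
  df_residual <- n - p - 1L

  r2 <- if (n >= 2) r_squared(y, fitted) else structure(NA_real_, raw = NA_real_)
  adj_r2 <- NA_real_
  se <- rep(NA_real_, p + 1)
  names(se) <- colnames(x1)
  if (!underdetermined && df_residual > 0) {
    sigma2 <- sum(resid^2) / df_residual
    ## unscaled covariance = V diag(1/d^2) V'
    vi <- sv$v[, pos, drop = FALSE]
    xtx_inv <- vi %*% (t(vi) / sv$d[pos]^2)
    se <- sqrt(diag(xtx_inv) * sigma2)
    names(se) <- colnames(x1)
    if (!is.na(attr(r2, "raw")))
      adj_r2 <- 1 - (1 - attr(r2, "raw")) * (n - 1) / df_residual
  }
  structure(list(
    intercept = unname(beta[1]),
    coefficients = beta[-1],
    r2 = as.numeric(r2),
    r2_raw = if (is.null(attr(r2, "raw"))) NA_real_ else attr(r2, "raw"),
    adj_r2 = adj_r2,
    n = n, p = p, rank = rank,
    underdetermined = underdetermined,
    fitted = fitted,
    residuals = resid,
    se = se,
    df_residual = df_residual
  ), class = "deskqsar_fit")
}

#' @export
print.deskqsar_fit <- function(x, ...) {
  cat(sprintf("Multilinear regression fit: n = %d, p = %d%s\n", x$n, x$p,
              if (x$underdetermined) " (UNDERDETERMINED, minimum-norm)" else ""))
  cat(sprintf("  r2 = %.4f%s\n", x$r2,
              if (!is.na(x$adj_r2)) sprintf(", adj r2 = %.4f", x$adj_r2) else ""))
  cat(sprintf("  intercept = %.6g\n", x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-12s %.6g\n", nm, x$coefficients[[nm]]))
  invisible(x)
}

#' 95% confidence intervals for fitted coefficients
#'
#' t-based intervals from the OLS standard errors; defined only for
#' well-determined fits with positive residual degrees of freedom.
#'
#' @param fit a `deskqsar_fit`.
#' @param level confidence level.
#' @return matrix with columns `lower`, `upper` (intercept first).
#' @export
coef_confint <- function(fit, level = 0.95) {
  if (!inherits(fit, "deskqsar_fit")) stop_config("fit must be a deskqsar_fit")
  if (fit$underdetermined || fit$df_residual <= 0)
    stop_domain("confidence intervals undefined for underdetermined fits")
  est <- c("(Intercept)" = fit$intercept, fit$coefficients)
  tq <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  cbind(lower = est - tq * fit$se, upper = est + tq * fit$se)
}

#' Forward stepwise descriptor selection
#'
#' Greedily adds the candidate descriptor that maximizes r-squared, stopping
#' when `max_terms` is reached, when the best improvement is below 1e-6, or
#' when adding a term would make the fit underdetermined (`p + 1 >= n`).
#' Ties are broken by candidate order.
#'
#' @param candidates named matrix or data.frame of candidate descriptor
#'   columns.
#' @param response response vector.
#' @param max_terms maximum number of descriptors to select (>= 1).
#' @return a list with `selected` (character vector in selection order),
#'   `fit` (final `deskqsar_fit`, or NULL if nothing was selected) and
#'   `trace` (data.frame of step, descriptor, r2).
#' @export
stepwise_forward <- function(candidates, response, max_terms) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) == 0) stop_domain("candidate set must be non-empty")
  if (!is_count(max_terms) || max_terms < 1)
    stop_domain("max_terms must be >= 1")
  n <- length(response)
  selected <- character()
  best_r2 <- 0
  trace <- data.frame(step = integer(), descriptor = character(),
                      r2 = numeric(), stringsAsFactors = FALSE)
  fit <- NULL
  repeat {
    if (length(selected) >= max_terms) break
    if (length(selected) + 1 + 1 >= n) break   # next fit would be underdetermined
    remaining <- setdiff(names(candidates), selected)
    if (length(remaining) == 0) break
    r2s <- vapply(remaining, function(cand) {
      xm <- as.matrix(candidates[c(selected, cand)])
      as.numeric(fit_ols(xm, response)$r2_raw)
    }, numeric(1))
    best <- which.max(r2s)   # first max wins: tie-break by candidate order
    if (r2s[best] - best_r2 < 1e-6) break
    selected <- c(selected, remaining[best])
    best_r2 <- r2s[best]
    fit <- fit_ols(as.matrix(candidates[selected]), response)
    trace <- rbind(trace, data.frame(step = length(selected),
                                     descriptor = remaining[best],
                                     r2 = best_r2,
                                     stringsAsFactors = FALSE))
  }
  list(selected = selected, fit = fit, trace = trace)
}

#' Evaluate a linear model on descriptor rows
#'
#' Pure evaluation, no fitting: `intercept + sum(coefficient * descriptor)`
#' for each row. Used to evaluate externally reported regression equations on
#' descriptor tables.
#'
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector or list mapping descriptor name
#'   to coefficient.
#' @param rows a data.frame whose columns include every coefficient name.
#' @return numeric vector of predictions, one per row.
#' @export
#' @examples
#' apply_model(1, c(x = 2), data.frame(x = 3))   # 7
apply_model <- function(intercept, coefficients, rows) {
  coefficients <- unlist(coefficients)
  missing_cols <- setdiff(names(coefficients), names(rows))
  if (length(missing_cols) > 0)
    stop_schema(sprintf("descriptor(s) missing from rows: %s",
                        paste(missing_cols, collapse = ", ")))
  pred <- rep(intercept, nrow(rows))
  for (nm in names(coefficients)) {
    pred <- pred + coefficients[[nm]] * rows[[nm]]
  }
  pred
}

#' Predicted-vs-observed table for a fitted model
#'
#' @param fit a `deskqsar_fit` dimensioned to `x`.
#' @param x design matrix used for the fit (or compatible new data).
#' @param y observed response.
#' @param compounds optional row labels.
#' @return data.frame with `compound`, `observed`, `predicted`, `residual`.
#'   When an intercept was fitted on a well-determined design the residuals
#'   sum to zero (up to numerical tolerance).
#' @export
predicted_vs_observed <- function(fit, x, y, compounds = NULL) {
  if (!inherits(fit, "deskqsar_fit")) stop_config("fit must be a deskqsar_fit")
  x <- as.matrix(x)
  if (nrow(x) == 0) stop_domain("design matrix must have at least one row")
  if (ncol(x) != fit$p || nrow(x) != length(y))
    stop_dimension("fit, design matrix and response dimensions disagree")
  pred <- drop(cbind(1, x) %*% c(fit$intercept, fit$coefficients))
  if (is.null(compounds)) {
    compounds <- if (!is.null(rownames(x))) rownames(x)
                 else paste0("row", seq_len(nrow(x)))
  }
  data.frame(compound = compounds, observed = y, predicted = pred,
             residual = y - pred, stringsAsFactors = FALSE)
}
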