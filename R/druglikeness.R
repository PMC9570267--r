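## Drug-likeness rule engines: Lipinski's rule of five, Veber's oral
## bioavailability criteria, and Golden-Triangle membership in the
## (logD7.4, MW) plane.

#' Lipinski rule-of-five evaluation
#'
#' Criteria (inclusive thresholds): logP <= 5, MW <= 500 Da, H-bond donors
#' <= 5, H-bond acceptors <= 10. The score counts satisfied criteria; a
#' compound passes if it violates at most one criterion.
#'
#' @param log_p octanol/water partition coefficient.
#' @param mw molecular weight in Da (> 0).
#' @param hbd hydrogen-bond donor count (>= 0 integer).
#' @param hba hydrogen-bond acceptor count (>= 0 integer).
#' @return a list with logical flags `logp_ok`, `mw_ok`, `hbd_ok`, `hba_ok`,
#'   the `score` (0-4) and `passed`.
#' @export
#' @examples
#' lipinski(1.39, 359.4, 3, 4)$score      # 4
#' lipinski(1.27, 588.56, 3, 13)$passed   # FALSE (two violations)
lipinski <- function(log_p, mw, hbd, hba) {
  if (!is.finite(mw) || mw <= 0) stop_validation("mw must be > 0")
  if (!is_count(hbd) || !is_count(hba))
    stop_validation("hbd and hba must be non-negative integer counts")
  flags <- c(logp_ok = log_p <= 5, mw_ok = mw <= 500,
             hbd_ok = hbd <= 5, hba_ok = hba <= 10)
  score <- sum(flags)
  c(as.list(flags), list(score = score, passed = (4L - score) <= 1L))
}

#' Veber oral-bioavailability criteria
#'
#' Both thresholds are strict, following the rule's "under" wording:
#' rotatable bonds < 10 and (topological) polar surface area < 140 A^2.
#'
#' @param n_rotb rotatable-bond count (>= 0 integer).
#' @param tpsa (topological) polar surface area in A^2 (>= 0).
#' @return a list with `rotb_ok`, `tpsa_ok`, `score` and `passed`
#'   (both criteria required).
#' @export
#' @examples
#' veber(1, 70.23)$passed     # TRUE
#' veber(5, 160.83)$passed    # FALSE
veber <- function(n_rotb, tpsa) {
  if (!is_count(n_rotb)) stop_validation("n_rotb must be a non-negative integer")
  if (!is.finite(tpsa) || tpsa < 0) stop_validation("tpsa must be >= 0")
  flags <- c(rotb_ok = n_rotb < 10, tpsa_ok = tpsa < 140)
  c(as.list(flags), list(score = sum(flags), passed = all(flags)))
}

#' Golden-Triangle membership policy
#'
#' The Golden Triangle is a region of the (logD7.4, MW) plane inside which
#' compounds tend to combine good permeability with metabolic stability. The
#' published construction has its base on MW = 200 spanning logD -2 to 5 and
#' its apex at (1.5, 450), which is the default here; the vertices are
#' configurable.
#'
#' @param vertices a 3x2 numeric matrix of (logD, MW) vertex pairs.
#' @param boundary_inclusive treat boundary points as inside (default TRUE).
#' @return a `triangle_policy` object.
#' @export
triangle_policy <- function(vertices = default_triangle_vertices(),
                            boundary_inclusive = TRUE) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || !all(dim(vertices) == c(3, 2)))
    stop_config("vertices must be a 3x2 numeric matrix of (logD, MW) pairs")
  cross <- .edge_cross(vertices[1, ], vertices[2, ], vertices[3, ])
  if (abs(cross) < 1e-12)
    stop_config("triangle vertices are collinear")
  structure(list(vertices = unname(vertices),
                 boundary_inclusive = isTRUE(boundary_inclusive)),
            class = "triangle_policy")
}

#' @rdname triangle_policy
#' @export
default_triangle_vertices <- function() {
  matrix(c(-2, 200, 5, 200, 1.5, 450), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("log_d", "mw")))
}

## signed cross product of (b - a) x (p - a)
.edge_cross <- function(a, b, p) {
  (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
}

#' Golden-Triangle classification of one compound
#'
#' Point-in-triangle test by sign consistency of the three edge cross
#' products, so the result does not depend on vertex ordering. Boundary
#' points count as inside when the policy is boundary-inclusive.
#'
#' @param log_d distribution coefficient at pH 7.4.
#' @param mw molecular weight in Da (> 0).
#' @param policy a [triangle_policy()].
#' @return `"inside"` or `"outside"`.
#' @export
#' @examples
#' golden_triangle(2.310, 359.4)    # inside
#' golden_triangle(2.416, 402.47)   # outside
golden_triangle <- function(log_d, mw, policy = triangle_policy()) {
  if (!inherits(policy, "triangle_policy"))
    stop_config("policy must be a triangle_policy object")
  if (!is.finite(mw) || mw <= 0) stop_validation("mw must be > 0")
  v <- policy$vertices
  p <- c(log_d, mw)
  d <- c(.edge_cross(v[1, ], v[2, ], p),
         .edge_cross(v[2, ], v[3, ], p),
         .edge_cross(v[3, ], v[1, ], p))
  tol <- 1e-9 * max(1, abs(d))
  on_boundary <- any(abs(d) <= tol)
  strictly_in <- all(d > tol) || all(d < -tol)
  inside <- strictly_in ||
    (on_boundary && policy$boundary_inclusive &&
       (all(d >= -tol) || all(d <= tol)))
  if (inside) "inside" else "outside"
}

#' Batch drug-likeness screening report
#'
#' Evaluates Lipinski, Veber and Golden-Triangle membership for every row of a
#' physicochemical descriptor table, in input order.
#'
#' @param physchem a physchem table (see [load_table()]).
#' @param policy a [triangle_policy()].
#' @return a `data.frame` with one row per compound: the per-criterion flags,
#'   `lipinski_score`, `lipinski_passed`, `veber_passed` and `triangle`.
#' @export
#' @examples
#' screen_compounds(bundled_fixture("physchem"))
screen_compounds <- function(physchem, policy = triangle_policy()) {
  required <- c("compound", "logp", "mw_da", "hbd", "hba", "n_rotb",
                "psa_A2", "logd74")
  missing_cols <- setdiff(required, names(physchem))
  if (length(missing_cols) > 0)
    stop_schema(sprintf("physchem table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  rows <- lapply(seq_len(nrow(physchem)), function(i) {
    r <- physchem[i, ]
    for (f in required) {
      if (is.na(r[[f]]))
        stop_validation(sprintf("compound %s: missing required field %s",
                                r$compound, f))
    }
    lp <- lipinski(r$logp, r$mw_da, r$hbd, r$hba)
    vb <- veber(r$n_rotb, r$psa_A2)
    data.frame(
      compound = r$compound,
      logp_ok = lp$logp_ok, mw_ok = lp$mw_ok,
      hbd_ok = lp$hbd_ok, hba_ok = lp$hba_ok,
      lipinski_score = lp$score, lipinski_passed = lp$passed,
      rotb_ok = vb$rotb_ok, tpsa_ok = vb$tpsa_ok, veber_passed = vb$passed,
      triangle = golden_triangle(r$logd74, r$mw_da, policy),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) == 0) {
    data.frame(compound = character(), logp_ok = logical(), mw_ok = logical(),
               hbd_ok = logical(), hba_ok = logical(),
               lipinski_score = integer(), lipinski_passed = logical(),
               rotb_ok = logical(), tpsa_ok = logical(),
               veber_passed = logical(), triangle = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}
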