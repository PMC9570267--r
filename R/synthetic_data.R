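## Seeded synthetic compound panels with the statistical structure the QSAR
## analysis assumes: orbital energies drawn uniformly over the observed
## ranges (so every derived descriptor identity holds by construction),
## physicochemical descriptors drawn uniformly over the observed ranges
## padded by 10% of their span, and activities generated from a known linear
## model on the transformed response scale plus Gaussian noise.

.default_orbital_ranges <- list(e_homo = c(-0.26, -0.19),
                                e_lumo = c(-0.13, -0.09))

#' Default physicochemical simulation ranges
#'
#' Continuous descriptors span the observed four-compound minimum/maximum
#' padded by 10% of the span on each side (logP and MW use the wider
#' conventional screening ranges `[-3, 3]` and `[300, 500]`); count
#' descriptors are sampled as integers over the observed range.
#'
#' @return named list of `c(low, high)` ranges.
#' @export
default_physchem_ranges <- function() {
  pc <- bundled_fixture("physchem")
  sar <- bundled_fixture("sar_properties")
  study <- c("2H", "6H", "7H", "9H")
  pc <- pc[pc$compound %in% study, ]
  sar <- sar[sar$compound %in% study, ]
  pad <- function(v) {
    lo <- min(v); hi <- max(v); s <- (hi - lo) * 0.1
    c(lo - s, hi + s)
  }
  list(
    logp = c(-3, 3),
    mw_da = c(300, 500),
    hbd = range(pc$hbd),
    hba = range(pc$hba),
    n_rotb = range(pc$n_rotb),
    psa_A2 = pad(pc$psa_A2),
    logd74 = pad(pc$logd74),
    pol_A3 = pad(sar$pol_A3),
    mr_A3 = pad(sar$mr_A3),
    vol_A3 = pad(sar$vol_A3),
    sag_A2 = pad(sar$sag_A2),
    he_kcalmol = pad(sar$he_kcalmol)
  )
}

#' Simulation configuration
#'
#' @param n_compounds number of synthetic compounds (>= 1).
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#' @param true_model list with `intercept` and named `coefficients` giving the
#'   generating linear model on the transformed response scale. Names must be
#'   resolvable descriptor columns (quantum or physicochemical).
#' @param response transform kind linking the linear predictor to IC50; the
#'   default `"log10_reciprocal"` (pIC50 convention) guarantees positive IC50
#'   for any noise draw.
#' @param noise_sigma Gaussian noise SD on the transformed response scale.
#' @param censor_fraction fraction of activities set missing
#'   (`0 <= f < 1`); exactly `round(n * f)` cells are censored.
#' @param orbital_ranges list with `e_homo`, `e_lumo` uniform ranges in
#'   hartree; ranges must keep `e_homo < e_lumo`.
#' @param physchem_ranges named list of ranges, see
#'   [default_physchem_ranges()].
#' @param cell_line cell-line label for the activity table.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_compounds = 60,
                              seed = 1L,
                              true_model = list(
                                intercept = -1.2,
                                coefficients = c(logp = 0.35, s_soft = 4.0,
                                                 n_rotb = -0.25)),
                              response = "log10_reciprocal",
                              noise_sigma = 0.1,
                              censor_fraction = 0,
                              orbital_ranges = .default_orbital_ranges,
                              physchem_ranges = default_physchem_ranges(),
                              cell_line = "HCT") {
  if (!is_count(n_compounds) || n_compounds < 1)
    stop_validation("n_compounds must be >= 1")
  if (!is.finite(censor_fraction) || censor_fraction < 0 || censor_fraction >= 1)
    stop_validation("censor_fraction must satisfy 0 <= f < 1")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop_validation("noise_sigma must be >= 0")
  for (rg in c(orbital_ranges, physchem_ranges)) {
    if (length(rg) != 2 || rg[1] > rg[2])
      stop_validation("every range must be c(low, high) with low <= high")
  }
  if (orbital_ranges$e_homo[2] >= orbital_ranges$e_lumo[1])
    stop_validation("orbital ranges must keep e_homo below e_lumo")
  if (is.null(true_model$intercept) || length(true_model$coefficients) == 0 ||
      is.null(names(true_model$coefficients)))
    stop_validation("true_model needs an intercept and named coefficients")
  structure(list(
    n_compounds = as.integer(n_compounds),
    seed = as.integer(seed),
    true_model = true_model,
    response = match.arg(response, .transform_kinds),
    noise_sigma = noise_sigma,
    censor_fraction = censor_fraction,
    orbital_ranges = orbital_ranges,
    physchem_ranges = physchem_ranges,
    cell_line = cell_line
  ), class = "simulation_config")
}

#' Simulate a synthetic compound panel
#'
#' Draws orbital energies and physicochemical descriptors, derives the global
#' reactivity descriptors through [compute_global_descriptors()] (so the
#' descriptor identities S*eta = 1/2, Eg = I - A, V = -chi hold exactly),
#' evaluates the configured true linear model on the transformed response
#' scale, adds Gaussian noise, and back-transforms to IC50.
#'
#' @param config a [simulation_config()].
#' @return list with `quantum`, `physchem`, `activity` (data frames in the
#'   [load_table()] schemas), `descriptors` (joined per-compound descriptor
#'   frame used to generate activities) and `config`.
#' @export
#' @examples
#' sim <- simulate_compounds(simulation_config(n_compounds = 10, seed = 42))
#' head(sim$activity)
simulate_compounds <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_validation("config must be a simulation_config")
  n <- config$n_compounds
  set.seed(config$seed)
  ids <- sprintf("S%03d", seq_len(n))

  e_homo <- stats::runif(n, config$orbital_ranges$e_homo[1],
                         config$orbital_ranges$e_homo[2])
  e_lumo <- stats::runif(n, config$orbital_ranges$e_lumo[1],
                         config$orbital_ranges$e_lumo[2])
  quantum <- data.frame(
    compound = ids, phase = "gas",
    e_total_au = stats::runif(n, -1700, -1480),
    dipole_D = stats::runif(n, 6, 16),
    e_homo_au = e_homo, e_lumo_au = e_lumo,
    stringsAsFactors = FALSE
  )
  attr(quantum, "deskqsar_schema") <- "quantum"

  draw <- function(col) {
    rg <- config$physchem_ranges[[col]]
    if (col %in% c("hbd", "hba", "n_rotb")) {
      vals <- seq.int(rg[1], rg[2])   # avoid sample()'s scalar surprise
      vals[sample.int(length(vals), n, replace = TRUE)]
    } else {
      stats::runif(n, rg[1], rg[2])
    }
  }
  physchem <- data.frame(
    compound = ids,
    logp = draw("logp"), mw_da = draw("mw_da"),
    hbd = draw("hbd"), hba = draw("hba"), n_rotb = draw("n_rotb"),
    psa_A2 = draw("psa_A2"), logd74 = draw("logd74"),
    pol_A3 = draw("pol_A3"), mr_A3 = draw("mr_A3"),
    vol_A3 = draw("vol_A3"), sag_A2 = draw("sag_A2"),
    he_kcalmol = draw("he_kcalmol"),
    stringsAsFactors = FALSE
  )
  attr(physchem, "deskqsar_schema") <- "physchem"

  desc <- descriptor_table(quantum, "gas")
  joined <- merge(desc, physchem, by = "compound", sort = FALSE)
  joined <- joined[match(ids, joined$compound), ]

  coefs <- config$true_model$coefficients
  missing_cols <- setdiff(names(coefs), names(joined))
  if (length(missing_cols) > 0)
    stop_validation(sprintf("true_model names not resolvable: %s",
                            paste(missing_cols, collapse = ", ")))
  linpred <- apply_model(config$true_model$intercept, coefs, joined)
  y <- linpred + stats::rnorm(n, 0, config$noise_sigma)
  ic50 <- inverse_transform_response(y, config$response)
  if (any(!is.finite(ic50) | ic50 <= 0))
    stop_validation(paste(
      "generated IC50 not strictly positive; choose a log-type response",
      "transform or a true model whose range stays positive"))

  n_censor <- round(n * config$censor_fraction)
  if (n_censor > 0) ic50[sample.int(n, n_censor)] <- NA_real_
  activity <- data.frame(compound = ids, cell_line = config$cell_line,
                         ic50_uM = ic50, stringsAsFactors = FALSE)
  attr(activity, "deskqsar_schema") <- "activity"

  list(quantum = quantum, physchem = physchem, activity = activity,
       descriptors = joined, config = config)
}

#' Coefficient-recovery experiment
#'
#' Repeatedly simulates a panel, refits the true descriptor set by OLS, and
#' summarizes per-coefficient bias, RMSE and empirical 95% confidence-interval
#' coverage. Replicate r uses seed `config$seed + r`, so the experiment is
#' reproducible from the base seed alone.
#'
#' @param config a [simulation_config()]; must be well-determined
#'   (`n_compounds` comfortably above the number of coefficients plus one,
#'   also after censoring).
#' @param replicates number of replicates (>= 1).
#' @return list with `summary` (data.frame: term, true, mean_estimate, bias,
#'   rmse, ci_coverage) and `estimates` (replicates x terms matrix).
#' @export
recovery_experiment <- function(config, replicates) {
  if (!inherits(config, "simulation_config"))
    stop_validation("config must be a simulation_config")
  if (!is_count(replicates) || replicates < 1)
    stop_domain("replicates must be >= 1")
  coefs <- config$true_model$coefficients
  p <- length(coefs)
  n_eff <- config$n_compounds -
    round(config$n_compounds * config$censor_fraction)
  if (p + 1 >= n_eff)
    stop_domain(paste(
      "configuration is underdetermined after censoring;",
      "increase n_compounds"))
  true <- c("(Intercept)" = unname(config$true_model$intercept), coefs)
  terms <- names(true)

  est <- matrix(NA_real_, nrow = replicates, ncol = p + 1,
                dimnames = list(NULL, terms))
  covered <- matrix(NA, nrow = replicates, ncol = p + 1,
                    dimnames = list(NULL, terms))
  spec <- model_spec(names(coefs), response = config$response)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_compounds(cfg)
    dm <- build_design_matrix(sim$quantum, sim$physchem, spec,
                              sim$activity, config$cell_line)
    fit <- fit_ols(dm$x, dm$y)
    est[r, ] <- c(fit$intercept, fit$coefficients[names(coefs)])
    ci <- coef_confint(fit)
    covered[r, ] <- true >= ci[terms, "lower"] & true <= ci[terms, "upper"]
  }
  summary <- data.frame(
    term = terms,
    true = unname(true),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(true),
    rmse = sqrt(colMeans(sweep(est, 2, true)^2)),
    ci_coverage = colMeans(covered),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(summary = summary, estimates = est)
}
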