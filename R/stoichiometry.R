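#' Compound registry for molar conversions
#'
#' Molar masses (g/mol) and carbon counts of the species measured across an
#' anaerobic/aerobic cycle. Glycogen, PHB and PHV are accounted per monomer
#' (anhydroglucose C6H10O5; 3-hydroxybutyrate C4H6O2; 3-hydroxyvalerate
#' C5H8O2). Ortho-phosphate is accounted per phosphorus atom.
#'
#' @return A data.frame `compound, molar_mass, carbons, unit`.
#' @export
compound_registry <- function() {
  data.frame(
    compound = c("acetate", "propionate", "glucose-monomer",
                 "phb-monomer", "phv-monomer", "ortho-p"),
    molar_mass = c(60.052, 74.079, 162.141, 86.090, 100.117, 30.974),
    carbons = c(2, 3, 6, 4, 5, NA),
    unit = c(rep("C-mmol/L", 5), "P-mmol/L"),
    stringsAsFactors = FALSE)
}

#' Convert a mass concentration to carbon- (or phosphorus-) mole units
#'
#' `mg/L * carbons / molar_mass` for carbon species; `mg/L / 30.974` for
#' ortho-phosphate. Cycle transformation ratios are molar, raw assays are
#' mass-based; this is the bridge.
#'
#' @param value_mg_l Concentration in mg/L (vectorized).
#' @param compound Registry key, see [compound_registry()].
#' @return C-mmol/L (or P-mmol/L for `"ortho-p"`).
#' @export
to_cmol <- function(value_mg_l, compound) {
  reg <- compound_registry()
  i <- match(compound, reg$compound)
  if (is.na(i)) {
    stop("unknown compound '", compound, "'; registry has: ",
         paste(reg$compound, collapse = ", "))
  }
  if (reg$compound[i] == "ortho-p") {
    value_mg_l / reg$molar_mass[i]
  } else {
    value_mg_l * reg$carbons[i] / reg$molar_mass[i]
  }
}

#' Reference anaerobic stoichiometry of a PAO or GAO enrichment
#'
#' Literature transformation ratios for acetate-fed enrichments of pure
#' polyphosphate- or glycogen-accumulating metabolism. These are the two
#' end members of the mixing model: P released, glycogen consumed and PHA
#' formed per C-mol of VFA taken up anaerobically. Defaults are the
#' conventional model values (PAO: P/VFA 0.5, Gly/VFA 0.5, PHA/VFA 1.33,
#' PHB/VFA 1.33, PHV/VFA 0; GAO: 0, 1.12, 1.85, 1.36, 0.46). Note the GAO
#' reference's tabulated PHA/VFA (1.85) is not exactly PHB + PHV (1.82);
#' the tabulated value is kept as metadata for interval checks while cycle
#' generation and fitting use the PHB and PHV components.
#'
#' @param role `"PAO"` or `"GAO"`.
#' @param p_vfa,gly_vfa,pha_vfa,phb_vfa,phv_vfa Ratios (>= 0).
#' @return Object of class `reference_stoichiometry`.
#' @export
reference_stoichiometry <- function(role, p_vfa, gly_vfa, pha_vfa,
                                    phb_vfa, phv_vfa) {
  vals <- c(p_vfa = p_vfa, gly_vfa = gly_vfa, pha_vfa = pha_vfa,
            phb_vfa = phb_vfa, phv_vfa = phv_vfa)
  if (any(vals < 0)) stop("reference ratios must be >= 0")
  structure(c(list(role = role), as.list(vals)),
            class = "reference_stoichiometry")
}

#' @rdname reference_stoichiometry
#' @export
pao_reference <- function() {
  reference_stoichiometry("PAO", 0.5, 0.5, 1.33, 1.33, 0)
}

#' @rdname reference_stoichiometry
#' @export
gao_reference <- function() {
  reference_stoichiometry("GAO", 0, 1.12, 1.85, 1.36, 0.46)
}

#' Specify a synthetic anaerobic/aerobic cycle
#'
#' Fixes the two-population mixing fraction and the reactor conditions of a
#' generated cycle: feed carbon, acetate share of it, phase durations,
#' influent P/C ratio, measurement noise and sampling density. Defaults
#' follow a typical lab-scale enrichment: 2 h anaerobic / 3 h aerobic,
#' 75% acetate / 25% propionate carbon feed, influent P/C 0.15.
#'
#' @param f_pao PAO fraction of the PAO+GAO biomass in \[0, 1\].
#' @param vfa_feed_cmol Influent VFA in C-mmol/L (default 12, roughly a
#'   400 mg COD/L acetate/propionate feed).
#' @param acetate_fraction Fraction of feed carbon as acetate (default 0.75).
#' @param anaerobic_min,aerobic_min Phase durations in minutes
#'   (defaults 120 and 180).
#' @param p_to_c_feed Influent P/C molar ratio (default 0.15).
#' @param noise_sd_rel Relative (multiplicative Gaussian) measurement noise.
#' @param n_timepoints Samples per cycle (default 31).
#' @param pao_ref,gao_ref End-member stoichiometries
#'   ([reference_stoichiometry()]).
#' @param seed Integer seed.
#' @return Object of class `cycle_spec`.
#' @export
cycle_spec <- function(f_pao, vfa_feed_cmol = 12, acetate_fraction = 0.75,
                       anaerobic_min = 120, aerobic_min = 180,
                       p_to_c_feed = 0.15, noise_sd_rel = 0,
                       n_timepoints = 31,
                       pao_ref = pao_reference(), gao_ref = gao_reference(),
                       seed = 1) {
  stopifnot(f_pao >= 0, f_pao <= 1, vfa_feed_cmol > 0,
            acetate_fraction >= 0, acetate_fraction <= 1,
            anaerobic_min > 0, aerobic_min > 0, noise_sd_rel >= 0,
            n_timepoints >= 4,
            inherits(pao_ref, "reference_stoichiometry"),
            inherits(gao_ref, "reference_stoichiometry"))
  structure(list(f_pao = f_pao, vfa_feed_cmol = vfa_feed_cmol,
                 acetate_fraction = acetate_fraction,
                 anaerobic_min = anaerobic_min, aerobic_min = aerobic_min,
                 p_to_c_feed = p_to_c_feed, noise_sd_rel = noise_sd_rel,
                 n_timepoints = as.integer(n_timepoints),
                 pao_ref = pao_ref, gao_ref = gao_ref,
                 seed = as.integer(seed)),
            class = "cycle_spec")
}

#' Generate a two-population cycle chemistry time series
#'
#' Piecewise-linear phase stoichiometry of a mixed PAO/GAO biomass.
#' Anaerobically, VFA declines to zero at a constant rate while ortho-P,
#' glycogen, PHB and PHV change in proportion to the VFA consumed, with
#' coefficients mixed linearly between the two end members:
#' `coef = f_pao * PAO + (1 - f_pao) * GAO`. Aerobically, PHA drains to
#' zero, glycogen is replenished to its initial pool, and ortho-P is taken
#' up to below its initial value whenever PAOs are present. Multiplicative
#' Gaussian noise at `noise_sd_rel` is applied to every concentration.
#'
#' @param spec A [cycle_spec()].
#' @return A `cycle_series` data.frame with columns `time_min, phase,
#'   hac_cmmol, hpr_cmmol, po4_pmmol, gly_cmmol, phb_cmmol, phv_cmmol`.
#' @export
generate_cycle <- function(spec) {
  stopifnot(inherits(spec, "cycle_spec"))
  f <- spec$f_pao
  mix <- function(key) f * spec$pao_ref[[key]] + (1 - f) * spec$gao_ref[[key]]
  T_an <- spec$anaerobic_min; T_ae <- spec$aerobic_min
  n <- spec$n_timepoints
  k_an <- max(2, round(n * T_an / (T_an + T_ae)))
  k_ae <- max(2, n - k_an)
  t_an <- seq(0, T_an, length.out = k_an)
  t_ae <- seq(T_an, T_an + T_ae, length.out = k_ae + 1)[-1]
  vfa0 <- spec$vfa_feed_cmol
  p0 <- spec$p_to_c_feed * vfa0
  gly0 <- 1.25 * mix("gly_vfa") * vfa0

  consumed <- vfa0 * t_an / T_an
  remaining <- vfa0 - consumed
  an <- data.frame(
    time_min = t_an, phase = "anaerobic",
    hac_cmmol = spec$acetate_fraction * remaining,
    hpr_cmmol = (1 - spec$acetate_fraction) * remaining,
    po4_pmmol = p0 + mix("p_vfa") * consumed,
    gly_cmmol = gly0 - mix("gly_vfa") * consumed,
    phb_cmmol = mix("phb_vfa") * consumed,
    phv_cmmol = mix("phv_vfa") * consumed,
    stringsAsFactors = FALSE)
  u <- (t_ae - T_an) / T_ae
  p_end_an <- p0 + mix("p_vfa") * vfa0
  p_final <- p0 * (1 - 0.5 * f)
  ae <- data.frame(
    time_min = t_ae, phase = "aerobic",
    hac_cmmol = 0, hpr_cmmol = 0,
    po4_pmmol = p_end_an + (p_final - p_end_an) * u,
    gly_cmmol = (gly0 - mix("gly_vfa") * vfa0) + mix("gly_vfa") * vfa0 * u,
    phb_cmmol = mix("phb_vfa") * vfa0 * (1 - u),
    phv_cmmol = mix("phv_vfa") * vfa0 * (1 - u),
    stringsAsFactors = FALSE)
  out <- rbind(an, ae)
  if (spec$noise_sd_rel > 0) {
    conc <- c("hac_cmmol", "hpr_cmmol", "po4_pmmol", "gly_cmmol",
              "phb_cmmol", "phv_cmmol")
    out[conc] <- with_stream(spec$seed, "cycle-noise", {
      lapply(out[conc], function(v) {
        pmax(0, v * (1 + stats::rnorm(length(v), 0, spec$noise_sd_rel)))
      })
    })
  }
  rownames(out) <- NULL
  class(out) <- c("cycle_series", "data.frame")
  out
}

#' Write / read a cycle series CSV
#'
#' Interchange format with header
#' `time_min,phase,hac_cmmol,hpr_cmmol,po4_pmmol,gly_cmmol,phb_cmmol,phv_cmmol`.
#'
#' @param series A `cycle_series` data.frame.
#' @param path File path.
#' @export
write_cycle <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cycle
#' @export
read_cycle <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cycle_series", "data.frame")
  out
}

#' A set of cycle transformation ratios
#'
#' Container for the anaerobic transformation ratios of a cycle: P released,
#' glycogen consumed, PHB and PHV formed per C-mol of VFA taken up. PHA/VFA
#' is the sum of the PHB and PHV components.
#'
#' @param p_vfa,gly_vfa,phb_vfa,phv_vfa Ratios.
#' @param method How the deltas were obtained (`"endpoint"`, `"rate"`, or
#'   `"declared"` for hand-entered values).
#' @return Object of class `ratio_set`.
#' @export
ratio_set <- function(p_vfa, gly_vfa, phb_vfa, phv_vfa,
                      method = "declared") {
  structure(list(p_vfa = p_vfa, gly_vfa = gly_vfa,
                 pha_vfa = phb_vfa + phv_vfa,
                 phb_vfa = phb_vfa, phv_vfa = phv_vfa,
                 method = method),
            class = "ratio_set")
}

#' @export
print.ratio_set <- function(x, ...) {
  cat(sprintf(
    "P/VFA %.3f  Glycogen/VFA %.3f  PHA/VFA %.3f  PHB/VFA %.3f  PHV/VFA %.3f  [%s]\n",
    x$p_vfa, x$gly_vfa, x$pha_vfa, x$phb_vfa, x$phv_vfa, x$method))
  invisible(x)
}

#' Anaerobic transformation ratios of a cycle series
#'
#' Over the anaerobic phase, VFA uptake is the drop in acetate + propionate;
#' each ratio is the corresponding release/consumption/formation divided by
#' that uptake. By default deltas are taken between the phase's first and
#' last timepoints; `method = "rate"` instead uses least-squares slopes over
#' the first `rate_window_min` minutes of the phase (initial-rate
#' convention) and takes ratios of rates.
#'
#' @param series A `cycle_series` data.frame.
#' @param method `"endpoint"` (default) or `"rate"`.
#' @param rate_window_min Initial-rate window in minutes (default 30).
#' @return A [ratio_set()].
#' @export
transformation_ratios <- function(series, method = c("endpoint", "rate"),
                                  rate_window_min = 30) {
  method <- match.arg(method)
  an <- series[series$phase == "anaerobic", , drop = FALSE]
  if (nrow(an) < 2) stop("series lacks an anaerobic phase")
  an <- an[order(an$time_min), ]
  if (method == "endpoint") {
    first <- an[1, ]; last <- an[nrow(an), ]
    d_vfa <- (first$hac_cmmol + first$hpr_cmmol) -
      (last$hac_cmmol + last$hpr_cmmol)
    if (d_vfa <= 0) stop("no anaerobic uptake (delta VFA <= 0)")
    ratio_set(
      p_vfa = (last$po4_pmmol - first$po4_pmmol) / d_vfa,
      gly_vfa = (first$gly_cmmol - last$gly_cmmol) / d_vfa,
      phb_vfa = (last$phb_cmmol - first$phb_cmmol) / d_vfa,
      phv_vfa = (last$phv_cmmol - first$phv_cmmol) / d_vfa,
      method = "endpoint")
  } else {
    w <- an[an$time_min <= an$time_min[1] + rate_window_min, , drop = FALSE]
    if (nrow(w) < 2) stop("rate window contains fewer than 2 timepoints")
    slope <- function(y) unname(stats::coef(stats::lm(y ~ w$time_min))[2])
    r_vfa <- -(slope(w$hac_cmmol + w$hpr_cmmol))
    if (r_vfa <= 0) stop("no anaerobic uptake (VFA rate <= 0)")
    ratio_set(
      p_vfa = slope(w$po4_pmmol) / r_vfa,
      gly_vfa = -slope(w$gly_cmmol) / r_vfa,
      phb_vfa = slope(w$phb_cmmol) / r_vfa,
      phv_vfa = slope(w$phv_cmmol) / r_vfa,
      method = "rate")
  }
}

#' Estimate the PAO fraction of the PAO+GAO biomass
#'
#' Two-component linear mixing: the observed ratios are modelled as
#' `f * PAO + (1 - f) * GAO`. With `basis = "p_vfa"` the estimate uses the
#' P-release-to-VFA-uptake ratio alone,
#' `f = (obs - GAO) / (PAO - GAO)`; with `basis = "least_squares"` the
#' closed-form least-squares fit over the selected ratios is used. The
#' estimate is clipped to \[0, 1\] with a warning when the observation lies
#' outside the reference span.
#'
#' @param observed A [ratio_set()].
#' @param pao_ref,gao_ref End members ([reference_stoichiometry()]).
#' @param basis `"p_vfa"` (default) or `"least_squares"`.
#' @param ratios Ratios entering the least-squares fit.
#' @return Object of class `pao_fraction_estimate`: `f_pao`, `f_gao`,
#'   `basis`, `clipped`, `raw`, and a per-ratio `residuals` data.frame.
#' @export
pao_fraction <- function(observed, pao_ref = pao_reference(),
                         gao_ref = gao_reference(),
                         basis = c("p_vfa", "least_squares"),
                         ratios = c("p_vfa", "gly_vfa", "phb_vfa", "phv_vfa")) {
  basis <- match.arg(basis)
  stopifnot(inherits(observed, "ratio_set"))
  if (basis == "p_vfa") {
    if (pao_ref$p_vfa == gao_ref$p_vfa) {
      stop("p_vfa basis requires distinct PAO and GAO P/VFA references")
    }
    raw <- (observed$p_vfa - gao_ref$p_vfa) / (pao_ref$p_vfa - gao_ref$p_vfa)
  } else {
    d <- vapply(ratios, function(r) pao_ref[[r]] - gao_ref[[r]], 0)
    o <- vapply(ratios, function(r) observed[[r]] - gao_ref[[r]], 0)
    raw <- sum(o * d) / sum(d^2)
  }
  f <- min(1, max(0, raw))
  if (f != raw) {
    warning(sprintf(
      "mixing estimate %.3f outside [0,1]; clipped (observation outside the reference span)",
      raw))
  }
  resid <- data.frame(
    ratio = ratios,
    observed = vapply(ratios, function(r) observed[[r]], 0),
    fitted = vapply(ratios, function(r) {
      f * pao_ref[[r]] + (1 - f) * gao_ref[[r]]
    }, 0))
  resid$residual <- resid$observed - resid$fitted
  rownames(resid) <- NULL
  structure(list(f_pao = f, f_gao = 1 - f, basis = basis,
                 clipped = f != raw, raw = raw, residuals = resid),
            class = "pao_fraction_estimate")
}

#' @export
print.pao_fraction_estimate <- function(x, ...) {
  cat(sprintf("PAO %.0f%% / GAO %.0f%% of the PAO+GAO biomass (basis: %s%s)\n",
              100 * x$f_pao, 100 * x$f_gao, x$basis,
              if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Check whether observed ratios lie between the two references
#'
#' A mixed PAO/GAO biomass should, ratio by ratio, fall inside the closed
#' interval spanned by the pure-culture references. This reports the facts:
#' for each ratio, `inside`, `below` or `above`.
#'
#' @inheritParams pao_fraction
#' @return Data.frame `ratio, observed, lower, upper, status`.
#' @export
betweenness_check <- function(observed, pao_ref = pao_reference(),
                              gao_ref = gao_reference()) {
  ratios <- c("p_vfa", "gly_vfa", "pha_vfa", "phb_vfa", "phv_vfa")
  lo <- vapply(ratios, function(r) min(pao_ref[[r]], gao_ref[[r]]), 0)
  hi <- vapply(ratios, function(r) max(pao_ref[[r]], gao_ref[[r]]), 0)
  obs <- vapply(ratios, function(r) observed[[r]], 0)
  data.frame(ratio = ratios, observed = obs, lower = lo, upper = hi,
             status = ifelse(obs < lo, "below",
                             ifelse(obs > hi, "above", "inside")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Side-by-side PAO-fraction report
#'
#' Computes the endpoint-delta mixing estimate and sets it beside a
#' rate-based figure (either computed from a series with
#' `transformation_ratios(method = "rate")` upstream, or an external
#' rate-based percentage), reporting both and their difference rather than
#' forcing agreement — the two conventions legitimately differ by a few
#' percentage points.
#'
#' @param observed A [ratio_set()] (endpoint convention).
#' @param rate_based_pct A rate-based PAO percentage to compare against
#'   (e.g. from an initial-rate analysis of the same cycle).
#' @inheritParams pao_fraction
#' @return Data.frame with rows `endpoint_p_vfa` and `rate_based`, their
#'   PAO percentages, and an attribute `difference_pp`.
#' @export
pao_fraction_report <- function(observed, rate_based_pct = NA,
                                pao_ref = pao_reference(),
                                gao_ref = gao_reference()) {
  est <- pao_fraction(observed, pao_ref, gao_ref, basis = "p_vfa")
  out <- data.frame(
    method = c("endpoint_p_vfa", "rate_based"),
    f_pao_pct = c(100 * est$f_pao, rate_based_pct),
    stringsAsFactors = FALSE)
  attr(out, "difference_pp") <- abs(out$f_pao_pct[1] - out$f_pao_pct[2])
  out
}
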