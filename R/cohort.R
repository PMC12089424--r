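#' Define a biomarker for the cohort generator
#'
#' Each biomarker is generated as
#' `group_mean + loading * (theta - group_theta_mean) + Normal(0, residual_sd_g)`
#' so its group means are exact in expectation. When `residual_sd` is NULL
#' (the default) the per-group residual SDs are derived so the per-group
#' target SDs are met exactly in expectation:
#' `residual_sd_g = sqrt(group_sd^2 - loading^2 * theta_sd_g^2)` (floored at
#' 0.05). A scalar `residual_sd` overrides the derivation in all groups.
#'
#' @param name biomarker column name.
#' @param group_means,group_sds numeric length-3 vectors (CN, MCI, AD) on the
#'   z-score scale.
#' @param loading regression of the biomarker on latent cognition within
#'   group (z-units per latent SD); negative for pathology markers that rise
#'   as cognition falls.
#' @param residual_sd optional scalar residual SD overriding the derivation.
#' @return list of class `biomarker_def`.
#' @export
biomarker_def <- function(name, group_means, group_sds, loading,
                          residual_sd = NULL) {
  stopifnot(length(group_means) == 3L, length(group_sds) == 3L,
            all(group_sds > 0), is.numeric(loading), length(loading) == 1L)
  structure(list(name = name, group_means = group_means,
                 group_sds = group_sds, loading = loading,
                 residual_sd = residual_sd),
            class = "biomarker_def")
}

default_biomarkers <- function() {
  list(
    biomarker_def("wmh",          c(-0.23, 0.11, 0.36), c(1.00, 1.01, 0.83), -0.20),
    biomarker_def("amyloid",      c(-0.41, 0.10, 0.89), c(0.74, 1.01, 0.96), -0.35),
    biomarker_def("entorhinal",   c(0.45, -0.01, -1.22), c(0.56, 0.98, 1.00),  0.45),
    biomarker_def("hippocampus",  c(0.47, -0.08, -1.10), c(0.70, 0.99, 0.82),  0.45),
    biomarker_def("mtl_volume",   c(0.39, -0.04, -0.99), c(0.75, 0.98, 0.96),  0.40),
    biomarker_def("ltl_volume",   c(0.39, -0.05, -0.97), c(0.82, 0.95, 0.89),  0.40)
  )
}

#' Specify a synthetic three-group cohort
#'
#' Defaults emulate the marginal structure of a clinical aging cohort with
#' stratified recruitment: 482 cognitively normal (CN), 430 mild cognitive
#' impairment (MCI) and 172 Alzheimer's disease (AD) participants; latent
#' cognition means (0.86, 0.19, -0.79) and SDs (0.47, 0.51, 0.36) by group;
#' six biomarkers on the z-score scale whose group means and SDs reproduce
#' published full-sample-standardized summaries (white matter
#' hyperintensities, amyloid burden, entorhinal thickness, hippocampal,
#' medial and lateral temporal volumes). Each biomarker also loads on latent
#' cognition within group, giving within-group correlations.
#'
#' @param n_per_group integer length-3 (CN, MCI, AD); all zero is an error at
#'   generation time.
#' @param group_cognition_means,group_cognition_sds latent cognition moments
#'   per group.
#' @param biomarkers list of [biomarker_def()] objects.
#' @param phase_probabilities length-2 probabilities for a two-level study
#'   phase indicator (phase 0 / phase 1), summing to one.
#' @param tracer_probabilities length-2 probabilities for a two-level PET
#'   tracer indicator, summing to one.
#' @param seed default seed used by [generate_cohort()].
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(cn = 482L, mci = 430L, ad = 172L),
                        group_cognition_means = c(0.86, 0.19, -0.79),
                        group_cognition_sds = c(0.47, 0.51, 0.36),
                        biomarkers = default_biomarkers(),
                        phase_probabilities = c(0.6, 0.4),
                        tracer_probabilities = c(0.7, 0.3),
                        seed = 1L) {
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 0),
            length(group_cognition_means) == 3L,
            length(group_cognition_sds) == 3L,
            all(group_cognition_sds > 0))
  for (p in list(phase_probabilities, tracer_probabilities)) {
    if (length(p) != 2L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("phase/tracer probabilities must be two nonnegative values summing to 1")
  }
  if (!all(vapply(biomarkers, inherits, logical(1), "biomarker_def")))
    stop("'biomarkers' must be a list of biomarker_def objects")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_cognition_means = group_cognition_means,
                 group_cognition_sds = group_cognition_sds,
                 biomarkers = biomarkers,
                 phase_probabilities = phase_probabilities,
                 tracer_probabilities = tracer_probabilities,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws, per person: diagnostic group (fixed counts), latent cognition
#' `theta ~ Normal(group mean, group SD)`, each biomarker as a linear loading
#' on theta plus a group shift plus normal noise, and phase/tracer
#' indicators. The exact latent R-squared implied by the realized cohort is
#' recorded for parameter-recovery tests: for each biomarker singly and for
#' all jointly, the R-squared of the least-squares projection of true
#' cognition on (phase, biomarkers).
#'
#' @param spec a [cohort_spec()].
#' @param seed seed overriding `spec$seed`.
#' @return data.frame of class `cohort` with columns `person_id`, `group`
#'   (factor CN/MCI/AD), `phase`, `tracer`, `true_cognition` and one column
#'   per biomarker; attribute `true_r2` holds the named latent R-squared
#'   vector, attribute `spec` the generating spec.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- sum(spec$n_per_group)
  if (n == 0L) stop("all group sizes are zero")
  set.seed(as.integer(seed))
  grp <- rep(factor(c("CN", "MCI", "AD"), levels = c("CN", "MCI", "AD")),
             times = spec$n_per_group)
  gi <- as.integer(grp)
  theta <- stats::rnorm(n, spec$group_cognition_means[gi],
                        spec$group_cognition_sds[gi])
  out <- data.frame(
    person_id = sprintf("p%04d", seq_len(n)),
    group = grp,
    phase = stats::rbinom(n, 1L, spec$phase_probabilities[2L]),
    tracer = stats::rbinom(n, 1L, spec$tracer_probabilities[2L]),
    true_cognition = theta,
    stringsAsFactors = FALSE
  )
  for (bm in spec$biomarkers) {
    if (is.null(bm$residual_sd)) {
      res_sd <- sqrt(pmax(bm$group_sds^2 -
                            bm$loading^2 * spec$group_cognition_sds^2, 0.05^2))
    } else {
      res_sd <- rep(bm$residual_sd, 3L)
    }
    out[[bm$name]] <- bm$group_means[gi] +
      bm$loading * (theta - spec$group_cognition_means[gi]) +
      stats::rnorm(n, 0, res_sd[gi])
  }
  bm_names <- vapply(spec$biomarkers, `[[`, character(1), "name")
  r2 <- vapply(bm_names, function(b) {
    summary(stats::lm(stats::reformulate(c("phase", b), "true_cognition"),
                      data = out))$r.squared
  }, numeric(1))
  r2 <- c(r2, all = summary(stats::lm(
    stats::reformulate(c("phase", bm_names), "true_cognition"),
    data = out))$r.squared)
  attr(out, "true_r2") <- r2
  attr(out, "spec") <- spec
  class(out) <- c("cohort", "data.frame")
  out
}

#' Adjust regional brain volumes for intracranial volume
#'
#' Removes the linear dependence on total intracranial volume (ICV):
#' `adjusted = raw - beta_hat * (ICV - mean(ICV))`, where `beta_hat` is the
#' least-squares slope of volume on ICV. The reversed regression direction,
#' occasionally seen in method descriptions, is exposed behind `direction`
#' but not recommended.
#'
#' @param volume_raw,icv_raw numeric vectors of equal length >= 3.
#' @param direction `"volume_on_icv"` (default, standard practice) or
#'   `"icv_on_volume"`.
#' @return adjusted volume vector.
#' @export
icv_adjust <- function(volume_raw, icv_raw,
                       direction = c("volume_on_icv", "icv_on_volume")) {
  direction <- match.arg(direction)
  if (length(volume_raw) != length(icv_raw) || length(icv_raw) < 3L)
    stop("'volume_raw' and 'icv_raw' must have equal length >= 3")
  if (stats::sd(icv_raw) == 0)
    stop("constant ICV: regression slope undefined")
  beta_hat <- if (direction == "volume_on_icv") {
    stats::cov(volume_raw, icv_raw) / stats::var(icv_raw)
  } else {
    if (stats::sd(volume_raw) == 0) stop("constant volume: slope undefined")
    stats::cov(volume_raw, icv_raw) / stats::var(volume_raw)
  }
  volume_raw - beta_hat * (icv_raw - mean(icv_raw))
}

#' Log-transform white matter hyperintensity volumes
#'
#' Natural log, elementwise. Volumes are physically positive; exact zeros
#' (possible after segmentation rounding) are replaced by a small offset
#' `delta` before the log, with a warning.
#'
#' @param wmh_cc numeric vector of volumes in cubic centimeters, >= 0.
#' @param delta offset substituted for exact zeros (cc).
#' @return log-volume vector.
#' @export
log_transform_wmh <- function(wmh_cc, delta = 0.001) {
  if (any(wmh_cc < 0, na.rm = TRUE)) stop("negative WMH volume")
  nz <- sum(wmh_cc == 0, na.rm = TRUE)
  if (nz > 0L) {
    warning(sprintf("%d zero WMH volume(s) replaced by delta = %g before log", nz, delta))
    wmh_cc[wmh_cc == 0] <- delta
  }
  log(wmh_cc)
}

#' Z-score a vector
#'
#' `(x - mean) / sd` with the n-1 denominator. Errors on constant input.
#'
#' @param values numeric vector, length >= 2.
#' @return standardized vector (mean 0, SD 1).
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("constant vector: z-score undefined")
  (values - mean(values)) / s
}

#' Score a synthetic cohort with an item bank
#'
#' Simulates item responses at each person's true latent cognition, computes
#' EAP scores with per-person SEMs, and standardizes both to the sample score
#' scale (mean 0, SD 1; SEMs divided by the same SD). The result is the unit
#' of analysis for the regression models: one row per person with `score`,
#' `sem`, group/phase/tracer and the biomarker columns.
#'
#' @param cohort a [generate_cohort()] result.
#' @param bank an [item_bank()].
#' @param seed integer seed for response simulation.
#' @param grid a [quadrature_grid()].
#' @return data.frame (a "scored dataset") with columns `person_id`,
#'   `domain`, `score`, `sem`, `group`, `phase`, `tracer`, `true_cognition`,
#'   and the biomarkers. Attribute `scale` records the standardization
#'   reference (mean, sd of raw EAP scores).
#' @export
score_cohort <- function(cohort, bank, seed, grid = quadrature_grid()) {
  stopifnot(inherits(cohort, "cohort"), inherits(bank, "item_bank"))
  resp <- simulate_responses(cohort$true_cognition, bank, seed)
  sc <- eap_score_matrix(resp, bank, grid)
  ref_mean <- mean(sc$theta_hat)
  ref_sd <- stats::sd(sc$theta_hat)
  std <- standardize_scores(sc$theta_hat, ref_mean, ref_sd, sems = sc$sem)
  out <- data.frame(person_id = cohort$person_id,
                    domain = bank$domain_label,
                    score = std$scores, sem = std$sems,
                    group = cohort$group, phase = cohort$phase,
                    tracer = cohort$tracer,
                    true_cognition = cohort$true_cognition,
                    stringsAsFactors = FALSE)
  bm <- setdiff(names(cohort),
                c("person_id", "group", "phase", "tracer", "true_cognition"))
  out[bm] <- cohort[bm]
  attr(out, "scale") <- c(mean = ref_mean, sd = ref_sd)
  attr(out, "true_r2") <- attr(cohort, "true_r2")
  out
}

#' Write / read a cohort as delimited text with metadata
#'
#' The cohort table is tab-separated; a companion JSON metadata file records
#' the generating spec and the implied true latent R-squared per model.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path table path (tab-separated).
#' @param metadata_path optional JSON path; defaults to `path` with a
#'   `.meta.json` suffix.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, metadata_path = paste0(path, ".meta.json")) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  spec <- attr(cohort, "spec")
  meta <- list(
    n_per_group = spec$n_per_group,
    group_cognition_means = spec$group_cognition_means,
    group_cognition_sds = spec$group_cognition_sds,
    seed = spec$seed,
    true_r2 = as.list(attr(cohort, "true_r2"))
  )
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
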