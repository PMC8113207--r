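# Synthetic patient cohort generator.
#
# One latent severity variable per subject drives every uptake metric,
# every regional strain, both biomarkers and the visual grade, through a
# single-factor linear model: a variable with loading `lambda` on severity
# is  mean + sd * (lambda * s + sqrt(1 - lambda^2) * noise),  so two
# variables with loadings a and b have population correlation a * b. Burden
# (dpd_load) carries the highest loading, which is what makes it the best
# correlate of strain and biomarkers in the synthetic world — mirroring the
# behaviour the analysis is designed to detect.

.cohort_regions <- c("LV_LATERAL", "IVS", "APEX", "RV_FREE_WALL", "LV",
                     "VENTRICLES")
.strain_regions <- c("LV_LATERAL", "IVS", "APEX", "RV_FREE_WALL", "LV")

# anchors: per-region mean/SD of each uptake metric and of regional strain
# in a severe type-A amyloid cardiomyopathy cohort (arbitrary SUV units;
# strain in signed percent)
.default_anchors <- function() {
  list(
    dpd_mean = list(LV_LATERAL = c(43.4, 17.5), IVS = c(54.6, 20.1),
                    APEX = c(36.5, 16.0), RV_FREE_WALL = c(30.2, 10.6),
                    LV = c(51.4, 18.9), VENTRICLES = c(50.9, 18.7)),
    dpd_max = list(LV_LATERAL = c(67.8, 26.0), IVS = c(87.5, 32.5),
                   APEX = c(57.6, 24.3), RV_FREE_WALL = c(53.9, 18.6),
                   LV = c(87.7, 32.3), VENTRICLES = c(87.7, 32.3)),
    dpd_load = list(LV_LATERAL = c(4448.0, 2595.8), IVS = c(5099.0, 2685.9),
                    APEX = c(1100.2, 700.8), RV_FREE_WALL = c(2574.1, 1476.1),
                    LV = c(9429.5, 5252.1), VENTRICLES = c(10144.4, 5688.7)),
    strain = list(LV_LATERAL = c(-14.1, 5.5), IVS = c(-11.6, 5.3),
                  APEX = c(-25.5, 7.5), RV_FREE_WALL = c(-20.2, 6.9),
                  LV = c(-17.0, 5.1)),
    troponin_t = c(28.8, 18.0),
    log10_nt_probnp = c(2.8, 0.6)
  )
}

#' Synthetic cohort specification
#'
#' @param n_subjects number of subjects, default 48.
#' @param strain_link_r target Pearson correlation between each regional
#'   `dpd_load` and its matched strain, default 0.70.
#' @param troponin_link_r,lognt_link_r target correlations between the
#'   ventricles `dpd_load` and troponin T / log10 NT-ProBNP.
#' @param metric_loading severity loadings of the three uptake metrics;
#'   `dpd_load` must carry the largest for burden to be the best correlate.
#' @param grade_overlap SD of the jitter added to severity before applying
#'   the visual-grade thresholds; 0 makes grades a deterministic function of
#'   severity, larger values blur the grade 2/3 boundary.
#' @param grade_probs expected fractions of grades 1, 2, 3 (defaults 3/48,
#'   10/48, 35/48).
#' @param n_troponin,n_nt_probnp,n_rv_strain subjects with the measurement
#'   available (complete-case analyses then reproduce varying denominators).
#' @param anchors per-variable mean/SD anchors; see `dpdquant:::.default_anchors`.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 48L,
                        strain_link_r = 0.70,
                        troponin_link_r = 0.558,
                        lognt_link_r = 0.356,
                        metric_loading = c(dpd_load = 0.95, dpd_mean = 0.80,
                                           dpd_max = 0.80),
                        grade_overlap = 0.5,
                        grade_probs = c(3, 10, 35) / 48,
                        n_troponin = 36L, n_nt_probnp = 40L,
                        n_rv_strain = 34L,
                        anchors = .default_anchors(),
                        seed = 1L) {
  if (n_subjects < 4L) stop("'n_subjects' must be at least 4")
  stopifnot(all(c("dpd_load", "dpd_mean", "dpd_max") %in% names(metric_loading)))
  for (r in c(strain_link_r, troponin_link_r, lognt_link_r))
    if (abs(r) > 1) stop("target correlations must lie in [-1, 1]")
  if (any(metric_loading <= 0) || any(metric_loading > 1))
    stop("metric loadings must lie in (0, 1]")
  if (strain_link_r / metric_loading[["dpd_load"]] > 1)
    stop("strain_link_r is unreachable with the given dpd_load loading")
  if (abs(sum(grade_probs) - 1) > 1e-9 || length(grade_probs) != 3L)
    stop("'grade_probs' must be three fractions summing to 1")
  if (grade_overlap < 0) stop("'grade_overlap' must be >= 0")
  ns <- c(n_troponin, n_nt_probnp, n_rv_strain)
  if (any(ns < 0) || any(ns > n_subjects))
    stop("availability counts must be between 0 and n_subjects")
  structure(list(n_subjects = as.integer(n_subjects),
                 strain_link_r = strain_link_r,
                 troponin_link_r = troponin_link_r,
                 lognt_link_r = lognt_link_r,
                 metric_loading = metric_loading,
                 grade_overlap = grade_overlap,
                 grade_probs = grade_probs,
                 n_troponin = as.integer(n_troponin),
                 n_nt_probnp = as.integer(n_nt_probnp),
                 n_rv_strain = as.integer(n_rv_strain),
                 anchors = anchors,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.factor_draw <- function(mean, sd, loading, s) {
  eps <- stats::rnorm(length(s))
  mean + sd * (loading * s + sqrt(max(0, 1 - loading^2)) * eps)
}

#' Generate a synthetic cohort table
#'
#' Draws one latent severity per subject and derives all uptake metrics,
#' regional strains, biomarkers, the visual grade and the apical-sparing
#' strain segments from it (see [cohort_spec()]). Missingness is imposed by
#' sampling which subjects carry each optional measurement.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` of class `cohort_table`: one row per subject with
#'   columns `subject`, `dpd_{mean,max,load}_<REGION>` for the six regions,
#'   `strain_<REGION>` for the five strain regions, `strain_apical`,
#'   `strain_basal`, `strain_mid`, `echo_sparing_ratio`, `troponin_t`,
#'   `nt_probnp`, `log10_nt_probnp`, `perugini_grade`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_subjects
  anc <- spec$anchors
  s <- stats::rnorm(n)  # latent severity

  out <- data.frame(subject = sprintf("S%03d", seq_len(n)))

  # uptake metrics (higher severity -> higher uptake); floors keep the
  # values physical without reshaping the distributions materially
  for (m in c("dpd_mean", "dpd_max", "dpd_load")) {
    lam <- spec$metric_loading[[m]]
    for (reg in .cohort_regions) {
      a <- anc[[m]][[reg]]
      floor_val <- if (m == "dpd_load") 50 else 5
      out[[paste0(m, "_", reg)]] <-
        pmax(floor_val, .factor_draw(a[1], a[2], lam, s))
    }
  }

  # strain: loading chosen so corr(dpd_load, strain) hits strain_link_r;
  # higher severity -> less negative strain, hence a positive loading
  lam_strain <- spec$strain_link_r / spec$metric_loading[["dpd_load"]]
  for (reg in .strain_regions) {
    a <- anc$strain[[reg]]
    out[[paste0("strain_", reg)]] <-
      pmin(-0.1, .factor_draw(a[1], a[2], lam_strain, s))
  }

  # apical sparing segments: apical mean equals basal + mid mean, so the
  # sparing prevalence is 50% by symmetry
  out$strain_apical <- out$strain_APEX
  out$strain_basal <- .factor_draw(-10.5, 3.0, lam_strain, s)
  out$strain_mid <- .factor_draw(-15.0, 3.0, lam_strain, s)
  out$echo_sparing_ratio <- vapply(seq_len(n), function(i)
    apical_sparing_echo(out$strain_apical[i], out$strain_basal[i],
                        out$strain_mid[i])$ratio, numeric(1))

  # biomarkers, linked to ventricles dpd_load through severity
  lam_load <- spec$metric_loading[["dpd_load"]]
  tro <- .factor_draw(anc$troponin_t[1], anc$troponin_t[2],
                      spec$troponin_link_r / lam_load, s)
  out$troponin_t <- pmax(1, tro)
  out$log10_nt_probnp <- .factor_draw(anc$log10_nt_probnp[1],
                                      anc$log10_nt_probnp[2],
                                      spec$lognt_link_r / lam_load, s)
  out$nt_probnp <- 10^out$log10_nt_probnp

  # visual grade: thresholds on jittered severity at the marginal quantiles
  # implied by grade_probs; jitter > 0 creates grade 2/3 overlap in burden
  g <- s + if (spec$grade_overlap > 0)
    stats::rnorm(n, sd = spec$grade_overlap) else 0
  g_sd <- sqrt(1 + spec$grade_overlap^2)
  cuts <- stats::qnorm(cumsum(spec$grade_probs)[1:2], sd = g_sd)
  out$perugini_grade <- as.integer(cut(g, c(-Inf, cuts, Inf), labels = FALSE))

  # missingness (complete-case denominators downstream)
  miss <- function(cols, n_avail) {
    drop <- sample.int(n, n - n_avail)
    for (col in cols) out[[col]][drop] <<- NA_real_
  }
  miss("troponin_t", spec$n_troponin)
  miss(c("nt_probnp", "log10_nt_probnp"), spec$n_nt_probnp)
  miss("strain_RV_FREE_WALL", spec$n_rv_strain)

  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a `cohort_table` (from [make_cohort()]).
#' @param path CSV path.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
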