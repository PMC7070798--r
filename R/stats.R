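# Statistical layer: per-batch summary records, linear fits of scan counts
# and estimated volumes against pruning dry biomass (pooled and by
# treatment), and sequential ANOVA for the treatment effect.

#' Ordinary least-squares fit with slope inference
#'
#' Plain OLS of `y` on `x` with the classical two-sided t test on the
#' slope; no robust errors, matching how estimate/SE/p tables are reported
#' for this kind of survey data.
#'
#' @param x,y equal-length numeric vectors, n >= 3, `var(x) > 0`
#' @return a one-row data frame of class `fit_report`: `slope`,
#'   `intercept`, `se_slope`, `p_value`, `r_squared`, `n`
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  if (var(x) == 0) stop("x has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  out <- data.frame(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]),
                    se_slope = sm$coefficients[2, 2],
                    p_value = sm$coefficients[2, 4],
                    r_squared = sm$r.squared,
                    n = n)
  class(out) <- c("fit_report", "data.frame")
  out
}

#' Assemble per-batch records from pipeline outputs
#'
#' @param truth a [batch_truth()] table (treatment, plot, volume, biomass)
#' @param volumes data frame with per-batch `n_scans`, `n_points`,
#'   `volume_total`, `volume_no_structures` in the same batch order
#' @param biomass observed biomass, kg; defaults to the truth biomass (for
#'   synthetic runs this is the ground truth; add noise upstream to emulate
#'   weighing/drying variability)
#' @return data frame of class `batch_records`
#' @export
batch_records <- function(truth, volumes, biomass = truth$true_biomass) {
  stopifnot(nrow(truth) == nrow(volumes))
  out <- data.frame(treatment = truth$treatment, plot = truth$plot,
                    n_scans = volumes$n_scans, n_points = volumes$n_points,
                    volume_total = volumes$volume_total,
                    volume_no_structures = volumes$volume_no_structures,
                    biomass = biomass,
                    true_volume = truth$true_shoot_volume)
  if (any(out$volume_no_structures > out$volume_total + 1e-12))
    stop("volume_no_structures exceeds volume_total")
  class(out) <- c("batch_records", "data.frame")
  out
}

#' Linear fits of biomass on a predictor, by treatment and pooled
#'
#' One OLS fit per treatment plus the pooled fit over all records,
#' mirroring the estimate/SE/p-value regression tables of pruning-biomass
#' surveys.  Groups with fewer than 3 records are skipped with a warning.
#'
#' @param records a [batch_records()] table
#' @param predictor one of `"n_scans"`, `"volume_total"`,
#'   `"volume_no_structures"`
#' @param response response column (default `"biomass"`)
#' @return data frame with `variable`, `treatment` (`"all"` = pooled),
#'   `estimate` (slope), `intercept`, `se`, `p_value`, `r_squared`, `n`
#' @export
fits_by_group <- function(records,
                          predictor = c("n_scans", "volume_total",
                                        "volume_no_structures"),
                          response = "biomass") {
  predictor <- match.arg(predictor)
  groups <- unique(as.character(records$treatment))
  rows <- list()
  addfit <- function(label, x, y) {
    f <- linear_fit(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = predictor, treatment = label, estimate = f$slope,
      intercept = f$intercept, se = f$se_slope, p_value = f$p_value,
      r_squared = f$r_squared, n = f$n)
  }
  for (g in groups) {
    sel <- records$treatment == g
    if (sum(sel) < 3) {
      warning(sprintf("treatment %s has fewer than 3 records; skipped", g))
      next
    }
    addfit(g, records[[predictor]][sel], records[[response]][sel])
  }
  addfit("all", records[[predictor]], records[[response]])
  do.call(rbind, rows)
}

#' Sequential ANOVA of biomass on a LiDAR predictor and treatment
#'
#' Fits `biomass ~ predictor + treatment` and returns the sequential
#' (type-I) ANOVA table, predictor entered first — the test of whether the
#' LiDAR reading explains shoot weight and whether treatment adds anything
#' beyond it.
#'
#' @param records a [batch_records()] table
#' @param predictor predictor column name
#' @param response response column name
#' @return the `anova` table (`Df`, `Sum Sq`, `F value`, `Pr(>F)` per term)
#' @export
anova_records <- function(records, predictor = "n_scans",
                          response = "biomass") {
  tr <- factor(records$treatment)
  if (nlevels(tr) < 2) stop("need at least 2 treatment levels")
  x <- records[[predictor]]
  y <- records[[response]]
  n <- length(y)
  if (n <= nlevels(tr) + 1)
    stop("singular design: not enough records for predictor + treatment")
  fit <- lm(y ~ x + tr)
  if (fit$df.residual < 1) stop("singular design: no residual df")
  a <- anova(fit)
  rownames(a) <- c(predictor, "treatment", "Residuals")
  a
}
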