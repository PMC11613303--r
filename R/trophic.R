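## Trophic level estimation from simulated diets and the ANCOVA of the
## food-limitation deviation on trophic level by life stage.

#' Trophic levels from a diet matrix
#'
#' Flow-weighted trophic levels: `TL(x) = 1 + sum_p f_p * TL(p)` with `f_p`
#' the biomass diet fractions, solved iteratively over the predator set to a
#' fixed point. LTL prey groups carry fixed base trophic levels.
#'
#' @param diets Diet matrix as in [SimulationResult-class]: predator
#'   species x stage rows (named `"species|stage"`), prey columns (predator
#'   keys plus LTL group names), biomass eaten.
#' @param base_tl Named numeric vector of base trophic levels for the LTL
#'   group columns. Defaults to the `tl` column of the demonstration groups.
#' @param tol Fixed-point tolerance (default 1e-6).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return data.frame with `species`, `stage`, `tl` and `diet_total` (g
#'   eaten); predators with empty diets get `NA`.
#' @export
trophicLevels <- function(diets, base_tl = NULL, tol = 1e-6, max_iter = 500L) {
  pred_keys <- rownames(diets)
  prey_keys <- colnames(diets)
  if (any(diets < 0)) stop("negative diet biomass")
  ltl_cols <- setdiff(prey_keys, pred_keys)
  if (is.null(base_tl)) {
    g <- demoLTLGroups()
    base_tl <- stats::setNames(g$tl, g$name)
  }
  if (!all(ltl_cols %in% names(base_tl)))
    stop("base_tl lacks entries for: ",
         paste(setdiff(ltl_cols, names(base_tl)), collapse = ", "))

  totals <- rowSums(diets)
  frac <- diets / ifelse(totals > 0, totals, 1)

  tl_pred <- rep(3, length(pred_keys))          # any finite start works
  names(tl_pred) <- pred_keys
  tl_prey <- c(stats::setNames(rep(NA_real_, length(pred_keys)), pred_keys),
               base_tl[ltl_cols])
  for (it in seq_len(max_iter)) {
    tl_prey[pred_keys] <- tl_pred
    new_tl <- 1 + as.numeric(frac %*% tl_prey[prey_keys])
    delta <- max(abs(new_tl - tl_pred), 0)
    tl_pred <- stats::setNames(new_tl, pred_keys)
    if (delta < tol) break
    if (it == max_iter)
      stop(sprintf("trophic-level fixed point did not converge in %d iterations (delta %.2g)",
                   max_iter, delta))
  }
  parts <- strsplit(pred_keys, "|", fixed = TRUE)
  data.frame(
    species = vapply(parts, `[`, character(1), 1),
    stage = vapply(parts, `[`, character(1), 2),
    tl = unname(ifelse(totals > 0, tl_pred, NA_real_)),
    diet_total = unname(totals), row.names = NULL)
}

#' ANCOVA of the food-limitation deviation on trophic level by life stage
#'
#' Least-squares fit of `d_food` (carried internally as a fraction, reported
#' in percentage points) on trophic level with life stage as a categorical
#' factor and a stage-specific slope:
#' `100 * d_food ~ 0 + stage + stage:tl`.
#'
#' @param dev Deviation table from [deviationStats()] (needs `species`,
#'   `stage`, `d_food`).
#' @param tl Trophic level table from [trophicLevels()] (needs `species`,
#'   `stage`, `tl`).
#' @return Object of class `"ancovaFit"`: a list with `coefficients` (per
#'   stage: intercept, slope in percentage points per trophic level, and
#'   standard errors), `model` (the underlying `lm`), `data` (the merged
#'   fitting table) and `fitted_lines` (per-stage line segments spanning the
#'   observed TL range, for plotting).
#' @export
ancovaFit <- function(dev, tl) {
  d <- merge(dev[, c("species", "stage", "d_food")],
             tl[, c("species", "stage", "tl")],
             by = c("species", "stage"))
  d <- d[stats::complete.cases(d[, c("d_food", "tl")]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete (d_food, tl) pairs to fit")
  d$stage <- factor(as.character(d$stage),
                    levels = intersect(stageLabels, unique(as.character(d$stage))))
  d$d_pct <- 100 * d$d_food
  per_stage_n <- tapply(d$tl, d$stage, function(x) length(unique(x)))
  if (any(per_stage_n < 2))
    stop("rank deficiency: fewer than 2 distinct trophic levels for stage(s) ",
         paste(names(per_stage_n)[per_stage_n < 2], collapse = ", "))
  stages <- levels(d$stage)
  if (length(stages) == 1L) {
    fit <- stats::lm(d_pct ~ tl, data = d)
    cf <- stats::coef(fit)
    ## zero-residual (noise-free) fits trip summary.lm's warning
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    coefs <- data.frame(stage = stages, intercept = cf[1], slope = cf[2],
                        intercept_se = se[1], slope_se = se[2],
                        row.names = NULL)
  } else {
    fit <- stats::lm(d_pct ~ 0 + stage + stage:tl, data = d)
    cf <- stats::coef(fit)
    ## zero-residual (noise-free) fits trip summary.lm's warning
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    coefs <- data.frame(
      stage = stages,
      intercept = cf[paste0("stage", stages)],
      slope = cf[paste0("stage", stages, ":tl")],
      intercept_se = se[paste0("stage", stages)],
      slope_se = se[paste0("stage", stages, ":tl")],
      row.names = NULL)
  }
  lines <- do.call(rbind, lapply(seq_len(nrow(coefs)), function(i) {
    rng <- range(d$tl[d$stage == coefs$stage[i]])
    data.frame(stage = coefs$stage[i], tl = rng,
               d_pct = coefs$intercept[i] + coefs$slope[i] * rng)
  }))
  structure(list(coefficients = coefs, model = fit, data = d,
                 fitted_lines = lines),
            class = "ancovaFit")
}

#' @export
print.ancovaFit <- function(x, ...) {
  cat("ANCOVA of food-limitation deviation (percentage points) on trophic level\n")
  cat(sprintf("  n = %d species x stage points\n", nrow(x$data)))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

## Direct linear solve of the trophic-level system (used as an independent
## cross-check of the fixed point in the tests): TL_h = 1 + F_hh TL_h +
## F_hl TL_l  =>  (I - F_hh) TL_h = 1 + F_hl TL_l.
trophicLevelsDirect <- function(diets, base_tl) {
  pred_keys <- rownames(diets)
  ltl_cols <- setdiff(colnames(diets), pred_keys)
  totals <- rowSums(diets)
  frac <- diets / ifelse(totals > 0, totals, 1)
  f_hh <- frac[, pred_keys, drop = FALSE]
  f_hl <- frac[, ltl_cols, drop = FALSE]
  rhs <- 1 + as.numeric(f_hl %*% base_tl[ltl_cols])
  tl <- solve(diag(length(pred_keys)) - f_hh, rhs)
  unname(ifelse(totals > 0, tl, NA_real_))
}
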