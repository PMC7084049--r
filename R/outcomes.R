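#' Stiffness from a load-displacement curve
#'
#' Identifies the maximum gradient in the linear region of the curve by
#' sliding a window of `window` consecutive points and fitting an
#' ordinary-least-squares line of load on displacement in each; the
#' returned stiffness is the maximum window slope. OLS over the window is
#' used (rather than an endpoint difference) for robustness to load noise.
#'
#' @param curve data.frame with columns `displacement_mm` (monotone
#'   non-decreasing) and `load_N`.
#' @param window window length in points (default 20).
#' @return stiffness in N/mm.
#' @export
extract_stiffness <- function(curve, window = 20L) {
  d <- curve$displacement_mm; l <- curve$load_N
  n <- length(d)
  if (n < window) stop(sprintf("curve has %d points; window needs %d", n,
                               window))
  if (any(diff(d) < 0)) stop("displacement must be monotone non-decreasing")
  # running OLS slopes via cumulative sums
  cs_d <- cumsum(c(0, d)); cs_l <- cumsum(c(0, l))
  cs_dd <- cumsum(c(0, d * d)); cs_dl <- cumsum(c(0, d * l))
  i0 <- seq_len(n - window + 1L)
  i1 <- i0 + window - 1L
  sd_ <- cs_d[i1 + 1L] - cs_d[i0]
  sl <- cs_l[i1 + 1L] - cs_l[i0]
  sdd <- cs_dd[i1 + 1L] - cs_dd[i0]
  sdl <- cs_dl[i1 + 1L] - cs_dl[i0]
  denom <- window * sdd - sd_^2
  if (any(denom <= 0))
    stop("zero displacement span within a gradient window")
  max((window * sdl - sd_ * sl) / denom)
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, measuring agreement of paired values with the identity
#' line. Degenerate cases: both vectors constant and equal gives 1; both
#' constant but unequal gives 0.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return value in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least two pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(1)            # identical constants
  if (sx2 == 0 && sy2 == 0) return(0)  # distinct constants
  2 * sxy / denom
}

#' Root-mean-square percentage error
#'
#' `sqrt(mean(((pred - exp) / exp)^2)) * 100`.
#'
#' @param pred,exp equal-length vectors; `exp` strictly positive.
#' @return RMS error in percent.
#' @export
rms_percent_error <- function(pred, exp) {
  if (length(pred) != length(exp)) stop("pred and exp must have equal length")
  if (any(exp <= 0)) stop("experimental values must be positive")
  sqrt(mean(((pred - exp) / exp)^2)) * 100
}

#' Seeded even split into build and validation sets
#'
#' @param ids vector of specimen identifiers (>= 2).
#' @param seed integer seed; the split is deterministic per seed.
#' @return list with `build_ids` and `validation_ids` (sizes differ by at
#'   most one; the build set gets the extra specimen when n is odd).
#' @export
split_specimens <- function(ids, seed = 1L) {
  n <- length(ids)
  if (n < 2L) stop("need at least two specimens to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  build <- sort(sample.int(n, ceiling(n / 2)))
  list(build_ids = ids[build], validation_ids = ids[-build])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' FE specimen bundle for calibration
#'
#' Pairs the solvable ingredients of one specimen (mesh and boundary
#' conditions) with its experimentally measured stiffness.
#'
#' @param mesh a `hex_mesh`.
#' @param bcs a `bc_spec` (platen type).
#' @param experimental_stiffness measured stiffness, N/mm.
#' @param id specimen identifier.
#' @return object of class `fe_specimen`.
#' @export
fe_specimen <- function(mesh, bcs, experimental_stiffness, id = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(bcs, "bc_spec"))
  structure(list(mesh = mesh, bcs = bcs,
                 experimental_stiffness = experimental_stiffness,
                 id = id %||% "specimen"),
            class = "fe_specimen")
}

#' Calibrate the grayscale-to-modulus conversion factor
#'
#' Bounded 1-D minimisation (golden-section search) of an agreement
#' objective between FE-predicted and experimental stiffness over the
#' build-set specimens. Every objective evaluation re-solves all build
#' models at the candidate conversion factor `k`; the default objective is
#' the RMS percentage error (switchable to maximising CCC). Convergence
#' when the bracket is below `tol_rel` relative to the upper bound. If the
#' optimum sits at a bound the result is flagged (`at_boundary`).
#'
#' @param specimens list of [fe_specimen()]s (the build set).
#' @param bounds length-2 positive bounds on `k` (GPa per grayscale unit).
#' @param objective `"rms_percent"` (minimised) or `"ccc"` (maximised).
#' @param cards,floor_modulus,bone_poisson material mapping, as in
#'   [assign_materials()].
#' @param config a [solver_config()].
#' @param tol_rel relative bracket tolerance.
#' @param stiffness_fns optional list of prebuilt stiffness evaluators (one
#'   per specimen, from [make_stiffness_fn()]); lets repeated calibrations
#'   of the same models (e.g. noise-replicate studies) share assembly and
#'   memoised solves.
#' @return object of class `stiffness_calibration` with `k_star`,
#'   `objective_value`, per-specimen predictions and the evaluator
#'   functions (reused by [predict.stiffness_calibration()] and
#'   [validate()]).
#' @export
calibrate_k <- function(specimens, bounds = c(1e-4, 1e-2),
                        objective = c("rms_percent", "ccc"),
                        cards = default_material_cards(),
                        floor_modulus = 1e-6, bone_poisson = 0.3,
                        config = solver_config(), tol_rel = 1e-3,
                        stiffness_fns = NULL) {
  objective <- match.arg(objective)
  stopifnot(length(specimens) >= 1L, length(bounds) == 2L,
            bounds[1] > 0, bounds[1] < bounds[2])
  exp_s <- vapply(specimens, function(s) s$experimental_stiffness, numeric(1))
  if (any(!is.finite(exp_s)) || any(exp_s <= 0))
    stop("every build specimen needs a positive experimental stiffness")
  fns <- stiffness_fns %||% lapply(specimens, function(s)
    make_stiffness_fn(s$mesh, s$bcs, cards = cards,
                      floor_modulus = floor_modulus,
                      bone_poisson = bone_poisson, config = config))
  stopifnot(length(fns) == length(specimens))
  predict_at <- function(k) vapply(fns, function(f) f(k), numeric(1))
  obj <- function(k) {
    pred <- predict_at(k)
    val <- if (objective == "rms_percent") rms_percent_error(pred, exp_s)
           else -ccc(pred, exp_s)
    if (!is.finite(val))
      stop(sprintf("objective non-finite at candidate k = %g", k))
    val
  }

  phi <- (sqrt(5) - 1) / 2
  lo <- bounds[1]; hi <- bounds[2]
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  while ((hi - lo) > tol_rel * hi) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- obj(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- obj(x2)
    }
  }
  k_star <- if (f1 <= f2) x1 else x2
  f_star <- min(f1, f2)
  # boundary handling: an optimum pinned against a bound means the bound
  # excludes the true optimum
  at_boundary <- FALSE
  for (b in bounds) {
    fb <- obj(b)
    if (fb <= f_star) { k_star <- b; f_star <- fb; at_boundary <- TRUE }
  }
  if (!at_boundary &&
      (k_star - bounds[1] < 2 * tol_rel * bounds[2] ||
       bounds[2] - k_star < 2 * tol_rel * bounds[2])) {
    bidx <- which.min(abs(bounds - k_star))
    if (obj(bounds[bidx]) <= f_star * (1 + 1e-9)) {
      k_star <- bounds[bidx]; at_boundary <- TRUE
    }
  }
  pred <- predict_at(k_star)
  structure(list(
    k_star = k_star,
    objective = objective,
    objective_value = if (objective == "ccc") -f_star else f_star,
    at_boundary = at_boundary,
    bounds = bounds, tol_rel = tol_rel,
    build_ids = vapply(specimens, function(s) s$id, character(1)),
    predicted = pred, experimental = exp_s,
    ccc = if (length(pred) >= 2L) ccc(pred, exp_s) else NA_real_,
    rms_percent = rms_percent_error(pred, exp_s),
    cards = cards, floor_modulus = floor_modulus,
    bone_poisson = bone_poisson, config = config),
    class = "stiffness_calibration")
}

#' @export
print.stiffness_calibration <- function(x, ...) {
  cat(sprintf("Grayscale-to-modulus calibration (%d build specimens)\n",
              length(x$build_ids)))
  cat(sprintf("  k = %.6g GPa per grayscale unit%s\n", x$k_star,
              if (x$at_boundary) " (at search bound!)" else ""))
  cat(sprintf("  build-set CCC = %.3f, RMS error = %.1f%%\n",
              x$ccc, x$rms_percent))
  invisible(x)
}

#' @export
summary.stiffness_calibration <- function(object, ...) {
  print(object)
  cat("\nPer-specimen stiffness (N/mm):\n")
  print(data.frame(id = object$build_ids,
                   experimental = object$experimental,
                   predicted = object$predicted,
                   error_percent = 100 * (object$predicted -
                                            object$experimental) /
                     object$experimental))
  invisible(object)
}

#' @export
coef.stiffness_calibration <- function(object, ...) {
  c(k = object$k_star)
}

#' Predict FE stiffness for specimens at the calibrated factor
#'
#' @param object a `stiffness_calibration`.
#' @param specimens list of [fe_specimen()]s.
#' @param ... unused.
#' @return numeric vector of predicted stiffness, N/mm.
#' @export
predict.stiffness_calibration <- function(object, specimens, ...) {
  vapply(specimens, function(s) {
    fn <- make_stiffness_fn(s$mesh, s$bcs, cards = object$cards,
                            floor_modulus = object$floor_modulus,
                            bone_poisson = object$bone_poisson,
                            config = object$config)
    fn(object$k_star)
  }, numeric(1))
}

#' @export
plot.stiffness_calibration <- function(x, ...) {
  rng <- range(c(x$experimental, x$predicted))
  graphics::plot(x$experimental, x$predicted, xlim = rng, ylim = rng,
                 xlab = "experimental stiffness (N/mm)",
                 ylab = "FE-predicted stiffness (N/mm)",
                 main = sprintf("CCC = %.2f, RMS = %.1f%%", x$ccc,
                                x$rms_percent), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Agreement of predictions with experimental stiffness
#'
#' Solves the validation specimens at the calibrated conversion factor and
#' reports Lin's CCC and the RMS percentage error against their
#' experimental stiffness.
#'
#' @param calibration a `stiffness_calibration`.
#' @param specimens list of [fe_specimen()]s (validation set, >= 2 for a
#'   meaningful CCC).
#' @return object of class `agreement_report`: `ccc`, `rms_percent_error`,
#'   and the `pairs` data.frame.
#' @export
validate <- function(calibration, specimens) {
  stopifnot(inherits(calibration, "stiffness_calibration"))
  if (length(specimens) == 0L) stop("empty validation set")
  pred <- predict(calibration, specimens)
  exp_s <- vapply(specimens, function(s) s$experimental_stiffness, numeric(1))
  structure(list(
    ccc = if (length(pred) >= 2L) ccc(pred, exp_s) else NA_real_,
    rms_percent_error = rms_percent_error(pred, exp_s),
    pairs = data.frame(id = vapply(specimens, function(s) s$id, character(1)),
                       predicted = pred, experimental = exp_s)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d pairs: CCC = %.3f, RMS error = %.1f%%\n",
              nrow(x$pairs), x$ccc, x$rms_percent_error))
  invisible(x)
}

#' Write an agreement report as CSV + JSON
#'
#' @param report an `agreement_report`.
#' @param stem output path stem (writes `<stem>.csv` and `<stem>.json`).
#' @export
write_agreement_report <- function(report, stem) {
  utils::write.csv(report$pairs, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(ccc = report$ccc,
                            rms_percent_error = report$rms_percent_error),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
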