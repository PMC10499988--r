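#' Exact ligand-depletion fraction bound
#'
#' Fraction of total ligand in complex at equilibrium for a 1:1 binding
#' system, from the physical root of the mass-action quadratic:
#' `f = ((L + P + K) - sqrt((L + P + K)^2 - 4 L P)) / (2 L)`,
#' with `L` total ligand, `P` total protein and `K` the dissociation
#' constant, all in the same concentration units (conventionally µM here).
#' No excess-protein approximation is made: the assays this models run with
#' ligand concentrations comparable to the K_D, where depletion matters.
#'
#' @param l_tot Total ligand concentration (µM), > 0.
#' @param p_tot Total protein concentration (µM), >= 0.
#' @param kd Dissociation constant (µM), >= 0.
#' @return Fraction bound in `[0, 1]`; vectorised over the inputs.
#' @examples
#' fraction_bound(1, 5, 5) # ~0.475
#' @export
fraction_bound <- function(l_tot, p_tot, kd) {
  if (any(l_tot <= 0) || any(p_tot < 0) || any(kd < 0)) {
    stop("concentrations must be nonnegative and l_tot > 0", call. = FALSE)
  }
  s <- l_tot + p_tot + kd
  disc <- pmax(s^2 - 4 * l_tot * p_tot, 0)
  (s - sqrt(disc)) / (2 * l_tot)
}

# Multistart box-constrained least squares over log10(kd) plus linear
# amplitude parameters. `model(kd, p)` must return fitted signal; returns
# the best nlsLM fit and its start.
kd_multistart <- function(formula_fn, data, kd_grid, start_extra) {
  best <- NULL; best_rss <- Inf; best_kd0 <- NA_real_
  for (kd0 in kd_grid) {
    fit <- tryCatch(
      suppressWarnings(formula_fn(kd0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) {
      best <- fit; best_rss <- rss; best_kd0 <- kd0
    }
  }
  list(fit = best, rss = best_rss, kd0 = best_kd0)
}

validate_curve <- function(data) {
  stopifnot(all(c("protein_conc", "signal") %in% names(data)))
  if (any(data$protein_conc < 0)) {
    stop("protein concentrations must be nonnegative", call. = FALSE)
  }
  if (any(!is.finite(data$signal))) {
    stop("signal must be finite", call. = FALSE)
  }
  invisible(data)
}

#' Fit a fluorescence-polarization titration
#'
#' Least-squares fit of the single-site ligand-depletion model to an FP
#' titration: `r(P) = r_free + (r_bound - r_free) * f(L, P, kd)` with
#' [fraction_bound()] `f`, over parameters `kd`, `r_free`, `r_bound`. The
#' fluorophore-labelled macrocycle is the ligand at fixed total
#' concentration `l_tot`; the protein is titrated. Initialisation is a
#' deterministic 7-point logarithmic multistart for `kd` spanning
#' `[min(P)/10, max(P)*10]`; the reported fit is the start with the lowest
#' residual sum of squares.
#'
#' @param data Tibble with columns `protein_conc` (µM) and `signal`
#'   (anisotropy), one row per measured point (replicates as extra rows).
#' @param l_tot Total ligand (labelled macrocycle) concentration, µM.
#' @return A `kd_fit` object; see [tidy.kd_fit()] and [glance.kd_fit()].
#'   `$estimate` holds `kd`, `r_free`, `r_bound`; `$converged` is honest.
#'   A signal that does not respond to protein raises an
#'   unidentifiable-kd warning.
#' @export
fit_fp_curve <- function(data, l_tot) {
  validate_curve(data)
  conc <- sort(unique(data$protein_conc[data$protein_conc > 0]))
  if (length(conc) < 5L || log10(max(conc) / min(conc)) < 1.5) {
    stop("need >= 5 distinct positive concentrations spanning >= 1.5 decades",
         call. = FALSE)
  }
  rng <- diff(range(data$signal))
  if (rng <= .Machine$double.eps * max(abs(data$signal), 1)) {
    warning("unidentifiable kd: signal does not vary with protein",
            call. = FALSE)
    return(new_kd_fit(assay = "fp",
                      estimate = c(kd = NA_real_,
                                   r_free = data$signal[1],
                                   r_bound = data$signal[1]),
                      ac50 = NA_real_, l_tot = l_tot, rss = 0,
                      converged = FALSE, fit = NULL, data = data))
  }
  kd_grid <- 10^seq(log10(min(conc) / 10), log10(max(conc) * 10),
                    length.out = 7)
  r0 <- data$signal[which.min(data$protein_conc)]
  r1 <- data$signal[which.max(data$protein_conc)]
  res <- kd_multistart(function(kd0) {
    minpack.lm::nlsLM(
      signal ~ r_free + (r_bound - r_free) *
        fraction_bound(l_tot, protein_conc, kd),
      data = data,
      start = list(kd = kd0, r_free = r0, r_bound = r1),
      lower = c(kd = 1e-9, r_free = -Inf, r_bound = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, data, kd_grid, NULL)
  if (is.null(res$fit)) {
    stop("fit failure: no multistart converged (l_tot = ", l_tot,
         " uM, ", nrow(data), " points)", call. = FALSE)
  }
  co <- stats::coef(res$fit)
  new_kd_fit(assay = "fp",
             estimate = c(kd = unname(co["kd"]),
                          r_free = unname(co["r_free"]),
                          r_bound = unname(co["r_bound"])),
             ac50 = NA_real_, l_tot = l_tot, rss = res$rss,
             converged = res$fit$convInfo$isConv %||% TRUE,
             fit = res$fit, data = data)
}

#' Fit a 19F NMR signal-suppression titration
#'
#' Models binding as complete loss of the observable fluorine signal for the
#' bound fraction (slow-exchange broadening):
#' `S(P) = S0 * (1 - f(L, P, kd))` with [fraction_bound()] `f`, fitted over
#' `kd` and `S0`. Under this model the protein concentration suppressing
#' half the protein-free signal is `ac50 = kd + l_tot / 2`, which is
#' reported alongside `kd`. When the model fit fails, a model-free AC50 by
#' monotone interpolation of the signal at `S0 / 2` is reported instead.
#' A signal rising with protein beyond 5% of its range raises a
#' complex-binding warning; a flat signal is flagged as no binding
#' (`kd = Inf`).
#'
#' @param data Tibble with columns `protein_conc` (µM, must include or start
#'   near 0 to define `S0`) and `signal` (normalised 19F integral).
#' @param l_tot Total macrocycle concentration, µM. Always explicit: the
#'   assay has been run at different ligand concentrations and the AC50
#'   shifts with `l_tot / 2`.
#' @return A `kd_fit` with `$estimate["kd"]`, `$estimate["s0"]`, `$ac50`.
#' @export
fit_nmr_suppression <- function(data, l_tot) {
  validate_curve(data)
  ord <- order(data$protein_conc)
  s0_obs <- data$signal[ord][1]
  rng <- diff(range(data$signal))
  if (rng <= 1e-12 * max(abs(data$signal), 1)) {
    warning("no binding detected: signal constant", call. = FALSE)
    return(new_kd_fit(assay = "nmr",
                      estimate = c(kd = Inf, s0 = s0_obs),
                      ac50 = Inf, l_tot = l_tot, rss = 0,
                      converged = TRUE, fit = NULL, data = data))
  }
  incr <- diff(data$signal[ord])
  if (any(incr > 0.05 * rng)) {
    warning("complex binding behaviour: signal not monotone in protein",
            call. = FALSE)
  }
  conc <- sort(unique(data$protein_conc[data$protein_conc > 0]))
  kd_grid <- 10^seq(log10(min(conc) / 10), log10(max(conc) * 10),
                    length.out = 7)
  res <- kd_multistart(function(kd0) {
    minpack.lm::nlsLM(
      signal ~ s0 * (1 - fraction_bound(l_tot, protein_conc, kd)),
      data = data,
      start = list(kd = kd0, s0 = s0_obs),
      lower = c(kd = 1e-9, s0 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, data, kd_grid, NULL)
  if (is.null(res$fit)) {
    # model-free fallback: monotone interpolation at half the zero-protein
    # signal
    ac50 <- stats::approx(data$signal[ord], data$protein_conc[ord],
                          xout = s0_obs / 2, ties = mean)$y
    return(new_kd_fit(assay = "nmr",
                      estimate = c(kd = NA_real_, s0 = s0_obs),
                      ac50 = ac50, l_tot = l_tot, rss = NA_real_,
                      converged = FALSE, fit = NULL, data = data))
  }
  co <- stats::coef(res$fit)
  new_kd_fit(assay = "nmr",
             estimate = c(kd = unname(co["kd"]), s0 = unname(co["s0"])),
             ac50 = unname(co["kd"]) + l_tot / 2,
             l_tot = l_tot, rss = res$rss,
             converged = res$fit$convInfo$isConv %||% TRUE,
             fit = res$fit, data = data)
}

new_kd_fit <- function(assay, estimate, ac50, l_tot, rss, converged, fit,
                       data) {
  structure(list(assay = assay, estimate = estimate, ac50 = ac50,
                 l_tot = l_tot, rss = rss, converged = converged,
                 fit = fit, data = data),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("<kd_fit> assay = ", x$assay, ", l_tot = ", x$l_tot, " uM\n", sep = "")
  cat("  kd = ", signif(x$estimate[["kd"]], 4), " uM",
      if (!is.na(x$ac50)) paste0(", ac50 = ", signif(x$ac50, 4), " uM"),
      "\n", sep = "")
  cat("  rss = ", signif(x$rss, 4), ", converged = ", x$converged, "\n",
      sep = "")
  invisible(x)
}

#' Tidy a fitted binding curve
#'
#' @param x A `kd_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy kd_fit
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' One-row summary of a fitted binding curve
#'
#' @param x A `kd_fit`.
#' @param ... Unused.
#' @return Tibble with `assay`, `kd`, `ac50`, `l_tot`, `rss`, `converged`,
#'   `n_points`.
#' @method glance kd_fit
#' @export
glance.kd_fit <- function(x, ...) {
  tibble::tibble(assay = x$assay, kd = x$estimate[["kd"]], ac50 = x$ac50,
                 l_tot = x$l_tot, rss = x$rss, converged = x$converged,
                 n_points = nrow(x$data))
}

#' @method autoplot kd_fit
#' @export
autoplot.kd_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(protein_conc = 10^seq(
    log10(max(min(d$protein_conc[d$protein_conc > 0]) / 2, 1e-4)),
    log10(max(d$protein_conc) * 2), length.out = 200))
  kd <- object$estimate[["kd"]]
  grid$signal <- if (object$assay == "fp") {
    object$estimate[["r_free"]] +
      (object$estimate[["r_bound"]] - object$estimate[["r_free"]]) *
      fraction_bound(object$l_tot, grid$protein_conc, kd)
  } else {
    object$estimate[["s0"]] *
      (1 - fraction_bound(object$l_tot, grid$protein_conc, kd))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$protein_conc, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (uM)",
                  y = if (object$assay == "fp") "anisotropy"
                      else "normalised 19F signal") +
    ggplot2::theme_minimal()
}

#' Read a titration TSV
#'
#' Expected columns: `protein_conc_uM`, `signal`, optional `replicate`.
#'
#' @param path TSV path.
#' @return Tibble with `protein_conc`, `signal`, `replicate`.
#' @export
read_titration <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("protein_conc_uM", "signal") %in% names(df)))
  tibble::tibble(protein_conc = df$protein_conc_uM, signal = df$signal,
                 replicate = if ("replicate" %in% names(df)) df$replicate
                             else 1L)
}

#' Binding free-energy change from a K_D ratio
#'
#' Alanine-scan energetics: `ddG = R T ln(kd_mut / kd_wt)` in kcal/mol, with
#' `R = 1.987e-3 kcal/(mol K)` and `T` in kelvin (default 298.15 K). A
#' mutant that binds 10-fold weaker at 298.15 K costs about 1.364 kcal/mol.
#'
#' @param kd_mut,kd_wt Dissociation constants (same units), > 0.
#' @param temperature Temperature in kelvin.
#' @return ddG in kcal/mol; vectorised.
#' @examples
#' ddg_from_kd(50, 5) # 10-fold loss, ~1.364 kcal/mol
#' @export
ddg_from_kd <- function(kd_mut, kd_wt, temperature = 298.15) {
  if (any(kd_mut <= 0) || any(kd_wt <= 0)) {
    stop("dissociation constants must be positive", call. = FALSE)
  }
  R_KCAL <- 1.987e-3
  R_KCAL * temperature * log(kd_mut / kd_wt)
}

#' Correlate experimental and computed ddG values
#'
#' Pearson correlation and ordinary least-squares line of computed
#' (`ddg_fep`) against experimental (`ddg_exp`) binding free-energy changes,
#' as used to compare alanine-scan energetics measured by titration with
#' free-energy-perturbation predictions supplied as numbers.
#'
#' @param records Tibble with columns `ddg_exp` and `ddg_fep` (>= 3 rows),
#'   e.g. one row per alanine mutant.
#' @return One-row tibble: `r`, `slope`, `intercept`, `n`.
#' @export
correlate_ddg <- function(records) {
  stopifnot(all(c("ddg_exp", "ddg_fep") %in% names(records)))
  if (nrow(records) < 3L) stop("need >= 3 records", call. = FALSE)
  if (stats::sd(records$ddg_exp) == 0 || stats::sd(records$ddg_fep) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  fit <- stats::lm(ddg_fep ~ ddg_exp, data = records)
  tibble::tibble(r = stats::cor(records$ddg_exp, records$ddg_fep),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = nrow(records))
}
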