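# 1:1 Langmuir SPR kinetics: closed-form sensorgram model, simulation, and
# global (shared-parameter) nonlinear least-squares fitting.

# closed-form 1:1 Langmuir response at times t (s) for analyte concentration
# C (M): association to t_assoc, then exponential dissociation
langmuir_response <- function(t, conc, ka, kd, rmax, t_assoc) {
  KD <- kd / ka
  req <- rmax * conc / (conc + KD)
  kobs <- ka * conc + kd
  r_assoc <- req * (1 - exp(-kobs * pmin(t, t_assoc)))
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc, r_assoc, r_end * exp(-kd * (t - t_assoc)))
}

#' Simulate a 1:1 Langmuir sensorgram series
#'
#' Association follows R(t) = Req (1 - exp(-(ka C + kd) t)) with
#' Req = Rmax C / (C + KD); dissociation decays exponentially at rate kd from
#' the association end point. Gaussian noise of standard deviation
#' `noise_sd` RU is added; a 0 M concentration produces a pure-noise blank.
#'
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param rmax saturation response, RU.
#' @param conc analyte concentrations, M (may include 0 for the blank).
#' @param t_assoc association time, s (default 120).
#' @param t_dissoc dissociation time, s (default 1360).
#' @param dt sampling interval, s (default 2).
#' @param noise_sd Gaussian noise SD, RU.
#' @param seed RNG seed (NULL to use the current stream).
#' @return list of sensorgrams; each is a data.frame `time_s`,
#'   `response_RU`, `concentration_M`, `phase`, with attribute `t_assoc`.
#' @export
simulate_sensorgram <- function(ka, kd, rmax, conc,
                                t_assoc = 120, t_dissoc = 1360, dt = 2,
                                noise_sd = 0, seed = NULL) {
  if (ka <= 0 || kd <= 0 || rmax <= 0) {
    stop_ab("rate constants and Rmax must be positive", "ablineage_domain_error")
  }
  if (noise_sd < 0) {
    stop_ab("noise_sd must be non-negative", "ablineage_domain_error")
  }
  with_seed(seed, {
    t <- seq(0, t_assoc + t_dissoc, by = dt)
    lapply(conc, function(C) {
      r <- if (C > 0) langmuir_response(t, C, ka, kd, rmax, t_assoc) else 0 * t
      r <- r + stats::rnorm(length(t), 0, noise_sd)
      out <- data.frame(time_s = t, response_RU = r, concentration_M = C,
                        phase = ifelse(t <= t_assoc, "association",
                                       "dissociation"))
      attr(out, "t_assoc") <- t_assoc
      out
    })
  })
}

#' Globally fit a 1:1 Langmuir model to a sensorgram series
#'
#' Shared ka, kd and Rmax are estimated across all non-blank curves by
#' Levenberg-Marquardt least squares on log-scale parameters, with a fixed
#' 3x3 log-spaced multi-start grid over (ka, kd) for deterministic
#' convergence. A 0 M blank curve, when present, is subtracted point-wise
#' from every other curve before fitting. KD is stored as kd/ka exactly.
#'
#' @param curves list of sensorgram data.frames as produced by
#'   [simulate_sensorgram()] (columns `time_s`, `response_RU`,
#'   `concentration_M`; attribute or column-derivable association end).
#' @param t_assoc association end time, s; taken from the curves' attribute
#'   when NULL.
#' @param starts_ka,starts_kd multi-start grids (log-spaced defaults).
#' @return object of class `kinetic_fit`: `ka`, `kd`, `rmax`, `KD`,
#'   `rms` (residual RMS, RU), `rel_ci` (approximate 95% relative
#'   half-widths per parameter), `flags` (e.g. `kd_poorly_constrained`),
#'   `n_curves`, `convergence`.
#' @export
fit_1to1 <- function(curves, t_assoc = NULL,
                     starts_ka = c(1e4, 1e5, 1e6),
                     starts_kd = c(1e-5, 1e-4, 1e-3)) {
  conc <- vapply(curves, function(x) x$concentration_M[1], numeric(1))
  if (is.null(t_assoc)) {
    t_assoc <- attr(curves[[1]], "t_assoc") %||%
      max(curves[[1]]$time_s[curves[[1]]$phase == "association"])
  }
  blank <- which(conc == 0)
  if (length(blank) > 0L) {
    b <- curves[[blank[1]]]$response_RU
    curves <- lapply(curves[-blank], function(x) {
      x$response_RU <- x$response_RU - b
      x
    })
    conc <- conc[-blank]
  }
  if (length(curves) < 2L) {
    stop_ab("global fit needs at least two non-blank concentrations",
            "ablineage_usage_error")
  }
  tt <- lapply(curves, `[[`, "time_s")
  rr <- lapply(curves, `[[`, "response_RU")
  resid_fn <- function(p) {
    ka <- exp(p[1]); kd <- exp(p[2]); rmax <- exp(p[3])
    unlist(lapply(seq_along(curves), function(i) {
      rr[[i]] - langmuir_response(tt[[i]], conc[i], ka, kd, rmax, t_assoc)
    }))
  }
  rmax0 <- max(1e-6, max(vapply(rr, max, numeric(1))) * 1.2)
  best <- NULL
  for (ka0 in starts_ka) for (kd0 in starts_kd) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(c(ka0, kd0, rmax0)), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    stop_ab("1:1 Langmuir fit failed to converge from every start",
            "ablineage_fit_error")
  }
  fit <- best$fit
  p <- fit$par
  ka <- exp(p[1]); kd <- exp(p[2]); rmax <- exp(p[3])
  n <- length(fit$fvec)
  dof <- max(1L, n - 3L)
  sigma2 <- best$sse / dof
  rel_ci <- rep(NA_real_, 3)
  cov_ok <- tryCatch({
    cv <- sigma2 * solve(fit$hessian)
    # log-scale sd -> approximate relative 95% half-width
    rel_ci <- exp(1.96 * sqrt(pmax(diag(cv), 0))) - 1
    TRUE
  }, error = function(e) FALSE)
  flags <- character(0)
  if (cov_ok) {
    nm <- c("ka", "kd", "rmax")
    poor <- nm[rel_ci > 0.5]
    if (length(poor)) flags <- paste0(poor, "_poorly_constrained")
  } else {
    flags <- "covariance_singular"
  }
  names(rel_ci) <- c("ka", "kd", "rmax")
  structure(list(ka = ka, kd = kd, rmax = rmax, KD = kd / ka,
                 rms = sqrt(mean(fit$fvec^2)), rel_ci = rel_ci,
                 flags = flags, n_curves = length(curves),
                 convergence = fit$info),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> ka %.3g 1/(M s), kd %.3g 1/s, Rmax %.3g RU, KD %.3g M (RMS %.3g RU)\n",
    x$ka, x$kd, x$rmax, x$KD, x$rms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fold change between two positive quantities
#'
#' @param numerator,denominator positive scalars.
#' @param rounding `"none"`, `"integer"`, or `"1dp"`; rounding is
#'   half-away-from-zero.
#' @return the (optionally rounded) ratio.
#' @examples
#' fold_change(8.5, 0.32, "integer")  # 27
#' @export
fold_change <- function(numerator, denominator,
                        rounding = c("none", "integer", "1dp")) {
  rounding <- match.arg(rounding)
  if (!is.finite(denominator) || denominator <= 0) {
    stop_ab("fold change denominator must be positive", "ablineage_domain_error")
  }
  r <- numerator / denominator
  switch(rounding,
         none = r,
         integer = round_half_away(r, 0),
         `1dp` = round_half_away(r, 1))
}

#' Summarize kinetic results in rate-constant table form
#'
#' Accepts either a named list of `kinetic_fit` objects or a data.frame of
#' reported values with columns `variant`, `ka_1e5` (1/(M s) x 1e5),
#' `kd_1e4` (1/s x 1e-4) and optionally `KD_nM` (M x 1e-9). The table
#' reports ka, kd on those scales, the KD computed as kd/ka in nM, and --
#' when a reported KD is available -- the internal-consistency measure
#' |KD_reported - kd/ka| / KD_reported with a flag above `tol`.
#'
#' @param fits named list of `kinetic_fit`s, or a reported-value data.frame.
#' @param tol relative inconsistency tolerated before flagging (default 0.1).
#' @return data.frame with columns `variant`, `ka_1e5`, `kd_1e4`,
#'   `KD_nM_calc`, `KD_nM_reported`, `consistency`, `flag`.
#' @export
summarize_kinetics <- function(fits, tol = 0.1) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("variant", "ka_1e5", "kd_1e4") %in% names(fits)))
    ka <- fits$ka_1e5 * 1e5
    kd <- fits$kd_1e4 * 1e-4
    variant <- fits$variant
    kd_rep <- if ("KD_nM" %in% names(fits)) fits$KD_nM else rep(NA_real_, nrow(fits))
  } else {
    variant <- names(fits) %||% as.character(seq_along(fits))
    ka <- vapply(fits, `[[`, numeric(1), "ka")
    kd <- vapply(fits, `[[`, numeric(1), "kd")
    kd_rep <- rep(NA_real_, length(fits))
  }
  kd_calc <- kd / ka * 1e9
  consistency <- ifelse(is.na(kd_rep), NA_real_,
                        abs(kd_rep - kd_calc) / kd_rep)
  data.frame(variant = variant,
             ka_1e5 = ka / 1e5,
             kd_1e4 = kd * 1e4,
             KD_nM_calc = kd_calc,
             KD_nM_reported = kd_rep,
             consistency = consistency,
             flag = !is.na(consistency) & consistency > tol,
             stringsAsFactors = FALSE)
}

#' Published rate-constant table for the 212579 variant panel
#'
#' Reads the packaged reported kinetics of antibody 212579, its inferred
#' UCA and the other panel variants (ka x 1e5 1/(M s), kd x 1e-4 1/s,
#' KD x 1e-9 M, as published).
#'
#' @return data.frame with columns `variant`, `ka_1e5`, `kd_1e4`, `KD_nM`.
#' @export
kinetics_table_212579 <- function() {
  utils::read.csv(system.file("extdata", "kinetics_212579.csv",
                              package = "ablineage"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write sensorgrams to CSV
#'
#' One row per sample point, columns `time_s`, `response_RU`,
#' `concentration_M`, `phase`, `curve`.
#'
#' @param curves list of sensorgram data.frames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cbind(curves[[i]], curve = i)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read sensorgrams from CSV written by [write_sensorgram_csv()]
#' @param path CSV path.
#' @return list of sensorgram data.frames.
#' @export
read_sensorgram_csv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(rows, rows$curve), function(x) {
    out <- x[, c("time_s", "response_RU", "concentration_M", "phase")]
    attr(out, "t_assoc") <- max(out$time_s[out$phase == "association"])
    rownames(out) <- NULL
    out
  })
}
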