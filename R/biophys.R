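# Thermostability (first-derivative Tm from dual-channel fluorescence melt
# curves), hydrodynamic radius (Taylor dispersion + Stokes-Einstein), and
# exact Mann-Whitney comparison of small variant groups.

KBOLTZ <- 1.380649e-23  # J/K

#' Dynamic viscosity of water
#'
#' Vogel-type empirical fit; reproduces the package defaults 8.9e-4 Pa s at
#' 25 C and 6.9e-4 Pa s at 37 C.
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return viscosity in Pa s.
#' @export
viscosity_water <- function(temperature_C) {
  2.414e-5 * 10^(247.8 / (temperature_C + 273.15 - 140))
}

#' Simulate a two-state thermal unfolding curve
#'
#' Unfolded fraction follows the van't Hoff two-state model
#' f_u(T) = 1 / (1 + exp(dH/R (1/T - 1/Tm))) (temperatures in kelvin), so
#' f_u(Tm) = 1/2 exactly. Each fluorescence channel mixes linear native and
#' unfolded baselines by f_u; multiplicative Gaussian noise emulates
#' detector noise.
#'
#' @param tm melting temperature, degrees C (inside the scan range).
#' @param dH_kJ van't Hoff enthalpy, kJ/mol (default 400).
#' @param baselines list of `c(intercept, slope_per_C)` pairs named
#'   `n330`, `u330`, `n350`, `u350` (intercepts at 25 C); defaults give a
#'   ratio rising on unfolding as for tryptophan fluorescence.
#' @param t_min,t_max scan range, degrees C (default 25--95).
#' @param step temperature sampling step, degrees C (default 0.1, i.e. 6 s
#'   sampling at the 1 C/min scan rate).
#' @param noise relative (multiplicative) noise SD per channel (default 0).
#' @param seed RNG seed.
#' @param replicate replicate identifier stored on the curve.
#' @return data.frame of class `melt_curve` with columns `temperature_C`,
#'   `f330`, `f350` and attribute `replicate`.
#' @export
simulate_melt_curve <- function(tm, dH_kJ = 400, baselines = NULL,
                                t_min = 25, t_max = 95, step = 0.1,
                                noise = 0, seed = NULL, replicate = 1L) {
  if (tm <= t_min || tm >= t_max) {
    stop_ab("Tm must lie inside the scan range", "ablineage_domain_error")
  }
  if (is.null(baselines)) {
    baselines <- list(n330 = c(1.00, -5e-4), u330 = c(0.95, -5e-4),
                      n350 = c(0.70, -3e-4), u350 = c(0.95, -3e-4))
  }
  with_seed(seed, {
    temp <- seq(t_min, t_max, by = step)
    TK <- temp + 273.15
    TmK <- tm + 273.15
    R <- 8.314462618
    fu <- 1 / (1 + exp(dH_kJ * 1000 / R * (1 / TK - 1 / TmK)))
    line <- function(b) b[1] + b[2] * (temp - 25)
    f330 <- line(baselines$n330) * (1 - fu) + line(baselines$u330) * fu
    f350 <- line(baselines$n350) * (1 - fu) + line(baselines$u350) * fu
    if (noise > 0) {
      f330 <- f330 * (1 + stats::rnorm(length(temp), 0, noise))
      f350 <- f350 * (1 + stats::rnorm(length(temp), 0, noise))
    }
    out <- data.frame(temperature_C = temp, f330 = f330, f350 = f350)
    attr(out, "replicate") <- replicate
    class(out) <- c("melt_curve", "data.frame")
    out
  })
}

# unfolded fraction of the two-state model (exposed for tests of the
# midpoint identity)
#' @rdname simulate_melt_curve
#' @param temperature_C temperatures (degrees C) at which to evaluate the
#'   unfolded fraction.
#' @export
unfolded_fraction <- function(temperature_C, tm, dH_kJ = 400) {
  R <- 8.314462618
  1 / (1 + exp(dH_kJ * 1000 / R *
                 (1 / (temperature_C + 273.15) - 1 / (tm + 273.15))))
}

#' Extract melting temperatures from the first derivative of melt curves
#'
#' Computes the fluorescence ratio 350/330 nm, estimates its first
#' derivative with a Savitzky-Golay (moving polynomial) differentiation
#' filter, and locates the melting temperature as the interior derivative
#' maximum refined by a quadratic fit over a neighborhood of the grid peak
#' (plain 3-point interpolation is too sensitive to detector noise at 0.1 C
#' sampling). Curves without a pronounced interior transition raise an
#' extraction error.
#'
#' @param curves one `melt_curve` or a list of replicate curves.
#' @param window Savitzky-Golay window, points (odd, default 51, i.e.
#'   5.1 C at 0.1 C sampling).
#' @param order Savitzky-Golay polynomial order (default 2).
#' @param peak_halfwidth half-width, in points, of the quadratic-fit
#'   neighborhood around the derivative maximum (default 15).
#' @return object of class `tm_result`: `tm` (degrees C per replicate),
#'   `mean_tm`, `sd_tm`.
#' @export
tm_from_first_derivative <- function(curves, window = 51L, order = 2L,
                                     peak_halfwidth = 15L) {
  if (is.data.frame(curves)) curves <- list(curves)
  tms <- vapply(curves, function(curve) {
    n <- nrow(curve)
    if (n < 50L) {
      stop_ab("melt curve has fewer than 50 points", "ablineage_usage_error")
    }
    temp <- curve$temperature_C
    step <- temp[2] - temp[1]
    r <- curve$f350 / curve$f330
    d <- signal::sgolayfilt(r, p = order, n = window, m = 1, ts = step)
    lo <- window %/% 2 + 1L; hi <- n - window %/% 2
    interior <- lo:hi
    i <- interior[which.max(d[interior])]
    prominence <- max(d[interior]) - stats::median(d[interior])
    scale <- stats::mad(d[interior], na.rm = TRUE)
    if (i <= lo || i >= hi || !(prominence > 5 * scale + 1e-9)) {
      stop_ab("no interior unfolding transition found in melt curve",
              "ablineage_extraction_error")
    }
    idx <- max(lo, i - peak_halfwidth):min(hi, i + peak_halfwidth)
    cf <- stats::coef(stats::lm(d[idx] ~ stats::poly(temp[idx], 2, raw = TRUE)))
    tm <- if (is.na(cf[3]) || cf[3] >= 0) temp[i] else -cf[2] / (2 * cf[3])
    if (tm < min(temp) || tm > max(temp)) {
      stop_ab("interpolated Tm outside the scan range",
              "ablineage_extraction_error")
    }
    tm
  }, numeric(1))
  structure(list(tm = tms, mean_tm = mean(tms),
                 sd_tm = if (length(tms) > 1L) stats::sd(tms) else NA_real_),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> mean Tm %.2f C (SD %.2f, n=%d)\n",
              x$mean_tm, x$sd_tm, length(x$tm)))
  invisible(x)
}

#' Simulate a taylorgram
#'
#' Taylor dispersion of a pulse through a capillary produces a Gaussian
#' concentration profile at the detector with temporal variance
#' sigma^2 = r_c^2 t_R / (24 D), where D follows from the hydrodynamic
#' radius by Stokes-Einstein (D = kB T / (6 pi eta R_h)). Multiple species
#' superimpose Gaussians of shared residence time.
#'
#' @param rh_nm hydrodynamic radius (nm); a vector simulates a mixture.
#' @param fractions amplitude fractions per species (default equal/one).
#' @param temperature_C run temperature, degrees C.
#' @param viscosity solvent viscosity, Pa s (default water at
#'   `temperature_C`).
#' @param rc capillary radius, m (default 37.5e-6).
#' @param t_r residence time, s (default 200).
#' @param amplitude total peak amplitude, AU.
#' @param noise additive Gaussian noise SD, AU.
#' @param dt sampling interval, s (default 0.5).
#' @param t_max trace duration, s (default 400).
#' @param seed RNG seed.
#' @return object of class `taylorgram`: `data` (data.frame `time_s`,
#'   `signal`), `rc`, `t_r`, `temperature_C`, `viscosity`.
#' @export
simulate_taylorgram <- function(rh_nm, fractions = NULL, temperature_C = 25,
                                viscosity = NULL, rc = 37.5e-6, t_r = 200,
                                amplitude = 1, noise = 0, dt = 0.5,
                                t_max = 400, seed = NULL) {
  if (any(rh_nm <= 0) || rc <= 0 || t_r <= 0) {
    stop_ab("radius, capillary radius and residence time must be positive",
            "ablineage_domain_error")
  }
  if (is.null(viscosity)) viscosity <- viscosity_water(temperature_C)
  if (is.null(fractions)) fractions <- rep(1 / length(rh_nm), length(rh_nm))
  stopifnot(length(fractions) == length(rh_nm))
  fractions <- fractions / sum(fractions)
  TK <- temperature_C + 273.15
  with_seed(seed, {
    t <- seq(0, t_max, by = dt)
    signal <- 0 * t
    for (i in seq_along(rh_nm)) {
      D <- KBOLTZ * TK / (6 * pi * viscosity * rh_nm[i] * 1e-9)
      s2 <- rc^2 * t_r / (24 * D)
      signal <- signal + amplitude * fractions[i] *
        exp(-(t - t_r)^2 / (2 * s2))
    }
    if (noise > 0) signal <- signal + stats::rnorm(length(t), 0, noise)
    structure(list(data = data.frame(time_s = t, signal = signal),
                   rc = rc, t_r = t_r, temperature_C = temperature_C,
                   viscosity = viscosity),
              class = "taylorgram")
  })
}

#' @export
print.taylorgram <- function(x, ...) {
  cat(sprintf("<taylorgram> %d points at %.0f C (rc %.1f um, tR %.0f s)\n",
              nrow(x$data), x$temperature_C, x$rc * 1e6, x$t_r))
  invisible(x)
}

gaussian1 <- function(t, A, t0, s2, base) A * exp(-(t - t0)^2 / (2 * s2)) + base

#' Hydrodynamic radius from a taylorgram
#'
#' Fits a Gaussian to the dispersion peak; the fitted residence time t_R and
#' temporal variance sigma^2 give the diffusion coefficient
#' D = r_c^2 t_R / (24 sigma^2) and R_h = kB T / (6 pi eta D).
#' Polydispersity is detected from the structured part of the
#' single-species residuals (a 21-point moving average suppresses white
#' detector noise but retains model misfit); when its RMS relative to the
#' peak amplitude exceeds `dual_threshold`, a dual-species model (two
#' Gaussians sharing the residence time) is fitted and the sample flagged.
#'
#' @param tg a `taylorgram`.
#' @param dual_threshold relative smoothed-residual RMS above which the
#'   dual-species model is tried (default 0.0012).
#' @return object of class `rh_result`: `rh` (nm, dominant species),
#'   `rh_species` (nm per fitted species), `n_species`, `dispersity`
#'   (logical), `rms`.
#' @export
rh_from_taylorgram <- function(tg, dual_threshold = 0.0012) {
  stopifnot(inherits(tg, "taylorgram"))
  t <- tg$data$time_s; y <- tg$data$signal
  base0 <- stats::median(c(utils::head(y, 10), utils::tail(y, 10)))
  yb <- pmax(y - base0, 0)
  if (sum(yb) <= 0) {
    stop_ab("taylorgram has no peak above baseline", "ablineage_extraction_error")
  }
  t0_0 <- sum(t * yb) / sum(yb)
  s2_0 <- max(sum((t - t0_0)^2 * yb) / sum(yb), 1e-6)
  A0 <- max(yb)
  fit1 <- tryCatch(
    minpack.lm::nls.lm(
      par = c(log(A0), t0_0, log(s2_0), base0),
      fn = function(p) y - gaussian1(t, exp(p[1]), p[2], exp(p[3]), p[4]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit1)) {
    stop_ab("taylorgram peak fit did not converge", "ablineage_extraction_error")
  }
  rms1 <- sqrt(mean(fit1$fvec^2))
  A1 <- exp(fit1$par[1])
  smooth_res <- stats::filter(fit1$fvec, rep(1 / 21, 21), sides = 2)
  structured <- sqrt(mean(smooth_res^2, na.rm = TRUE)) / A1
  TK <- tg$temperature_C + 273.15
  rh_of <- function(t0, s2) {
    D <- tg$rc^2 * t0 / (24 * s2)
    KBOLTZ * TK / (6 * pi * tg$viscosity * D) * 1e9
  }
  if (structured <= dual_threshold) {
    return(structure(list(
      rh = rh_of(fit1$par[2], exp(fit1$par[3])),
      rh_species = rh_of(fit1$par[2], exp(fit1$par[3])),
      n_species = 1L, dispersity = FALSE, rms = rms1),
      class = "rh_result"))
  }
  # dual-species model: shared residence time, two variances
  fit2 <- tryCatch(
    minpack.lm::nls.lm(
      par = c(log(0.7 * A1), log(0.3 * A1), fit1$par[2],
              fit1$par[3] - 0.7, fit1$par[3] + 0.7, fit1$par[4]),
      fn = function(p) {
        y - (exp(p[1]) * exp(-(t - p[3])^2 / (2 * exp(p[4]))) +
               exp(p[2]) * exp(-(t - p[3])^2 / (2 * exp(p[5]))) + p[6])
      },
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (is.null(fit2) || sqrt(mean(fit2$fvec^2)) >= rms1) {
    # dual fit no better; keep single-species but flag dispersity
    return(structure(list(
      rh = rh_of(fit1$par[2], exp(fit1$par[3])),
      rh_species = rh_of(fit1$par[2], exp(fit1$par[3])),
      n_species = 1L, dispersity = TRUE, rms = rms1),
      class = "rh_result"))
  }
  amps <- exp(fit2$par[1:2])
  rhs <- rh_of(fit2$par[3], exp(fit2$par[4:5]))
  ord <- order(amps, decreasing = TRUE)
  structure(list(rh = rhs[ord][1], rh_species = rhs[ord],
                 amplitudes = amps[ord] / sum(amps),
                 n_species = 2L, dispersity = TRUE,
                 rms = sqrt(mean(fit2$fvec^2))),
            class = "rh_result")
}

#' @export
print.rh_result <- function(x, ...) {
  cat(sprintf("<rh_result> Rh %.2f nm (%d species%s)\n", x$rh, x$n_species,
              if (x$dispersity) ", polydisperse" else ""))
  invisible(x)
}

#' Exact Mann-Whitney U test for two small groups
#'
#' U counts, over all pairs, how often a value of the first group exceeds a
#' value of the second (ties credit 0.5). The two-sided p-value is exact:
#' the rank-sum distribution over all choose(n_a+n_b, n_a) group labelings
#' is enumerated (via a subset-sum recursion over midranks, identical to
#' full enumeration), and p = min(1, 2 min(P(U <= u), P(U >= u))).
#'
#' @param a,b numeric vectors, each of 1--12 values.
#' @return list of class `mw_result`: `U` (first group), `U_other`
#'   (second group; `U + U_other = n_a n_b`), `p` (exact two-sided).
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_exact <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop_ab("both groups must be non-empty", "ablineage_usage_error")
  }
  if (length(a) > 12L || length(b) > 12L) {
    stop_ab("exact enumeration supports at most 12 values per group",
            "ablineage_usage_error")
  }
  na <- length(a); nb <- length(b)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(a, b)
  d <- as.integer(round(2 * rank(pool)))  # doubled midranks (integers)
  # distribution of the doubled rank-sum of a size-na subset
  total <- sum(d)
  f <- matrix(0, nrow = na + 1L, ncol = total + 1L)  # [k+1, s+1]
  f[1L, 1L] <- 1
  for (x in d) {
    for (k in na:1) {
      shifted <- c(rep(0, x), f[k, seq_len(total + 1L - x)])
      f[k + 1L, ] <- f[k + 1L, ] + shifted
    }
  }
  dist <- f[na + 1L, ]
  counts <- dist[dist > 0]
  sums <- which(dist > 0) - 1L
  s_obs <- as.integer(round(2 * (U + na * (na + 1) / 2)))
  n_total <- choose(na + nb, na)
  p_le <- sum(counts[sums <= s_obs]) / n_total
  p_ge <- sum(counts[sums >= s_obs]) / n_total
  structure(list(U = U, U_other = na * nb - U,
                 p = min(1, 2 * min(p_le, p_ge)),
                 n_a = na, n_b = nb),
            class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("<mw_result> U = %g (n=%d,%d), exact two-sided p = %.4g\n",
              x$U, x$n_a, x$n_b, x$p))
  invisible(x)
}

#' Mean and sample SD per group
#'
#' Arithmetic mean and n-1 sample standard deviation per group, rounded to
#' two decimals (half away from zero) for table reporting. Singleton groups
#' are an error (their SD is undefined).
#'
#' @param values numeric vector.
#' @param groups grouping vector aligned with `values`.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- do.call(rbind, lapply(split(values, groups), function(v) {
    if (length(v) < 2L) {
      stop_ab("singleton group: sample SD undefined", "ablineage_usage_error")
    }
    data.frame(n = length(v),
               mean = round_half_away(mean(v), 2),
               sd = round_half_away(stats::sd(v), 2))
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Residue-40 identity of 212579 panel variants
#'
#' Variants whose name carries the `T40_H_N` reversion (or the full UCA
#' reversion set) have asparagine at heavy-chain position 40; all others
#' retain the mature threonine.
#'
#' @param variant character vector of panel variant names.
#' @return character vector `"N40"`/`"T40"`.
#' @export
residue40_group <- function(variant) {
  ifelse(grepl("T40_H_N", variant) | variant %in% c("UCA", "uca"),
         "N40", "T40")
}

#' Published Tm / hydrodynamic-radius table for the 212579 panel
#'
#' Reads the packaged reported thermostability and Taylor-dispersion results
#' of the 212579 panel (mean +/- SD over triplicates; `NA` where a value was
#' not determined).
#'
#' @return data.frame with columns `variant`, `tm_mean`, `tm_sd`,
#'   `rh25_mean`, `rh25_sd`, `rh37_mean`, `rh37_sd`.
#' @export
biophys_table_212579 <- function() {
  utils::read.csv(system.file("extdata", "biophys_212579.csv",
                              package = "ablineage"),
                  stringsAsFactors = FALSE)
}
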