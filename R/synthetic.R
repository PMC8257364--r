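#' Define a group profile for the synthetic generator
#'
#' A profile holds, for one diagnostic group, the per-feature mean, standard
#' deviation, admissible range and integrality flag used by
#' [generate_cohort()].
#'
#' @param label Group label, 0 (control) or 1 (MCI).
#' @param n Group size.
#' @param features Named list with one entry per feature, each a list with
#'   elements `mean`, `sd`, `min`, `max`, `integer`.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(label, n, features) {
  stopifnot(label %in% c(0L, 1L), n >= 1, is.list(features))
  for (f in names(features)) {
    p <- features[[f]]
    if (p$min > p$max) stop("min > max for feature ", f, call. = FALSE)
    if (p$mean < p$min || p$mean > p$max) {
      stop("mean outside range for feature ", f, call. = FALSE)
    }
    if (p$sd < 0) stop("negative sd for feature ", f, call. = FALSE)
    if (p$sd > 0 && p$min == p$max) {
      stop("infeasible profile: zero-width range with sd > 0 for feature ", f,
           call. = FALSE)
    }
  }
  structure(list(label = as.integer(label), n = as.integer(n),
                 features = features), class = "group_profile")
}

feat <- function(mean, sd, min, max, integer = TRUE) {
  list(mean = mean, sd = sd, min = min, max = max, integer = integer)
}

#' Reference cohort specification
#'
#' Returns the specification of the default synthetic cohort: 203 controls
#' and 128 MCI subjects whose per-group feature means, standard deviations
#' and ranges match the characteristics of the ADNI-derived sample the
#' screening system was developed on (e.g. control MMSE 29.1 (1.2) in
#' 24--30, MCI FAQ 3.6 (4.4) in 0--20). Features are drawn independently
#' within group; no inter-feature correlation is modelled.
#'
#' @param seed Integer seed stored in the spec; [generate_cohort()] is
#'   deterministic given it.
#' @param scale_n Multiplier applied to both group sizes (e.g. 20 for a
#'   20-fold cohort in moment checks).
#' @return An object of class `cohort_spec` with elements `control`, `mci`
#'   and `seed`.
#' @export
adni_like_spec <- function(seed = 1L, scale_n = 1) {
  stopifnot(scale_n > 0)
  control <- group_profile(0L, max(1L, as.integer(round(203 * scale_n))), list(
    age  = feat(74.1, 6.3, 56.3, 89.1, integer = FALSE),
    yoe  = feat(16.5, 2.6, 10, 20),
    mmse = feat(29.1, 1.2, 24, 30),
    faq  = feat(0.2, 0.6, 0, 5),
    gds  = feat(0.8, 1.2, 0, 6)
  ))
  mci <- group_profile(1L, max(1L, as.integer(round(128 * scale_n))), list(
    age  = feat(74.9, 7.2, 56.3, 88.0, integer = FALSE),
    yoe  = feat(15.5, 3.2, 4, 20),
    mmse = feat(27.2, 1.7, 24, 30),
    faq  = feat(3.6, 4.4, 0, 20),
    gds  = feat(1.6, 1.5, 0, 5)
  ))
  structure(list(control = control, mci = mci, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Expected value of a normal(mu, sd) truncated to [lo, hi], optionally
# discretized to the integers of the range (rounding after truncation,
# boundary cells clamped).
truncated_mean <- function(mu, sd, lo, hi, integer) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z <= 0) return(if (a > 0) lo else hi)
  if (!integer) {
    return(mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z)
  }
  k <- seq(ceiling(lo), floor(hi))
  upper <- pmin(k + 0.5, hi)
  lower <- pmax(k - 0.5, lo)
  p <- (stats::pnorm((upper - mu) / sd) - stats::pnorm((lower - mu) / sd)) / Z
  sum(k * p)
}

# Location calibration: choose the parent normal's mean so that the
# realized post-truncation (and post-rounding) expectation equals the
# profile mean. The profile sd is used for the parent normal as-is, so the
# realized spread is attenuated wherever the range clips hard.
calibrate_mu <- function(target, sd, lo, hi, integer) {
  if (sd == 0) return(target)
  f <- function(mu) truncated_mean(mu, sd, lo, hi, integer) - target
  span <- 10 * sd + (hi - lo)
  stats::uniroot(f, lower = lo - span, upper = hi + span, tol = 1e-9)$root
}

# Truncated-normal draws by rejection from the untruncated normal.
# Integer rounding (when requested by the caller) happens after truncation.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("infeasible profile: rejection sampling failed for mean ", mean,
           " sd ", sd, " range [", lo, ", ", hi, "]", call. = FALSE)
    }
    x <- rnorm(max(n - length(out), 16L) * 2L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

generate_group <- function(profile, id_prefix) {
  cols <- lapply(cpn_features(), function(f) {
    p <- profile$features[[f]]
    mu <- calibrate_mu(p$mean, p$sd, p$min, p$max, isTRUE(p$integer))
    v <- rtrunc_norm(profile$n, mu, p$sd, p$min, p$max)
    if (isTRUE(p$integer)) round(v) else round(v, 1)
  })
  names(cols) <- cpn_features()
  df <- as.data.frame(cols)
  df$subject_id <- sprintf("%s%04d", id_prefix, seq_len(profile$n))
  df$label <- profile$label
  df
}

#' Generate a synthetic cohort
#'
#' Draws each feature from a truncated normal confined to the profile's
#' range, with integer features rounded after truncation (ages are
#' recorded at 0.1-year resolution). The parent normal's location is
#' calibrated so the realized mean after truncation and rounding equals
#' the profile mean; its spread is the profile sd, so the realized sd is
#' attenuated for features whose range clips hard (e.g. FAQ near 0).
#' Controls precede MCI subjects in the output. Deterministic given
#' `spec$seed`.
#'
#' @param spec A `cohort_spec`, e.g. from [adni_like_spec()].
#' @return A [cohort()] with provenance `"synthetic"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  df <- rbind(generate_group(spec$control, "C"),
              generate_group(spec$mci, "M"))
  cohort(df, provenance = "synthetic")
}
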