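#' Generate a synthetic EPSC amplitude series around a plasticity induction
#'
#' Sweeps at fixed intervals hold a stationary baseline amplitude before the
#' induction event and `baseline_mean * post_ratio` after it, plus Gaussian
#' sweep noise. The baseline window spans the 8 min before induction and the
#' post window 30-40 min after it, matching how depo-pairing LTP magnitude
#' is quantified.
#'
#' @param baseline_mean Baseline EPSC amplitude, pA.
#' @param post_ratio Post/baseline amplitude ratio (2.18 emulates robust
#'   wild-type LTP; 0.93 its absence).
#' @param noise_sd Sweep-to-sweep noise, pA.
#' @param seed Integer seed.
#' @param sweep_interval Seconds between sweeps (0.1 Hz default).
#' @param t_pre,t_post Recorded time before/after induction, s.
#' @return A `sweep_series` tibble (`time_s`, `amplitude_pa`) with
#'   `event_time`, `baseline_window`, `post_window` attributes.
#' @examples
#' s <- generate_ltp_series(100, 2.18, noise_sd = 0, seed = 1)
#' normalize_timecourse(s)$ltp_percent
#' @export
generate_ltp_series <- function(baseline_mean = 100, post_ratio = 2.18,
                                noise_sd = 5, seed = 1L,
                                sweep_interval = 10, t_pre = 600,
                                t_post = 2400) {
  stopifnot_positive(baseline_mean = baseline_mean,
                     sweep_interval = sweep_interval,
                     t_pre = t_pre, t_post = t_post)
  if (post_ratio < 0 || noise_sd < 0)
    abort("`post_ratio` and `noise_sd` must be >= 0",
          class = "spinemorph_parameter_error")
  t <- seq(-t_pre, t_post, by = sweep_interval)
  mu <- ifelse(t <= 0, baseline_mean, baseline_mean * post_ratio)
  amp <- with_seed(seed, mu + rnorm(length(t), 0, noise_sd))
  amp <- pmax(amp, 0)
  out <- tibble::tibble(time_s = t, amplitude_pa = amp)
  attr(out, "event_time") <- 0
  attr(out, "baseline_window") <- c(-480, 0)
  attr(out, "post_window") <- c(1800, 2400)
  class(out) <- c("sweep_series", class(out))
  out
}

#' Generate synthetic exploration trials
#'
#' Object-displacement trials draw per-subject novel/familiar exploration
#' times from gamma distributions sharing a scale, so the expected
#' displacement index equals the group's preference parameter exactly
#' (the index is then Beta-distributed). Y-maze trials distribute total
#' exploration across three arms the same way.
#'
#' @param group_effects Named list: one entry per group, each a list with
#'   `preference` (expected novel fraction, 0-1) and optionally
#'   `total_time` (mean total exploration, s; default 60) and
#'   `concentration` (gamma shape total; default 20 — larger means less
#'   between-subject spread).
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @param task `"object"` (novel/familiar times) or `"ymaze"` (three arm
#'   times: novel, start, other).
#' @return An exploration tibble with one row per subject.
#' @examples
#' generate_behavior_trials(list(wt = list(preference = 0.682)), 5, seed = 1)
#' @export
generate_behavior_trials <- function(group_effects, n_per_group, seed = 1L,
                                     task = c("object", "ymaze")) {
  task <- match.arg(task)
  if (n_per_group < 1) abort("`n_per_group` must be >= 1",
                             class = "spinemorph_parameter_error")
  with_seed(seed, purrr::imap_dfr(group_effects, function(eff, grp) {
    p <- eff$preference
    if (is.null(p) || p < 0 || p > 1)
      abort("each group needs a `preference` in [0, 1]",
            class = "spinemorph_parameter_error")
    total <- eff$total_time %||% 60
    k <- eff$concentration %||% 20
    scale <- total / k
    if (task == "object") {
      t_nov <- rgamma(n_per_group, shape = k * p, scale = scale)
      t_fam <- rgamma(n_per_group, shape = k * (1 - p), scale = scale)
      tibble::tibble(subject = paste0(grp, "_", seq_len(n_per_group)),
                     group = grp, condition = task,
                     t_novel = t_nov, t_familiar = t_fam)
    } else {
      q <- (1 - p) / 2
      t_nov <- rgamma(n_per_group, shape = k * p, scale = scale)
      t_start <- rgamma(n_per_group, shape = k * q, scale = scale)
      t_other <- rgamma(n_per_group, shape = k * q, scale = scale)
      tibble::tibble(subject = paste0(grp, "_", seq_len(n_per_group)),
                     group = grp, condition = task,
                     t_novel = t_nov, t_start = t_start, t_other = t_other)
    }
  }))
}

#' Generate synthetic binding assay points
#'
#' Duplicate total and non-specific binding measurements per animal with
#' lognormal assay noise around a group-specific density.
#'
#' @param density_fmol_mg Expected specific binding, fmol per mg protein.
#' @param n_animals Animals (assay points, each in duplicate).
#' @param protein_mg Protein per assay point, mg.
#' @param nonspecific_frac Non-specific binding as a fraction of total.
#' @param cv Assay coefficient of variation.
#' @param seed Integer seed.
#' @return Tibble with duplicate rows per animal: `id`, `total`,
#'   `nonspecific` (fmol), `protein` (mg).
#' @export
generate_binding_points <- function(density_fmol_mg = 38, n_animals = 6,
                                    protein_mg = 0.010,
                                    nonspecific_frac = 0.2, cv = 0.1,
                                    seed = 1L) {
  stopifnot_positive(density_fmol_mg = density_fmol_mg,
                     protein_mg = protein_mg)
  with_seed(seed, {
    specific <- density_fmol_mg * protein_mg
    nonspec <- specific * nonspecific_frac / (1 - nonspecific_frac)
    n <- n_animals * 2L
    noise <- function(mu) mu * exp(rnorm(n, -cv^2 / 2, cv))
    tibble::tibble(id = rep(seq_len(n_animals), each = 2L),
                   total = noise(specific + nonspec),
                   nonspecific = noise(nonspec),
                   protein = protein_mg)
  })
}
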