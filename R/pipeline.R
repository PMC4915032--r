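#' Configuration for a full synthetic experiment
#'
#' Bundles every stage's parameters with a single top-level seed that is
#' fanned out to per-stage child seeds, so a rerun with the same
#' configuration is reproducible end to end.
#'
#' @param seed Integer master seed.
#' @param groups Named list of [morph_params()]; the first group is the
#'   reference for the KS comparisons.
#' @param n_spines_per_group Target spines per group.
#' @param dendrite_length Length of each simulated dendritic branch, um.
#' @param imaging An [imaging_config()].
#' @param morphometry A [morph_options()].
#' @param D Diffusion coefficient for the tau column, um^2/s.
#' @param alpha Significance level for the group tests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            groups = list(wt = morph_params("wt"),
                                          appps1 = morph_params("appps1")),
                            n_spines_per_group = 250L,
                            dendrite_length = 20,
                            imaging = imaging_config(),
                            morphometry = morph_options(),
                            D = 0.45, alpha = 0.05) {
  if (length(groups) < 2 || is.null(names(groups)))
    abort("`groups` must be a named list of at least two morph_params",
          class = "spinemorph_parameter_error")
  stopifnot_positive(dendrite_length = dendrite_length, D = D)
  structure(list(seed = as.integer(seed), groups = groups,
                 n_spines_per_group = as.integer(n_spines_per_group),
                 dendrite_length = dendrite_length, imaging = imaging,
                 morphometry = morphometry, D = D, alpha = alpha),
            class = "pipeline_config")
}

#' Run the full synthetic experiment
#'
#' For every group: sample spine populations branch by branch (branch spine
#' counts are Poisson around the group density), render each branch as a
#' STED-like stack, measure every annotated spine on the maximum-intensity
#' projection, and compute per-spine compartmentalization. Then compare the
#' groups against the first (reference) group: a two-sample KS test and a
#' normality-gated two-group test per morphological variable, plus the
#' per-branch spine density.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return A `spinemorph_experiment`: list with `ground_truth`,
#'   `morphometry` (measured, with `V`, `A`, `cf`, `tau`), `density`
#'   (per branch), `stats` (tidy test table), `config`.
#' @export
run_full_synthetic_experiment <- function(config = pipeline_config(),
                                          quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  groups <- names(config$groups)
  gt_all <- list()
  meas_all <- list()
  dens_all <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    params <- config$groups[[gi]]
    target <- config$n_spines_per_group
    expected <- params$spine_density * config$dendrite_length / 10
    total <- 0L
    b <- 0L
    while (total < target) {
      b <- b + 1L
      sd_b <- child_seed(config$seed, gi * 1000L + b)
      n_b <- with_seed(sd_b, max(1L, stats::rpois(1, expected)))
      ann <- sample_spine_population(params, n_b, config$dendrite_length,
                                     seed = sd_b + 1L)
      ann$spine_id <- paste0(g, "_b", b, "_", seq_len(n_b))
      stack <- render_stack(ann, config$imaging, seed = sd_b + 2L)
      meas <- measure_spines(stack, ann, config$morphometry)
      meas$spine_id <- ann$spine_id
      meas$branch <- b
      ann$branch <- b
      gt_all[[length(gt_all) + 1L]] <- ann
      meas_all[[length(meas_all) + 1L]] <- meas
      dens_all[[length(dens_all) + 1L]] <- tibble::tibble(
        group = g, branch = b, n_spines = n_b,
        dendrite_length = config$dendrite_length,
        density = spine_density(n_b, config$dendrite_length))
      total <- total + n_b
    }
    say("group %s: %d spines across %d branches", g, total, b)
  }
  gt <- dplyr::bind_rows(lapply(gt_all, function(a) {
    a$path <- NULL
    a
  }))
  meas <- add_compartmentalization(dplyr::bind_rows(meas_all), D = config$D)
  dens <- dplyr::bind_rows(dens_all)

  ref <- groups[1]
  vars <- c("spine_length", "head_width", "neck_length", "neck_width", "cf")
  stats_rows <- list()
  for (g in setdiff(groups, ref)) {
    for (v in vars) {
      a <- meas[[v]][meas$group == ref & is.finite(meas[[v]])]
      bvals <- meas[[v]][meas$group == g & is.finite(meas[[v]])]
      ks <- ks_two_sample(a, bvals, alpha = config$alpha)
      gt2 <- compare_two_groups(a, bvals, alpha = config$alpha)
      stats_rows[[length(stats_rows) + 1L]] <-
        dplyr::bind_rows(ks, gt2) |>
        dplyr::mutate(variable = v, group = g, reference = ref,
                      .before = 1)
    }
    da <- dens$density[dens$group == ref]
    db <- dens$density[dens$group == g]
    dens_tests <- ks_two_sample(da, db, alpha = config$alpha)
    if (length(da) >= 2 && length(db) >= 2)
      dens_tests <- dplyr::bind_rows(
        dens_tests, compare_two_groups(da, db, alpha = config$alpha))
    stats_rows[[length(stats_rows) + 1L]] <- dens_tests |>
      dplyr::mutate(variable = "density", group = g, reference = ref,
                    .before = 1)
  }
  structure(list(ground_truth = gt, morphometry = meas, density = dens,
                 stats = dplyr::bind_rows(stats_rows), config = config),
            class = "spinemorph_experiment")
}

#' @export
print.spinemorph_experiment <- function(x, ...) {
  cat("<spinemorph_experiment>\n")
  cat(sprintf("  %d spines measured in %d groups (%d branches)\n",
              nrow(x$morphometry), length(unique(x$morphometry$group)),
              nrow(x$density)))
  ks <- x$stats[x$stats$test_name == "ks_two_sample", ]
  for (i in seq_len(nrow(ks)))
    cat(sprintf("  KS %-12s vs %s: D = %.3f, p = %.4g%s\n", ks$variable[i],
                ks$group[i], ks$statistic[i], ks$p_value[i],
                ifelse(ks$significant[i], " *", "")))
  invisible(x)
}

#' @export
tidy.spinemorph_experiment <- function(x, ...) x$stats

#' @export
glance.spinemorph_experiment <- function(x, ...) {
  x$morphometry |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(c("spine_length", "head_width",
                                     "neck_length", "neck_width", "cf"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Cumulative-distribution panels for a synthetic experiment
#'
#' @param object A `spinemorph_experiment`.
#' @param ... Ignored.
#' @return A ggplot of per-variable ECDFs by group.
#' @export
autoplot.spinemorph_experiment <- function(object, ...) {
  long <- object$morphometry |>
    dplyr::select("group", "spine_length", "head_width", "neck_length",
                  "neck_width", "cf") |>
    tidyr::pivot_longer(-"group", names_to = "variable")
  ggplot2::ggplot(long[is.finite(long$value), ],
                  ggplot2::aes(.data$value, colour = .data$group)) +
    ggplot2::stat_ecdf(pad = FALSE) +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "cumulative fraction")
}
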