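#' Validate a titration dataset
#'
#' A titration dataset is a long-format data frame with one row per replicate
#' plate: columns `mutant_fraction` (in `[0, 1]`), `replicate` (identifier),
#' `count` (nonnegative integer plaque count) and `scale` (positive effective
#' volume/dilution factor; expected counts are `A0 * scale * A(p)`).
#'
#' @param data A data frame in the titration layout.
#' @param require_control Must the dataset contain at least one
#'   `mutant_fraction == 0` row? Required whenever the baseline amplitude `A0`
#'   is to be estimated from the data.
#'
#' @return `data` as a tibble, invisibly validated.
#' @export
validate_titration <- function(data, require_control = TRUE) {
  needed <- c("mutant_fraction", "count", "scale")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "titration data lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- as_tibble(data)
  check_fraction(data$mutant_fraction, "mutant_fraction")
  if (anyNA(data$count) || any(data$count < 0) ||
      any(data$count != round(data$count))) {
    abort("`count` must be nonnegative integers (plaque counts).")
  }
  if (anyNA(data$scale) || any(data$scale <= 0)) {
    abort("`scale` must be positive.")
  }
  if (require_control && !any(data$mutant_fraction == 0)) {
    abort(paste(
      "titration data must include a mutant_fraction = 0 control row;",
      "the baseline amplitude A0 is unidentifiable without one."
    ))
  }
  data
}

#' Poisson log-likelihood of a titration dataset under a ring model
#'
#' Each replicate count is modelled as Poisson with mean
#' `A0 * scale * (A(p) + epsilon)`, where `A(p)` is the model's relative
#' activity and `epsilon` an optional background rate. With `epsilon = 0`,
#' rows at `A(p) = 0` contribute 0 to the log-likelihood for a zero count and
#' `-Inf` for a positive count (an impossible outcome under the model).
#'
#' @param data Titration data (see [validate_titration()]); a control row is
#'   not required here because `A0` is supplied explicitly.
#' @param model A [ring_model()].
#' @param A0 Baseline expected count at `p = 0` per unit scale; positive.
#' @param rule A [dimer_rule()] (dimer-seeded mode only).
#' @param epsilon Background activity rate added to `A(p)`; default 0.
#'
#' @return The log-likelihood (may be `-Inf`).
#' @export
titration_loglik <- function(data, model, A0, rule = dimer_rule(),
                             epsilon = 0) {
  if (!is.numeric(A0) || length(A0) != 1L || is.na(A0) || A0 <= 0) {
    abort("`A0` must be a single positive number.")
  }
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  data <- validate_titration(data, require_control = FALSE)
  a <- relative_activity(data$mutant_fraction, model, rule)
  mu <- A0 * data$scale * (a + epsilon)
  sum(dpois(data$count, lambda = mu, log = TRUE))
}

#' Profile (closed-form) maximum-likelihood baseline amplitude
#'
#' For fixed ring model the Poisson MLE of the baseline amplitude is
#' `A0_hat = sum(counts) / sum(scale * (A(p) + epsilon))` over rows with
#' positive expected activity.
#'
#' @inheritParams titration_loglik
#' @return The MLE `A0_hat` (positive real, or 0 if all counts are 0).
#' @export
profile_A0 <- function(data, model, rule = dimer_rule(), epsilon = 0) {
  data <- validate_titration(data, require_control = FALSE)
  a <- relative_activity(data$mutant_fraction, model, rule) + epsilon
  keep <- a > 0
  denom <- sum(data$scale[keep] * a[keep])
  if (denom == 0) {
    abort("no rows with positive expected activity; A0 is unidentifiable.")
  }
  sum(data$count[keep]) / denom
}

fit_grid <- function(data, z_range, modes, rule, epsilon, k_penalty,
                     structural_penalty) {
  cells <- tidyr::expand_grid(mode = modes, z = z_range) |>
    # dimer-seeded assembly is undefined for a single-subunit ring
    filter(!(.data$mode == "dimer_seeded" & .data$z < 2)) |>
    mutate(K = purrr::map(.data$z, seq_len)) |>
    tidyr::unnest("K")
  res <- purrr::pmap(
    list(cells$z, cells$K, cells$mode),
    function(z, K, mode) {
      model <- ring_model(z, K, mode)
      A0 <- tryCatch(
        suppressWarnings(profile_A0(data, model, rule, epsilon)),
        error = function(e) NA_real_
      )
      if (is.na(A0) || A0 <= 0) {
        return(list(A0 = NA_real_, loglik = -Inf))
      }
      ll <- suppressWarnings(titration_loglik(data, model, A0, rule, epsilon))
      list(A0 = A0, loglik = ll)
    }
  )
  cells |>
    mutate(
      A0 = map_dbl(res, "A0"),
      loglik = map_dbl(res, "loglik"),
      aic = -2 * .data$loglik + 2 * k_penalty +
        structural_penalty * (.data$z + .data$K)
    )
}

#' Fit ring stoichiometry by exhaustive maximum likelihood
#'
#' Fits the subunit-poisoning model to titration data by exhaustive search
#' over the integer grid z in `z_range`, K in `1..z`, assembly mode in
#' `modes`. Each cell's baseline amplitude `A0` is maximised in closed form
#' ([profile_A0()]); cells are ranked by AIC (which, with a constant number of
#' free parameters per cell, orders cells by maximized log-likelihood plus any
#' configured structural penalty). Ties break deterministically: smallest `z`,
#' then smallest `K`, then random mode before dimer-seeded.
#'
#' @param data Titration data with at least one `mutant_fraction = 0` control
#'   row (see [validate_titration()]).
#' @param z_range Integer vector of candidate subunit counts; default `1:12`
#'   (the widest ring plausible for this motor — the connector itself has 12
#'   subunits).
#' @param modes Character vector of assembly modes to search.
#' @param rule A [dimer_rule()] used by dimer-seeded cells.
#' @param epsilon Background rate; default 0.
#' @param k_penalty Effective free-parameter count per cell for the AIC;
#'   default 2. Constant across cells, so it never changes the winner.
#' @param structural_penalty Optional AIC penalty per unit of `z + K`
#'   (an integer-complexity guard); default 0.
#'
#' @return An object of class `ring_fit` with elements `z_hat`, `K_hat`,
#'   `mode_hat`, `A0_hat`, `loglik`, `aic`, `grid` (the full per-cell table)
#'   and `data`. Methods: [tidy()], [glance()], [autoplot()], `print`.
#' @export
#' @examples
#' d <- simulate_titration(titration_design(seed = 1))
#' fit <- fit_stoichiometry(d, modes = "random")
#' glance(fit)
fit_stoichiometry <- function(data, z_range = 1:12,
                              modes = c("random", "dimer_seeded"),
                              rule = dimer_rule(), epsilon = 0,
                              k_penalty = 2, structural_penalty = 0) {
  data <- validate_titration(data, require_control = TRUE)
  if (any(z_range < 1) || any(z_range != round(z_range))) {
    abort("`z_range` must be positive integers.")
  }
  modes <- match.arg(modes, c("random", "dimer_seeded"), several.ok = TRUE)
  grid <- fit_grid(data, z_range, modes, rule, epsilon, k_penalty,
                   structural_penalty)
  if (nrow(grid) == 0 || all(!is.finite(grid$loglik))) {
    abort("no model in the grid has finite likelihood for these data.")
  }
  best <- grid |>
    mutate(mode_rank = match(.data$mode, c("random", "dimer_seeded"))) |>
    arrange(.data$aic, .data$z, .data$K, .data$mode_rank) |>
    slice(1)
  structure(
    list(
      z_hat = best$z, K_hat = best$K, mode_hat = best$mode,
      A0_hat = best$A0, loglik = best$loglik, aic = best$aic,
      grid = select(grid, "mode", "z", "K", "A0", "loglik", "aic"),
      data = data,
      settings = list(
        z_range = z_range, modes = modes, rule = rule, epsilon = epsilon,
        k_penalty = k_penalty, structural_penalty = structural_penalty
      )
    ),
    class = "ring_fit"
  )
}

#' @export
print.ring_fit <- function(x, ...) {
  cat("<ring_fit> subunit-poisoning maximum-likelihood fit\n")
  cat(sprintf(
    "  selected: z = %d, K = %d, %s assembly\n",
    x$z_hat, x$K_hat, gsub("_", "-", x$mode_hat)
  ))
  cat(sprintf("  A0 = %.3f counts/unit scale, logLik = %.3f, AIC = %.3f\n",
              x$A0_hat, x$loglik, x$aic))
  cat(sprintf("  grid: %d candidate models\n", nrow(x$grid)))
  invisible(x)
}

#' @describeIn fit_stoichiometry Per-cell grid table: one row per candidate
#'   `(mode, z, K)` with its profiled `A0`, log-likelihood and AIC.
#' @param x,object A `ring_fit`.
#' @param ... Unused.
#' @method tidy ring_fit
#' @export
tidy.ring_fit <- function(x, ...) {
  arrange(x$grid, .data$aic)
}

#' @describeIn fit_stoichiometry One-row summary of the selected model.
#' @method glance ring_fit
#' @export
glance.ring_fit <- function(x, ...) {
  tibble(
    z_hat = x$z_hat, K_hat = x$K_hat, mode_hat = x$mode_hat,
    A0_hat = x$A0_hat, loglik = x$loglik, aic = x$aic,
    n_obs = nrow(x$data), n_models = nrow(x$grid)
  )
}

#' @describeIn fit_stoichiometry Observed relative activity (counts normalised
#'   by the fitted `A0 * scale`) overlaid on the selected model's activity
#'   curve.
#' @method autoplot ring_fit
#' @export
autoplot.ring_fit <- function(object, ...) {
  model <- ring_model(object$z_hat, object$K_hat, object$mode_hat)
  curve <- activity_curve(model, seq(0, 1, length.out = 101),
                          object$settings$rule)
  obs <- object$data |>
    mutate(relative = .data$count / (object$A0_hat * .data$scale))
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = .data$p, y = .data$activity),
      colour = "steelblue"
    ) +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$mutant_fraction, y = .data$relative),
      alpha = 0.6
    ) +
    ggplot2::labs(
      x = "mutant fraction p",
      y = "relative activity",
      title = sprintf(
        "Fitted ring model: z = %d, K = %d (%s assembly)",
        object$z_hat, object$K_hat, gsub("_", "-", object$mode_hat)
      )
    )
}

#' Bootstrap confidence intervals for the fitted stoichiometry
#'
#' Case-resampling bootstrap over titration levels (p-rows): the nonzero
#' mutant-fraction levels are resampled with replacement while every control
#' (`p = 0`) level is always retained, respecting the titration design and
#' keeping `A0` identifiable in every replicate. Each replicate dataset is
#' refit and percentile intervals are reported for `z_hat` and `K_hat`.
#'
#' @param data Titration data (see [validate_titration()]).
#' @param n_boot Number of bootstrap replicates (`>= 1`).
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @param level Confidence level; default 0.95.
#' @param ... Passed on to [fit_stoichiometry()].
#'
#' @return A list of class `ring_boot`: `ci` (tibble with percentile bounds
#'   for `z_hat` and `K_hat`), `draws` (per-replicate estimates), `n_boot`,
#'   `seed`.
#' @export
bootstrap_ci <- function(data, n_boot = 200, seed = 1, level = 0.95, ...) {
  if (!is.numeric(n_boot) || length(n_boot) != 1 || n_boot < 1) {
    abort("`n_boot` must be an integer >= 1.")
  }
  data <- validate_titration(data, require_control = TRUE)
  levels_all <- sort(unique(data$mutant_fraction))
  levels_free <- levels_all[levels_all > 0]
  rows_by_level <- split(seq_len(nrow(data)), data$mutant_fraction)
  control_rows <- unlist(rows_by_level[as.character(0)], use.names = FALSE)
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      picked <- if (length(levels_free) > 0) {
        sample(as.character(levels_free), length(levels_free), replace = TRUE)
      } else {
        character()
      }
      idx <- c(control_rows, unlist(rows_by_level[picked], use.names = FALSE))
      fit <- fit_stoichiometry(data[idx, , drop = FALSE], ...)
      tibble(replicate = b, z_hat = fit$z_hat, K_hat = fit$K_hat,
             mode_hat = fit$mode_hat)
    })
  }) |> bind_rows()
  alpha <- (1 - level) / 2
  pct <- function(x) quantile(x, c(alpha, 1 - alpha), type = 1, names = FALSE)
  ci <- tibble(
    parameter = c("z_hat", "K_hat"),
    lower = c(pct(draws$z_hat)[1], pct(draws$K_hat)[1]),
    upper = c(pct(draws$z_hat)[2], pct(draws$K_hat)[2]),
    level = level
  )
  structure(
    list(ci = ci, draws = draws, n_boot = n_boot, seed = seed),
    class = "ring_boot"
  )
}

#' @export
print.ring_boot <- function(x, ...) {
  cat(sprintf("<ring_boot> %d bootstrap replicates (seed %d)\n",
              x$n_boot, x$seed))
  print(x$ci)
  invisible(x)
}

#' @rdname bootstrap_ci
#' @param x A `ring_boot`.
#' @method tidy ring_boot
#' @export
tidy.ring_boot <- function(x, ...) x$ci
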