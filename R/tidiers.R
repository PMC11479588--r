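#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Q10 fit
#'
#' @param x A `"q10_fit"` object.
#' @param ... Unused.
#' @return One row per model quantity (`f_ref`, `q10`) with estimates and
#'   standard errors on the natural (exponentiated) scale via the delta
#'   method.
#' @export
tidy.q10_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  est <- exp(co[, "Estimate"])
  se <- est * co[, "Std. Error"]
  tibble::tibble(
    term = c("f_ref", "q10"),
    estimate = unname(est),
    std.error = unname(se)
  )
}

#' @rdname tidy.q10_fit
#' @export
glance.q10_fit <- function(x, ...) {
  tibble::tibble(
    q10 = x$q10, f_ref = x$f_ref, t_ref = x$t_ref,
    residual_sd = x$residual_sd, n = x$n
  )
}

#' Tidy a phase slope fit
#'
#' @param x A `"phase_slope"` object.
#' @param ... Unused.
#' @return One-row tibble with the slope (per degC and per 10 degC),
#'   intercept and number of temperatures.
#' @export
tidy.phase_slope <- function(x, ...) {
  tibble::tibble(
    event = x$event,
    slope_per_c = x$slope_per_c,
    slope_per_10c = x$slope_per_10c,
    intercept = x$intercept,
    n_temps = x$n_temps
  )
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `"rm_anova"` object.
#' @param ... Unused.
#' @return `tidy()`: the pairwise Tukey HSD table; `glance()`: the omnibus
#'   F, df and p.
#' @export
tidy.rm_anova <- function(x, ...) x$pairwise

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(f = x$f, df1 = x$df1, df2 = x$df2, p = x$p,
                 epsilon = x$epsilon, n_subjects = x$n_subjects)
}

#' Tidy an Ih percent-block result
#'
#' @param x An `"ih_block"` object.
#' @param ... Unused.
#' @return `tidy()`: per-cell reductions; `glance()`: group mean, SD, n.
#' @export
tidy.ih_block <- function(x, ...) x$per_cell

#' @rdname tidy.ih_block
#' @export
glance.ih_block <- function(x, ...) {
  tibble::tibble(mean_pct = x$mean_pct, sd_pct = x$sd_pct, n = x$n)
}
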