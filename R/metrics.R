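# Error metrics used for all software-vs-hardware and
# prediction-vs-target comparisons.

check_pair <- function(reference, test) {
  if (length(reference) == 0) stop("metrics: empty sequences")
  if (length(reference) != length(test)) {
    stop("metrics: sequences of unequal length (", length(reference),
         " vs ", length(test), ")")
  }
}

#' Root-mean-square error
#' @param reference,test paired numeric sequences of equal length.
#' @return `sqrt(mean((reference - test)^2))`.
#' @export
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 4)) # 1/sqrt(3)
rmse <- function(reference, test) {
  check_pair(reference, test)
  sqrt(mean((reference - test)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return `mean(abs(reference - test))`.
#' @export
mae <- function(reference, test) {
  check_pair(reference, test)
  mean(abs(reference - test))
}

#' R-square of a test sequence against a reference
#'
#' `1 - sum((reference - test)^2) / sum((mean(reference) - reference)^2)`;
#' the reference plays the software/ground-truth role and must not be
#' constant.
#'
#' @inheritParams rmse
#' @return R-square (at most 1; can be negative).
#' @export
r_squared <- function(reference, test) {
  check_pair(reference, test)
  ss_ref <- sum((mean(reference) - reference)^2)
  if (ss_ref == 0) stop("r_squared: reference sequence is constant")
  1 - sum((reference - test)^2) / ss_ref
}

#' Compare the hardware and reference paths of a component
#'
#' Runs the floating-point reference and the fixed-point/PWL hardware
#' emulation of one component on identical inputs and reports RMSE, MAE
#' and R-square.
#'
#' Components:
#' \describe{
#'   \item{`pwl_sigmoid`}{five-segment PWL sigmoid vs the exact sigmoid on
#'     a uniform grid (default \[-8, 8\], step 0.01, spanning all
#'     breakpoints and the clipping onset).}
#'   \item{`pwl_deriv`}{six-segment PWL derivative vs the exact
#'     `sigma'` on the same grid.}
#'   \item{`shift_mul`}{shift-add products vs exact products on random
#'     pairs `a ~ U(0, 1)`, `b ~ U(-8, 8)`.}
#'   \item{`mlif_trace`}{somatic voltage of one hidden MLIF neuron
#'     simulated for 200 ms on an identical random input raster under both
#'     backends.}
#' }
#'
#' @param component one of the names above.
#' @param probe optional list overriding the probe defaults: `grid_range`,
#'   `grid_step` (PWL components), `n` (shift_mul), `n_steps`, `n_in`,
#'   `rates_hz` (mlif_trace).
#' @param seed RNG seed for random probes.
#' @return a one-row data.frame (`metric_report`) with `component`,
#'   `rmse`, `mae`, `r2`, `n`.
#' @export
#' @examples
#' compare_backends("pwl_sigmoid")$rmse # about 0.011
compare_backends <- function(component = c("pwl_sigmoid", "pwl_deriv",
                                           "shift_mul", "mlif_trace"),
                             probe = list(), seed = 1) {
  component <- match.arg(component)
  pr <- modifyList(list(grid_range = c(-8, 8), grid_step = 0.01,
                        n = 1e4, n_steps = 200, n_in = 8,
                        rates_hz = NULL), probe)
  if (component %in% c("pwl_sigmoid", "pwl_deriv")) {
    V <- seq(pr$grid_range[1], pr$grid_range[2], by = pr$grid_step)
    if (component == "pwl_sigmoid") {
      ref <- plogis(V)
      test <- pwl_eval(pwl_sigmoid5(), V, backend = "hw")
    } else {
      ref <- plogis(V) * (1 - plogis(V))
      test <- pwl_eval(pwl_dsigmoid6(), V, backend = "hw")
    }
  } else if (component == "shift_mul") {
    set.seed(seed)
    a <- runif(pr$n); b <- runif(pr$n, -8, 8)
    ref <- a * b
    test <- shift_mul(a, b)
  } else {
    set.seed(seed)
    rates <- if (is.null(pr$rates_hz)) runif(pr$n_in, 20, 200) else
      pr$rates_hz
    raster <- matrix(
      as.integer(runif(pr$n_steps * pr$n_in) <
                   rep(rates / 1000, each = pr$n_steps)),
      nrow = pr$n_steps)
    w <- runif(pr$n_in, -0.1, 0.1)
    ref <- simulate_hidden_neuron(raster, w, 0, backend = "float")$V
    test <- simulate_hidden_neuron(raster, w, 0, backend = "hw")$V
  }
  structure(data.frame(component = component,
                       rmse = rmse(ref, test), mae = mae(ref, test),
                       r2 = r_squared(ref, test), n = length(ref)),
            class = c("metric_report", "data.frame"))
}

#' Error table of both PWL approximations
#'
#' Convenience wrapper evaluating the PWL sigmoid and PWL derivative
#' against their exact counterparts on the default grid.
#'
#' @param grid_range,grid_step evaluation grid.
#' @return data.frame with one row per function.
#' @export
pwl_error_table <- function(grid_range = c(-8, 8), grid_step = 0.01) {
  probe <- list(grid_range = grid_range, grid_step = grid_step)
  rbind(compare_backends("pwl_sigmoid", probe),
        compare_backends("pwl_deriv", probe))
}
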