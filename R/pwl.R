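# Piecewise-linear approximations of the sigmoid and its derivative.
# The hardware evaluates sigma(V) as a small set of segments m_i*V + k_i
# whose slopes are exact powers of two, so each slope multiplication is a
# single truncating shift.

#' Piecewise-linear function specification
#'
#' A PWL function is an ordered list of line segments `m_i * V + k_i` over
#' domains split by strictly increasing borders `N_i`: the first segment
#' covers `V <= N_1`, interior segments `N_{i-1} < V <= N_i`, and the last
#' `V > N_last`. The output is clipped to `[clip_low, clip_high]`.
#'
#' @param slopes,intercepts numeric vectors of equal length (one per segment).
#' @param borders strictly increasing numeric vector, one shorter than
#'   `slopes`.
#' @param clip length-2 numeric: lower/upper clip values (may be infinite).
#' @return An object of class `pwl_spec`.
#' @export
pwl_spec <- function(slopes, intercepts, borders, clip = c(-Inf, Inf)) {
  stopifnot(length(slopes) == length(intercepts),
            length(borders) == length(slopes) - 1,
            length(clip) == 2, clip[1] <= clip[2])
  if (length(borders) && any(diff(borders) <= 0)) {
    stop("pwl_spec: borders must be strictly increasing")
  }
  structure(list(slopes = as.numeric(slopes),
                 intercepts = as.numeric(intercepts),
                 borders = as.numeric(borders),
                 clip = as.numeric(clip)),
            class = "pwl_spec")
}

#' @export
print.pwl_spec <- function(x, ...) {
  cat(sprintf("<pwl_spec: %d segments, clip [%g, %g]>\n",
              length(x$slopes), x$clip[1], x$clip[2]))
  print(data.frame(slope = x$slopes, intercept = x$intercepts,
                   upper_border = c(x$borders, Inf)))
  invisible(x)
}

#' Five-segment approximation of the sigmoid
#'
#' The default hardware sigmoid: five segments with power-of-two slopes,
#' borders at -3.4, -1.3, 1.3, 3.4, output clipped to \[0, 1\]. The center
#' segment `0.25 V + 0.5` matches the sigmoid's value and slope at the
#' origin exactly.
#'
#' @return a [pwl_spec()].
#' @export
#' @examples
#' pwl_eval(pwl_sigmoid5(), 0) # 0.5
pwl_sigmoid5 <- function() {
  pwl_spec(slopes = c(0.0078125, 0.0625, 0.25, 0.0625, 0.0078125),
           intercepts = c(0.05, 0.24, 0.5, 0.76, 0.95),
           borders = c(-3.4, -1.3, 1.3, 3.4),
           clip = c(0, 1))
}

#' Six-segment approximation of the sigmoid derivative
#'
#' Six segments forming an even bump peaking at 0.25 near the origin,
#' borders at -3.2, -2, 0, 2, 3.2, output clipped below at 0. Slopes on
#' the positive flank are the negated mirror of the negative flank.
#'
#' @return a [pwl_spec()].
#' @export
#' @examples
#' pwl_eval(pwl_dsigmoid6(), 0) # 0.25, the true maximum of sigma'
pwl_dsigmoid6 <- function() {
  pwl_spec(slopes = c(0.0078125, 0.03125, 0.0625, -0.0625, -0.03125, -0.0078125),
           intercepts = c(0.05, 0.15, 0.25, 0.26, 0.15, 0.05),
           borders = c(-3.2, -2, 0, 2, 3.2),
           clip = c(0, Inf))
}

#' Evaluate a piecewise-linear function
#'
#' Selects each value's segment by the borders and returns the clipped
#' affine response. The `"float"` backend evaluates `m_i V + k_i` in double
#' precision; the `"hw"` backend quantizes the input to 24-bit fixed point
#' and computes every slope product as a shift-add constant multiplication
#' with truncation, as the digital circuit does.
#'
#' @param spec a [pwl_spec()].
#' @param V numeric vector of evaluation points.
#' @param backend `"float"` or `"hw"`.
#' @return numeric vector, same length as `V`.
#' @export
#' @examples
#' pwl_eval(pwl_sigmoid5(), c(-10, 0, 2)) # 0, 0.5, 0.885
pwl_eval <- function(spec, V, backend = c("float", "hw")) {
  backend <- match.arg(backend)
  idx <- findInterval(V, spec$borders, left.open = TRUE) + 1L
  if (backend == "float") {
    y <- spec$slopes[idx] * V + spec$intercepts[idx]
  } else {
    Vq <- fx_quantize(V)
    y <- numeric(length(V))
    for (s in seq_along(spec$slopes)) {
      in_seg <- idx == s
      if (!any(in_seg)) next
      y[in_seg] <- fx_quantize(
        fx_const_mul(spec$slopes[s], Vq[in_seg]) +
          fx_quantize(spec$intercepts[s]))
    }
  }
  pmin(pmax(y, spec$clip[1]), spec$clip[2])
}

#' Fit a piecewise-linear approximation by deterministic grid descent
#'
#' Searches borders, slopes and intercepts on fixed grids to minimize the
#' root-mean-square error against `target_fn` on a dense evaluation grid.
#' A full joint enumeration over 5-6 segments is combinatorially
#' infeasible, so the search is a deterministic coordinate descent: borders
#' start equally spaced over `fit_range`, slopes and intercepts start from
#' per-segment least squares snapped to their grids, then each parameter in
#' turn is moved by its step in the improving direction until no single
#' move improves the RMSE.
#'
#' @param target_fn vectorized function of one numeric argument.
#' @param n_segments number of segments (>= 1).
#' @param steps length-3 numeric: grid steps for borders, slopes,
#'   intercepts (defaults 0.1, 0.01, 0.01).
#' @param fit_range length-2 numeric interval to fit over.
#' @param grid_step spacing of the evaluation grid.
#' @param clip clip range applied during fitting and stored in the result.
#' @param max_sweeps upper bound on coordinate-descent sweeps.
#' @return a [pwl_spec()] with attribute `rmse` (the achieved RMSE on the
#'   fit grid).
#' @export
#' @examples
#' f <- fit_pwl(function(v) v, 1, fit_range = c(-1, 1))
#' attr(f, "rmse") # 0
fit_pwl <- function(target_fn, n_segments,
                    steps = c(border = 0.1, slope = 0.01, intercept = 0.01),
                    fit_range, grid_step = 0.01, clip = c(-Inf, Inf),
                    max_sweeps = 60) {
  stopifnot(n_segments >= 1, all(steps > 0), length(fit_range) == 2)
  if (fit_range[2] <= fit_range[1]) stop("fit_pwl: empty fit_range")
  V <- seq(fit_range[1], fit_range[2], by = grid_step)
  y <- target_fn(V)
  snap <- function(v, s) round(v / s) * s

  seg_rmse <- function(borders, slopes, intercepts) {
    idx <- findInterval(V, borders, left.open = TRUE) + 1L
    pred <- pmin(pmax(slopes[idx] * V + intercepts[idx], clip[1]), clip[2])
    sqrt(mean((pred - y)^2))
  }

  # warm start: equal borders; per-segment least squares snapped to grid
  borders <- if (n_segments > 1) {
    snap(seq(fit_range[1], fit_range[2],
             length.out = n_segments + 1)[2:n_segments], steps[1])
  } else numeric(0)
  slopes <- numeric(n_segments); intercepts <- numeric(n_segments)
  idx <- findInterval(V, borders, left.open = TRUE) + 1L
  for (s in seq_len(n_segments)) {
    vi <- V[idx == s]; yi <- y[idx == s]
    if (length(vi) >= 2 && stats::var(vi) > 0) {
      ft <- stats::lm.fit(cbind(1, vi), yi)
      intercepts[s] <- snap(ft$coefficients[1], steps[3])
      slopes[s] <- snap(ft$coefficients[2], steps[2])
    } else if (length(yi)) {
      intercepts[s] <- snap(mean(yi), steps[3])
    }
  }

  best <- seg_rmse(borders, slopes, intercepts)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    # borders
    for (j in seq_along(borders)) {
      for (dir in c(1, -1)) {
        repeat {
          cand <- borders; cand[j] <- cand[j] + dir * steps[1]
          if (length(cand) > 1 && any(diff(cand) <= 0)) break
          r <- seg_rmse(cand, slopes, intercepts)
          if (r >= best) break
          borders <- cand; best <- r; improved <- TRUE
        }
      }
    }
    # slopes and intercepts
    for (j in seq_len(n_segments)) {
      for (dir in c(1, -1)) {
        repeat {
          cand <- slopes; cand[j] <- cand[j] + dir * steps[2]
          r <- seg_rmse(borders, cand, intercepts)
          if (r >= best) break
          slopes <- cand; best <- r; improved <- TRUE
        }
      }
      for (dir in c(1, -1)) {
        repeat {
          cand <- intercepts; cand[j] <- cand[j] + dir * steps[3]
          r <- seg_rmse(borders, slopes, cand)
          if (r >= best) break
          intercepts <- cand; best <- r; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  out <- pwl_spec(slopes, intercepts, borders, clip)
  attr(out, "rmse") <- best
  out
}
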