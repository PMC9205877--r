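## Wiener first-passage-time machinery. Diffusion coefficient is fixed at 1;
## the legacy 0.1 scale used by older toolboxes is supported as a pure
## reparameterization (see legacy_to_unit()).

# First-passage density at the LOWER boundary for the normalized process:
# unit boundary separation, zero drift, start w in (0,1), at normalized time
# tau = t / a^2. Dual series with an accuracy-based switch: the small-time
# (Gaussian image) expansion and the large-time (sine) expansion agree on the
# bound `eps`; whichever needs fewer terms is used per element.
wfpt_f1 <- function(tau, w, eps = 1e-10) {
  n <- length(tau)
  out <- numeric(n)
  pos <- which(tau > 0)
  if (!length(pos)) return(out)
  tt <- tau[pos]

  # number of terms needed (Navarro-Fuss style bounds)
  ks <- rep(2, length(tt))
  sml <- 2 * sqrt(2 * pi * tt) * eps < 1
  ks[sml] <- 2 + sqrt(-2 * tt[sml] * log(2 * sqrt(2 * pi * tt[sml]) * eps))
  ks <- pmax(ks, sqrt(tt) + 1)
  kl <- 1 / (pi * sqrt(tt))
  lrg <- pi * tt * eps < 1
  kl[lrg] <- pmax(sqrt(-2 * log(pi * tt[lrg] * eps) / (pi^2 * tt[lrg])), kl[lrg])

  use_small <- ks < kl
  f <- numeric(length(tt))

  if (any(use_small)) {
    ts <- tt[use_small]
    K <- min(ceiling(max(ks[use_small]) / 2) + 1, 60)
    kk <- (-K):K
    # sum_k (w + 2k) * exp(-(w + 2k)^2 / (2 tau))
    arg <- outer(ts, kk, function(t, k) -(w + 2 * k)^2 / (2 * t))
    s <- drop(exp(arg) %*% (w + 2 * kk))
    f[use_small] <- s / sqrt(2 * pi * ts^3)
  }
  if (any(!use_small)) {
    tl <- tt[!use_small]
    K <- min(ceiling(max(kl[!use_small])) + 1, 200)
    kk <- seq_len(K)
    arg <- outer(tl, kk, function(t, k) -k^2 * pi^2 * t / 2)
    s <- drop(exp(arg) %*% (kk * sin(kk * pi * w)))
    f[!use_small] <- pi * s
  }
  out[pos] <- pmax(f, 0)
  out
}

# density at the lower boundary, scalar parameters, vector t
wfpt_lower <- function(t, a, v, w, t0, eps = 1e-10) {
  dt_ <- t - t0
  out <- numeric(length(t))
  pos <- which(dt_ > 0)
  if (!length(pos)) return(out)
  tau <- dt_[pos] / a^2
  out[pos] <- wfpt_f1(tau, w, eps) / a^2 * exp(-v * a * w - v^2 * dt_[pos] / 2)
  out
}

# quadrature grids for inter-trial variability (uniform start point / t0,
# normal drift); each row of the returned data frame is one node
variability_grid <- function(a, v, w, t0, eta = 0, sz = 0, st = 0, n_quad = 7L) {
  vg <- if (eta > 0) {
    gh <- pracma::gaussHermite(n_quad)
    list(v = v + sqrt(2) * eta * gh$x, w = gh$w / sqrt(pi))
  } else list(v = v, w = 1)
  wg <- if (sz > 0) {
    gl <- pracma::gaussLegendre(n_quad, -0.5, 0.5)
    list(w = w + sz / a * gl$x, wt = gl$w)    # z uniform over z +/- sz/2
  } else list(w = w, wt = 1)
  tg <- if (st > 0) {
    gl <- pracma::gaussLegendre(n_quad, -0.5, 0.5)
    list(t0 = pmax(t0 + st * gl$x, 0), wt = gl$w)
  } else list(t0 = t0, wt = 1)
  grid <- expand.grid(iv = seq_along(vg$v), iw = seq_along(wg$w), it = seq_along(tg$t0))
  data.frame(v = vg$v[grid$iv], w = wg$w[grid$iw], t0 = tg$t0[grid$it],
             wt = vg$w[grid$iv] * wg$wt[grid$iw] * tg$wt[grid$it])
}

#' Wiener first-passage-time density
#'
#' Density of the decision time of a drift-diffusion process (diffusion
#' coefficient 1) absorbing at the named boundary, evaluated at observed time
#' `t` (which includes the non-decision time `t0`). Computed by dual
#' small-time/large-time series with an accuracy-based switch. Optional
#' inter-trial variabilities (normal in drift, uniform in start point and
#' non-decision time) are integrated by Gaussian quadrature.
#'
#' @param t vector of observed response times (seconds). Values at or below
#'   `t0` get density 0 by convention.
#' @param a boundary separation (> 0).
#' @param v drift rate (evidence units/s; positive drives toward the upper
#'   boundary).
#' @param w relative starting point `z/a` in (0, 1).
#' @param t0 non-decision time (s, >= 0).
#' @param boundary `"upper"` or `"lower"`, scalar or per-element vector.
#' @param eta inter-trial SD of drift (>= 0).
#' @param sz inter-trial range of the start point, evidence units
#'   (`sz < 2 a min(w, 1-w)`).
#' @param st inter-trial range of the non-decision time (s, `st < 2 t0`).
#' @param eps truncation accuracy of the series.
#' @param n_quad quadrature nodes per variability dimension.
#' @return vector of densities (1/s).
#' @examples
#' tt <- seq(0.3, 3, by = 0.01)
#' f <- dwiener(tt, a = 1.6, v = -0.3, w = 0.5, t0 = 0.25, boundary = "upper")
#' @export
dwiener <- function(t, a, v, w, t0 = 0, boundary = "upper",
                    eta = 0, sz = 0, st = 0, eps = 1e-10, n_quad = 7L) {
  stopifnot(a > 0, w > 0, w < 1, t0 >= 0, eta >= 0, sz >= 0, st >= 0)
  if (sz > 0 && sz >= 2 * a * min(w, 1 - w))
    stop("sz must be smaller than 2*min(z, a-z)")
  if (st > 0 && st >= 2 * t0) stop("st must be smaller than 2*t0")
  boundary <- rep_len(boundary, length(t))
  up <- boundary == "upper"
  grid <- variability_grid(a, v, w, t0, eta, sz, st, n_quad)
  out <- numeric(length(t))
  for (g in seq_len(nrow(grid))) {
    vi <- grid$v[g]; wi <- grid$w[g]; ti <- grid$t0[g]; wt <- grid$wt[g]
    if (any(up))
      out[up] <- out[up] + wt * wfpt_lower(t[up], a, -vi, 1 - wi, ti, eps)
    if (any(!up))
      out[!up] <- out[!up] + wt * wfpt_lower(t[!up], a, vi, wi, ti, eps)
  }
  out
}

#' Boundary absorption probability
#'
#' Closed-form probability that the diffusion absorbs at the given boundary:
#' for drift `v != 0`, `P(upper) = (1 - exp(-2 v a w)) / (1 - exp(-2 v a))`;
#' for `v = 0`, `P(upper) = w`. Drift variability is integrated by
#' Gauss-Hermite quadrature.
#'
#' @inheritParams dwiener
#' @return probability of absorbing at `boundary`.
#' @export
choice_probability <- function(a, v, w, boundary = c("upper", "lower"),
                               eta = 0, n_quad = 21L) {
  boundary <- match.arg(boundary)
  stopifnot(a > 0, w > 0, w < 1, eta >= 0)
  p_up_one <- function(v) {
    if (abs(v * a) < 1e-9) return(w + v * a * w * (1 - w))  # series around v = 0
    expm1(-2 * v * a * w) / expm1(-2 * v * a)
  }
  p <- if (eta > 0) {
    gh <- pracma::gaussHermite(n_quad)
    sum(gh$w / sqrt(pi) * vapply(v + sqrt(2) * eta * gh$x, p_up_one, 0))
  } else p_up_one(v)
  if (boundary == "upper") p else 1 - p
}

#' Deviance (-2 log-likelihood) of choice-RT data under a diffusion model
#'
#' Sums `-2 log f` of the Wiener first-passage density at each trial's
#' observed boundary and response time. Densities are floored at
#' `dens_floor` so that response times at or below the candidate `t0` incur a
#' large but finite penalty instead of an infinite one; this keeps the
#' objective usable by derivative-free optimizers.
#'
#' @param rt vector of response times (s).
#' @param choice trial choices: logical (`TRUE` = upper boundary), or
#'   character `"cooperate"` (upper) / `"deceive"` (lower).
#' @param params named list or vector with `a`, `v`, `w`, `t0` and optional
#'   `eta`, `sz`, `st`.
#' @param dens_floor density floor (default `1e-10`).
#' @param eps,n_quad passed to [dwiener()].
#' @return the deviance (numeric scalar).
#' @export
ddm_deviance <- function(rt, choice, params, dens_floor = 1e-10,
                         eps = 1e-10, n_quad = 7L) {
  up <- as_upper(choice)
  stopifnot(length(rt) == length(up), length(rt) >= 1L)
  p <- as.list(params)
  eta <- p$eta %||% 0; sz <- p$sz %||% 0; st <- p$st %||% 0
  f <- numeric(length(rt))
  if (eta == 0 && sz == 0 && st == 0) {
    # fast path used throughout fitting
    if (any(up)) f[up] <- wfpt_lower(rt[up], p$a, -p$v, 1 - p$w, p$t0, eps)
    if (any(!up)) f[!up] <- wfpt_lower(rt[!up], p$a, p$v, p$w, p$t0, eps)
  } else {
    grid <- variability_grid(p$a, p$v, p$w, p$t0, eta, sz, st, n_quad)
    for (g in seq_len(nrow(grid))) {
      if (any(up))
        f[up] <- f[up] + grid$wt[g] *
          wfpt_lower(rt[up], p$a, -grid$v[g], 1 - grid$w[g], grid$t0[g], eps)
      if (any(!up))
        f[!up] <- f[!up] + grid$wt[g] *
          wfpt_lower(rt[!up], p$a, grid$v[g], grid$w[g], grid$t0[g], eps)
    }
  }
  -2 * sum(log(pmax(f, dens_floor)))
}

# canonical choice coding: TRUE = upper boundary = cooperate
as_upper <- function(choice) {
  if (is.logical(choice)) return(choice)
  ch <- as.character(choice)
  bad <- !is.na(ch) & !ch %in% c("cooperate", "deceive")
  if (any(bad)) stop("choices must be 'cooperate' or 'deceive'")
  ch == "cooperate"
}

#' Convert legacy-scale diffusion parameters to the unit-diffusion scale
#'
#' Older toolboxes fix the within-trial diffusion coefficient at `s = 0.1`.
#' The Wiener process is invariant under joint rescaling of evidence units,
#' so parameters published on that scale map to this package's unit scale by
#' dividing all evidence-denominated parameters by `s`; time-denominated
#' parameters are unchanged. Deviances computed on the two scales are
#' identical.
#'
#' @param params named list/vector with `a`, `v`, `w`, `t0`, optional `eta`,
#'   `sz`, `st`, expressed with diffusion coefficient `s`.
#' @param s legacy diffusion coefficient (default 0.1).
#' @return the same parameters on the unit-diffusion scale.
#' @export
legacy_to_unit <- function(params, s = 0.1) {
  p <- as.list(params)
  p$a <- p$a / s
  p$v <- p$v / s
  if (!is.null(p$eta)) p$eta <- p$eta / s
  if (!is.null(p$sz)) p$sz <- p$sz / s
  p  # w, t0, st are scale-free / time-denominated
}

#' Simulate Wiener first-passage times
#'
#' Draws choices and response times from the diffusion process by a
#' small-step Euler scheme (default step 1 ms). With `bridge = TRUE` an
#' exact Brownian-bridge crossing probability is applied between successive
#' steps, removing most of the discretization bias in absorption
#' probabilities; it is off by default and enabled where high analytic
#' fidelity matters.
#'
#' @param n number of trials to draw.
#' @inheritParams dwiener
#' @param dt Euler time step (s).
#' @param bridge apply the bridge crossing correction.
#' @param max_t maximum decision time; rare unabsorbed paths are returned
#'   with `rt = t0 + max_t` and the boundary nearer to their current
#'   position (flagged via the `"censored"` attribute).
#' @return data frame with `choice` (`"cooperate"` upper / `"deceive"`
#'   lower) and `rt` (seconds, first-passage time plus `t0`).
#' @export
rwiener_fp <- function(n, a, v, w, t0 = 0, dt = 1e-3, bridge = FALSE, max_t = 20) {
  stopifnot(n >= 1, a > 0, w > 0, w < 1, t0 >= 0, dt > 0)
  if (n <= 16L) {
    sims <- lapply(seq_len(n), function(i) rwiener_one(a, v, w, t0, dt, bridge, max_t))
    out <- data.frame(choice = vapply(sims, `[[`, "", "choice"),
                      rt = vapply(sims, `[[`, 0, "rt"),
                      stringsAsFactors = FALSE)
    attr(out, "censored") <- any(vapply(sims, `[[`, TRUE, "censored"))
    return(out)
  }
  x <- rep(a * w, n)
  rt <- rep(NA_real_, n)
  upper <- rep(NA, n)
  active <- seq_len(n)
  sdt <- sqrt(dt)
  step <- 0L
  max_steps <- ceiling(max_t / dt)
  while (length(active) && step < max_steps) {
    step <- step + 1L
    xo <- x[active]
    xn <- xo + v * dt + sdt * stats::rnorm(length(active))
    hit_up <- xn >= a
    hit_lo <- xn <= 0
    if (bridge) {
      inside <- !hit_up & !hit_lo
      if (any(inside)) {
        pu <- exp(-2 * (a - xo[inside]) * (a - xn[inside]) / dt)
        pl <- exp(-2 * xo[inside] * xn[inside] / dt)
        u <- stats::runif(sum(inside))
        bu <- u < pu
        bl <- !bu & (u < pu + pl)
        hit_up[inside][bu] <- TRUE
        hit_lo[inside][bl] <- TRUE
      }
    }
    done <- hit_up | hit_lo
    if (any(done)) {
      idx <- active[done]
      rt[idx] <- t0 + step * dt
      upper[idx] <- hit_up[done]
    }
    x[active] <- xn
    active <- active[!done]
  }
  censored <- length(active) > 0L
  if (censored) {
    rt[active] <- t0 + max_t
    upper[active] <- x[active] >= a / 2
  }
  out <- data.frame(choice = ifelse(upper, "cooperate", "deceive"), rt = rt,
                    stringsAsFactors = FALSE)
  attr(out, "censored") <- censored
  out
}

# single-trajectory sampler: simulates the Euler path in blocks of
# pre-drawn increments (vectorized cumsum) instead of stepping one
# increment at a time
rwiener_one <- function(a, v, w, t0, dt, bridge, max_t, block = 2048L) {
  sdt <- sqrt(dt)
  x_last <- a * w
  offset <- 0L
  max_steps <- ceiling(max_t / dt)
  while (offset < max_steps) {
    nb <- min(block, max_steps - offset)
    path <- x_last + cumsum(v * dt + sdt * stats::rnorm(nb))
    x0 <- c(x_last, path[-nb])
    hit_up <- path >= a
    hit_lo <- path <= 0
    if (bridge) {
      inside <- !hit_up & !hit_lo
      if (any(inside)) {
        u <- stats::runif(nb)
        pu <- exp(-2 * pmax(a - x0, 0) * pmax(a - path, 0) / dt)
        pl <- exp(-2 * pmax(x0, 0) * pmax(path, 0) / dt)
        bu <- inside & u < pu
        bl <- inside & !bu & u < pu + pl
        hit_up <- hit_up | bu
        hit_lo <- hit_lo | bl
      }
    }
    hit <- hit_up | hit_lo
    if (any(hit)) {
      k <- which.max(hit)
      return(list(choice = if (hit_up[k]) "cooperate" else "deceive",
                  rt = t0 + (offset + k) * dt, censored = FALSE))
    }
    x_last <- path[nb]
    offset <- offset + nb
  }
  list(choice = if (x_last >= a / 2) "cooperate" else "deceive",
       rt = t0 + max_t, censored = TRUE)
}
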