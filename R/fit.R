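#' Control settings for diffusion-model fitting
#'
#' @param restarts number of jittered optimizer restarts after the heuristic
#'   start (default 5).
#' @param reltol relative convergence tolerance of the simplex optimizer.
#' @param maxit maximum simplex iterations per start.
#' @param rt_floor trials with RT below this floor (s) are excluded from
#'   fitting as likely contaminants; the count is recorded on the fit.
#' @param dens_floor density floor used in the deviance (see
#'   [ddm_deviance()]).
#' @param quad_points quadrature nodes per inter-trial-variability dimension.
#' @param jitter_sd standard deviation of the restart jitter on the
#'   transformed parameter scale.
#' @param start optional named list of starting parameter values on the
#'   natural scale (`a`, `w`, `v`, `t0`, and any active `eta`/`sz`/`st`);
#'   used e.g. to warm-start a free model from a fixed-model optimum.
#' @return a list of class `"ddm_control"`.
#' @export
fit_control <- function(restarts = 5L, reltol = 1e-7, maxit = 800L,
                        rt_floor = 0.2, dens_floor = 1e-10, quad_points = 7L,
                        jitter_sd = 0.4, start = NULL) {
  structure(list(restarts = as.integer(restarts), reltol = reltol,
                 maxit = as.integer(maxit), rt_floor = rt_floor,
                 dens_floor = dens_floor, quad_points = as.integer(quad_points),
                 jitter_sd = jitter_sd, start = start),
            class = "ddm_control")
}

# ---- internal parameter packing -------------------------------------------

.free_names <- c("none", "a", "z", "v", "t0", "eta", "sz", "st")
.var3 <- c("eta", "sz", "st")

# map user-facing free-parameter name to internal coefficient name
free_internal <- function(free) if (free == "z") "w" else free

# layout: ordered parameter names with per-level expansion for the free one
param_layout <- function(free, include, levels) {
  fint <- free_internal(free)
  active_var <- .var3[.var3 %in% union(include, if (free %in% .var3) free)]
  base <- c("a", "w", "v", "t0", active_var)
  lay <- list()
  for (p in base) {
    lay[[p]] <- if (p == fint && length(levels) > 1L) {
      paste(p, levels, sep = ".")
    } else p
  }
  lay
}

# transform theta (unconstrained) -> list of per-level natural parameter lists
unpack_theta <- function(theta, layout, levels, t0_max) {
  get <- function(p, lev_i) {
    nm <- layout[[p]]
    val <- if (length(nm) > 1L) theta[[nm[lev_i]]] else theta[[nm]]
    val
  }
  out <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    a <- exp(get("a", i))
    w <- stats::plogis(get("w", i))
    v <- get("v", i)
    t0m <- if (length(t0_max) > 1L) t0_max[i] else t0_max
    t0 <- stats::plogis(get("t0", i)) * t0m
    p <- list(a = a, w = w, v = v, t0 = t0)
    if (!is.null(layout$eta)) p$eta <- exp(get("eta", i))
    if (!is.null(layout$sz))
      p$sz <- stats::plogis(get("sz", i)) * 1.98 * a * min(w, 1 - w)
    if (!is.null(layout$st)) p$st <- stats::plogis(get("st", i)) * 1.98 * t0
    out[[i]] <- p
  }
  names(out) <- levels
  out
}

# inverse transform for starting values (natural -> unconstrained)
pack_start <- function(start, layout, levels, t0_max) {
  theta <- c()
  clamp <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
  for (p in names(layout)) {
    nm <- layout[[p]]
    for (i in seq_along(nm)) {
      lev_i <- if (length(nm) > 1L) i else 1L
      s <- start[[p]]
      val <- if (length(s) > 1L) s[lev_i] else s
      a_here <- if (length(start$a) > 1L) start$a[lev_i] else start$a
      w_here <- if (length(start$w) > 1L) start$w[lev_i] else start$w
      t0_here <- if (length(start$t0) > 1L) start$t0[lev_i] else start$t0
      t0m <- if (length(t0_max) > 1L) t0_max[lev_i] else t0_max
      theta[nm[i]] <- switch(p,
        a = log(val),
        w = stats::qlogis(clamp(val)),
        v = val,
        t0 = stats::qlogis(clamp(val / t0m)),
        eta = log(max(val, 1e-3)),
        sz = stats::qlogis(clamp(val / (1.98 * a_here * min(w_here, 1 - w_here)))),
        st = stats::qlogis(clamp(val / (1.98 * t0_here))))
    }
  }
  theta
}

# data-driven starting values (natural scale)
heuristic_start <- function(rt, upper, active_var) {
  pc <- min(max(mean(upper), 0.05), 0.95)
  t0 <- 0.85 * min(rt)
  mdt <- max(mean(rt) - t0, 0.05)
  a <- sqrt(4 * mdt)
  s <- list(a = a, w = 0.5 + 0.3 * (pc - 0.5), v = stats::qlogis(pc) / a, t0 = t0)
  if ("eta" %in% active_var) s$eta <- 0.3
  if ("sz" %in% active_var) s$sz <- 0.2 * s$a * min(s$w, 1 - s$w)
  if ("st" %in% active_var) s$st <- 0.3 * s$t0
  s
}

# ---- the fitting function --------------------------------------------------

#' Fit a drift-diffusion model to choices and response times
#'
#' Maximum-likelihood estimation of the Wiener diffusion parameters from
#' trial-level choices and response times, optionally across the levels of a
#' grouping factor (by default the stimulation condition). All parameters are
#' shared across group levels except the one named in `free`, which gets one
#' value per level — the nested one-parameter-free model family used for
#' chi-square difference testing. Estimation uses a derivative-free simplex
#' with jittered multi-starts; bounds are enforced by transform (log for
#' `a`/`eta`, logit for the starting bias and for `t0`, `sz`, `st` relative
#' to their admissible ranges).
#'
#' The upper boundary codes cooperation throughout the package.
#'
#' @param rt response times in seconds.
#' @param choice trial choices (`"cooperate"`/`"deceive"` or logical with
#'   `TRUE` = cooperate).
#' @param group optional factor splitting trials into conditions; `NULL`
#'   fits a single condition.
#' @param free parameter allowed to differ across group levels: `"none"`
#'   (fully fixed baseline), `"a"`, `"z"` (starting point, estimated as the
#'   normalized bias), `"v"`, `"t0"`, `"eta"`, `"sz"`, or `"st"`.
#' @param include inter-trial variability parameters (`"eta"`, `"sz"`,
#'   `"st"`) estimated but shared across levels; a variability named in
#'   `free` is active automatically. Variabilities not listed are fixed at 0.
#' @param control a [fit_control()] list.
#' @return an object of class `"ddmfit"` with per-level coefficients,
#'   deviance, parameter counts and convergence diagnostics. Non-convergence
#'   is flagged (`converged = FALSE`), never thrown.
#' @seealso [ddm_compare()], [ddm_scan()], [starting_bias()]
#' @examples
#' set.seed(1)
#' d <- rwiener_fp(300, a = 1.6, v = -0.3, w = 0.55, t0 = 0.3)
#' fit <- fit_ddm(d$rt, d$choice, control = fit_control(restarts = 2))
#' coef(fit)
#' @export
fit_ddm <- function(rt, choice, group = NULL, free = "none",
                    include = character(), control = fit_control()) {
  cl <- match.call()
  free <- match.arg(free, .free_names)
  if (!all(include %in% .var3))
    stop("include may only contain 'eta', 'sz', 'st'")
  upper <- as_upper(choice)
  if (is.null(group)) group <- factor(rep("all", length(rt)))
  group <- droplevels(factor(group))
  keep <- is.finite(rt) & !is.na(upper) & rt >= control$rt_floor
  n_excluded <- sum(!keep)
  rt <- rt[keep]; upper <- upper[keep]; group <- droplevels(group[keep])
  levels <- levels(group)
  if (any(table(group) < 5L))
    stop("each group level needs at least 5 valid trials")
  layout <- param_layout(free, include, levels)
  active_var <- intersect(.var3, names(layout))
  fint <- free_internal(free)

  rts <- split(rt, group)
  ups <- split(upper, group)
  t0_max <- if (fint == "t0" && length(levels) > 1L) {
    vapply(rts, function(x) 0.999 * min(x), 0)
  } else 0.999 * min(rt)

  objective <- function(theta) {
    pars <- unpack_theta(theta, layout, levels, t0_max)
    dev <- 0
    for (i in seq_along(levels)) {
      dev <- dev + ddm_deviance(rts[[i]], ups[[i]], pars[[i]],
                                dens_floor = control$dens_floor,
                                n_quad = control$quad_points)
      if (!is.finite(dev)) return(1e12)
    }
    dev
  }

  start_nat <- control$start %||% heuristic_start(rt, upper, active_var)
  # make sure all active parameters have a start
  defaults <- heuristic_start(rt, upper, active_var)
  for (p in names(layout)) if (is.null(start_nat[[p]])) start_nat[[p]] <- defaults[[p]]
  theta0 <- pack_start(start_nat, layout, levels, t0_max)

  best <- NULL
  for (r in 0:control$restarts) {
    th <- if (r == 0) theta0 else theta0 + stats::rnorm(length(theta0), 0, control$jitter_sd)
    opt <- stats::optim(th, objective, method = "Nelder-Mead",
                        control = list(reltol = control$reltol, maxit = control$maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish from the incumbent
  opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                      control = list(reltol = control$reltol, maxit = control$maxit))
  if (opt$value <= best$value) best <- opt

  pars <- unpack_theta(best$par, layout, levels, t0_max)
  coefs <- do.call(rbind, lapply(seq_along(levels), function(i) {
    p <- pars[[i]]
    data.frame(level = levels[i], a = p$a, v = p$v, b = p$w, t0 = p$t0,
               eta = p$eta %||% 0, sz = p$sz %||% 0, st = p$st %||% 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    coefficients = coefs,
    deviance = best$value,
    npar = length(best$par),
    free = free, include = active_var, levels = levels,
    nobs = vapply(rts, length, 0L), n_excluded = n_excluded,
    converged = best$convergence == 0,
    optim = list(convergence = best$convergence, counts = best$counts),
    data = list(rt = rt, upper = upper, group = group),
    control = control, call = cl), class = "ddmfit")
}

#' @export
print.ddmfit <- function(x, digits = 4, ...) {
  cat("Drift-diffusion model fit",
      if (x$free != "none") paste0("(free parameter: ", x$free, ")") else "(all parameters fixed across levels)",
      "\n")
  cat("Levels:", paste(x$levels, collapse = ", "),
      "  trials:", paste(x$nobs, collapse = ", "),
      if (x$n_excluded > 0) paste0("  (", x$n_excluded, " excluded below RT floor)"), "\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat("Deviance:", format(x$deviance, digits = digits + 3),
      " free parameters:", x$npar,
      if (!x$converged) " [NOT CONVERGED]", "\n")
  invisible(x)
}

#' @export
coef.ddmfit <- function(object, ...) object$coefficients

#' @export
deviance.ddmfit <- function(object, ...) object$deviance

#' @export
logLik.ddmfit <- function(object, ...) {
  structure(-object$deviance / 2, df = object$npar,
            nobs = sum(object$nobs), class = "logLik")
}

#' Normalized starting bias per group level
#'
#' The starting point divided by the boundary separation, `b = z/a`, on a
#' 0-1 scale with 0.5 meaning no initial preference for either choice.
#'
#' @param fit a [fit_ddm()] object.
#' @return named numeric vector of biases, one per group level.
#' @export
starting_bias <- function(fit) {
  stopifnot(inherits(fit, "ddmfit"))
  stats::setNames(fit$coefficients$b, fit$coefficients$level)
}

#' @export
summary.ddmfit <- function(object, ...) {
  cf <- object$coefficients
  cf$p_cooperate_fit <- vapply(seq_len(nrow(cf)), function(i)
    choice_probability(cf$a[i], cf$v[i], cf$b[i], "upper", eta = cf$eta[i]), 0)
  obs <- tapply(object$data$upper, object$data$group, mean)
  cf$p_cooperate_obs <- as.numeric(obs[cf$level])
  cf$n <- as.integer(object$nobs[cf$level])
  out <- list(coefficients = cf, deviance = object$deviance, npar = object$npar,
              free = object$free, converged = object$converged)
  class(out) <- "summary.ddmfit"
  out
}

#' @export
print.summary.ddmfit <- function(x, digits = 4, ...) {
  cat("Drift-diffusion model summary (free:", x$free, ")\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat("Deviance:", format(x$deviance, digits = digits + 3),
      " parameters:", x$npar,
      if (!x$converged) " [NOT CONVERGED]", "\n")
  invisible(x)
}

#' @export
simulate.ddmfit <- function(object, nsim = 1, seed = NULL, dt = 1e-3,
                            bridge = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- object$coefficients
  one <- function() {
    do.call(rbind, lapply(seq_len(nrow(cf)), function(i) {
      n <- object$nobs[[cf$level[i]]]
      if (cf$eta[i] > 0 || cf$sz[i] > 0 || cf$st[i] > 0) {
        vs <- stats::rnorm(n, cf$v[i], cf$eta[i])
        ws <- cf$b[i] + stats::runif(n, -0.5, 0.5) * cf$sz[i] / cf$a[i]
        t0s <- pmax(cf$t0[i] + stats::runif(n, -0.5, 0.5) * cf$st[i], 0)
        d <- do.call(rbind, lapply(seq_len(n), function(j)
          rwiener_fp(1L, cf$a[i], vs[j], ws[j], t0s[j], dt = dt, bridge = bridge)))
      } else {
        d <- rwiener_fp(n, cf$a[i], cf$v[i], cf$b[i], cf$t0[i], dt = dt, bridge = bridge)
      }
      d$level <- cf$level[i]
      d
    }))
  }
  out <- lapply(seq_len(nsim), function(k) one())
  if (nsim == 1) out[[1]] else out
}

#' @export
predict.ddmfit <- function(object, type = c("choice", "quantiles"),
                           probs = c(.1, .3, .5, .7, .9), ...) {
  type <- match.arg(type)
  cf <- object$coefficients
  if (type == "choice") {
    data.frame(level = cf$level,
               p_cooperate = vapply(seq_len(nrow(cf)), function(i)
                 choice_probability(cf$a[i], cf$v[i], cf$b[i], "upper",
                                    eta = cf$eta[i]), 0))
  } else {
    do.call(rbind, lapply(seq_len(nrow(cf)), function(i) {
      p <- list(a = cf$a[i], v = cf$v[i], w = cf$b[i], t0 = cf$t0[i],
                eta = cf$eta[i], sz = cf$sz[i], st = cf$st[i])
      do.call(rbind, lapply(c("upper", "lower"), function(bnd) {
        q <- wiener_quantiles(p, bnd, probs)
        data.frame(level = cf$level[i],
                   choice = if (bnd == "upper") "cooperate" else "deceive",
                   prob = probs, rt = q)
      }))
    }))
  }
}

# RT quantiles implied by the fitted density (grid CDF inversion)
wiener_quantiles <- function(params, boundary, probs, t_max = 30, n_grid = 6000L) {
  tt <- seq(params$t0 + 1e-4, params$t0 + t_max, length.out = n_grid)
  f <- dwiener(tt, params$a, params$v, params$w, params$t0, boundary,
               eta = params$eta %||% 0, sz = params$sz %||% 0,
               st = params$st %||% 0)
  cdf <- cumsum(f) * diff(tt[1:2])
  cdf <- cdf / cdf[n_grid]
  vapply(probs, function(p) tt[which.max(cdf >= p)], 0)
}

#' @export
plot.ddmfit <- function(x, breaks = 30, ...) {
  cf <- x$coefficients
  nl <- nrow(cf)
  op <- graphics::par(mfrow = c(nl, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nl)) {
    lev <- cf$level[i]
    sel <- x$data$group == lev
    rt <- x$data$rt[sel]; up <- x$data$upper[sel]
    for (bnd in c("upper", "lower")) {
      side_rt <- if (bnd == "upper") rt[up] else rt[!up]
      pr <- if (bnd == "upper") mean(up) else mean(!up)
      ttl <- paste(lev, "-", if (bnd == "upper") "cooperate" else "deceive")
      if (length(side_rt) < 2) { graphics::plot.new(); graphics::title(ttl); next }
      h <- graphics::hist(side_rt, breaks = breaks, freq = FALSE,
                          main = ttl, xlab = "RT (s)", ...)
      tt <- seq(min(rt), max(rt), length.out = 300)
      f <- dwiener(tt, cf$a[i], cf$v[i], cf$b[i], cf$t0[i], bnd,
                   eta = cf$eta[i], sz = cf$sz[i], st = cf$st[i])
      graphics::lines(tt, f / max(pr, 1e-12), col = "red3", lwd = 2)
    }
  }
  invisible(x)
}
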