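#' Construct an enzyme inhibition model
#'
#' General modifier parameterization of reversible inhibition,
#' v = Vmax S / (Km (1 + I/Ki) + S (1 + I/Ki')), with absent terms dropped:
#' `"MM"` has no inhibition terms, `"competitive"` only Ki (binding to free
#' enzyme, raising apparent Km), `"uncompetitive"` only Ki' (binding to the
#' ES complex), `"noncompetitive"` Ki = Ki', and `"mixed"` independent Ki
#' and Ki'. This family nests, which is what makes corrected-AIC model
#' comparison meaningful.
#'
#' @param kind One of `"MM"`, `"competitive"`, `"uncompetitive"`,
#'   `"noncompetitive"`, `"mixed"`.
#' @param vmax Limiting rate, absorbance units/min (> 0).
#' @param km Michaelis constant, mM (> 0).
#' @param ki Inhibitor dissociation constant from free enzyme, uM.
#' @param ki_prime Inhibitor dissociation constant from the ES complex, uM.
#'   For `"noncompetitive"` supply only `ki` (it is copied to `ki_prime`).
#' @return An `inhibition_model` list.
#' @export
inhibition_model <- function(kind = c("MM", "competitive", "uncompetitive",
                                      "noncompetitive", "mixed"),
                             vmax, km, ki = NULL, ki_prime = NULL) {
  kind <- match.arg(kind)
  stopifnot(vmax > 0, km > 0)
  chk <- function(x) !is.null(x) && is.finite(x) && x > 0
  switch(kind,
    MM = {
      if (chk(ki) || chk(ki_prime))
        stop("MM model takes no inhibition constants", call. = FALSE)
    },
    competitive = {
      if (!chk(ki)) stop("competitive model requires ki > 0", call. = FALSE)
      if (chk(ki_prime)) stop("competitive model has no ki_prime", call. = FALSE)
    },
    uncompetitive = {
      if (!chk(ki_prime)) stop("uncompetitive model requires ki_prime > 0", call. = FALSE)
      if (chk(ki)) stop("uncompetitive model has no ki", call. = FALSE)
    },
    noncompetitive = {
      if (!chk(ki)) stop("noncompetitive model requires ki > 0", call. = FALSE)
      if (chk(ki_prime) && ki_prime != ki)
        stop("noncompetitive model has ki = ki_prime", call. = FALSE)
      ki_prime <- ki
    },
    mixed = {
      if (!chk(ki) || !chk(ki_prime))
        stop("mixed model requires ki and ki_prime > 0", call. = FALSE)
    }
  )
  structure(list(kind = kind, vmax = vmax, km = km,
                 ki = if (is.null(ki)) NA_real_ else ki,
                 ki_prime = if (is.null(ki_prime)) NA_real_ else ki_prime),
            class = "inhibition_model")
}

#' Model velocity at given substrate and inhibitor concentrations
#'
#' @param model An [inhibition_model()].
#' @param S Substrate, mM (> 0; vectorized).
#' @param I Inhibitor, uM (>= 0; vectorized).
#' @return Velocity in the model's rate units.
#' @examples
#' m <- inhibition_model("competitive", vmax = 1, km = 0.1, ki = 3)
#' model_rate(m, S = 0.1, I = 0)  # Vmax/2
#' @export
model_rate <- function(model, S, I = 0) {
  if (any(S <= 0)) stop("substrate concentration must be positive", call. = FALSE)
  if (any(I < 0)) stop("inhibitor concentration must be non-negative", call. = FALSE)
  alpha <- if (is.na(model$ki)) 1 else 1 + I / model$ki
  alpha_p <- if (is.na(model$ki_prime)) 1 else 1 + I / model$ki_prime
  model$vmax * S / (model$km * alpha + S * alpha_p)
}

#' Lineweaver-Burk (double reciprocal) analysis
#'
#' Per inhibitor level, fits the OLS line through (1/S, 1/v): slope equals
#' apparent Km / apparent Vmax and intercept 1 / apparent Vmax. Competitive
#' inhibition leaves the intercept common across levels (lines crossing on
#' the 1/v axis); mixed inhibition moves both.
#'
#' @param data data.frame with columns `S_mM`, `I_uM`, `v` (all v > 0).
#' @return data.frame per inhibitor level: `I_uM`, `slope`, `intercept`,
#'   `km_app`, `vmax_app`, `n`.
#' @export
lineweaver_burk <- function(data) {
  if (any(data$v <= 0))
    stop("all velocities must be positive for reciprocal analysis", call. = FALSE)
  rows <- lapply(split(data, data$I_uM), function(g) {
    co <- stats::.lm.fit(cbind(1, 1 / g$S_mM), 1 / g$v)$coefficients
    data.frame(I_uM = g$I_uM[1], slope = co[2], intercept = co[1],
               km_app = co[2] / co[1], vmax_app = 1 / co[1], n = nrow(g))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$I_uM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

n_params <- c(MM = 2L, competitive = 3L, uncompetitive = 3L,
              noncompetitive = 3L, mixed = 4L)

aicc <- function(ssr, n, p) {
  n * log(ssr / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# Build start grid: Km from the I=0 Lineweaver-Burk line, Vmax from
# 1.2 * max(v), Ki (and Ki') from the midpoint of the positive-I range,
# each perturbed by factors {0.5, 1, 2}.
start_grid <- function(data, kind) {
  base_I <- min(data$I_uM)
  g0 <- data[data$I_uM == base_I, ]
  co <- stats::.lm.fit(cbind(1, 1 / g0$S_mM), 1 / g0$v)$coefficients
  km0 <- co[2] / co[1]
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(data$S_mM)
  vmax0 <- 1.2 * max(data$v)
  ki0 <- if (any(data$I_uM > 0)) mean(range(data$I_uM[data$I_uM > 0])) else 1
  fac <- c(0.5, 1, 2)
  grid <- expand.grid(km = km0 * fac, ki = ki0 * fac)
  lapply(seq_len(nrow(grid)), function(i) {
    st <- c(log_vmax = log(vmax0), log_km = log(grid$km[i]))
    if (kind %in% c("competitive", "noncompetitive", "mixed"))
      st <- c(st, log_ki = log(grid$ki[i]))
    if (kind %in% c("uncompetitive", "mixed"))
      st <- c(st, log_kip = log(grid$ki[i]))
    st
  })
}

rate_from_logpars <- function(pars, kind, S, I) {
  m <- inhibition_model(
    kind, vmax = exp(pars[["log_vmax"]]), km = exp(pars[["log_km"]]),
    ki = if ("log_ki" %in% names(pars)) exp(pars[["log_ki"]]) else NULL,
    ki_prime = if ("log_kip" %in% names(pars)) exp(pars[["log_kip"]]) else NULL
  )
  model_rate(m, S, I)
}

#' Fit an inhibition model by nonlinear least squares
#'
#' Levenberg-Marquardt least squares (via minpack.lm) on log-transformed
#' parameters (guaranteeing positivity), started from a small documented
#' multi-start grid around Lineweaver-Burk-derived initial values; the best
#' converged start by SSR wins. Deterministic for given data.
#'
#' The default `"relative"` weighting minimizes relative residuals
#' `(v - v_hat)/v_hat`, matching the constant-CV error structure of
#' absorbance-rate measurements (noise scales with signal); `"absolute"`
#' minimizes raw residuals. AICc comparison is only meaningful between
#' fits sharing one weighting.
#'
#' @param data data.frame with `S_mM`, `I_uM`, `v` (replicates as extra
#'   rows). Inhibition models need >= 2 inhibitor levels and >= 5 points
#'   per level.
#' @param kind Model kind, see [inhibition_model()].
#' @param weighting `"relative"` (default) or `"absolute"` residuals.
#' @return A `kinetics_fit`: list with `model` (fitted
#'   [inhibition_model()]), `ssr` (in the chosen residual scale), `aicc`,
#'   `se` (approximate standard errors of the natural-scale parameters,
#'   delta method), `n`, `kind`, `weighting`.
#' @export
fit_model <- function(data, kind = c("MM", "competitive", "uncompetitive",
                                     "noncompetitive", "mixed"),
                      weighting = c("relative", "absolute")) {
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  stopifnot(all(c("S_mM", "I_uM", "v") %in% names(data)))
  lvl <- sort(unique(data$I_uM))
  if (kind != "MM") {
    if (length(lvl) < 2 || !any(lvl > 0))
      stop("inhibition models are unidentifiable without >= 2 inhibitor levels ",
           "including a positive one", call. = FALSE)
    if (any(table(data$I_uM) < 5))
      stop("need >= 5 points per inhibitor level", call. = FALSE)
  }
  p <- n_params[[kind]]
  if (nrow(data) <= p + 2)
    stop("too few data points for a ", kind, " fit", call. = FALSE)
  resid_fn <- if (weighting == "relative") {
    function(pars) {
      vh <- rate_from_logpars(pars, kind, data$S_mM, data$I_uM)
      (data$v - vh) / vh
    }
  } else {
    function(pars) data$v - rate_from_logpars(pars, kind, data$S_mM, data$I_uM)
  }
  best <- NULL
  for (st in start_grid(data, kind)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best_ssr) {
      best <- fit
      best_ssr <- ssr
    }
  }
  if (is.null(best))
    stop("nonlinear fit failed to converge from every start (", kind, ")",
         call. = FALSE)
  pars <- best$par
  model <- inhibition_model(
    kind, vmax = exp(pars[["log_vmax"]]), km = exp(pars[["log_km"]]),
    ki = if ("log_ki" %in% names(pars)) exp(pars[["log_ki"]]) else NULL,
    ki_prime = if ("log_kip" %in% names(pars)) exp(pars[["log_kip"]]) else NULL
  )
  n <- nrow(data)
  se_log <- tryCatch(sqrt(diag(vcov(best))), error = function(e) rep(NA_real_, p))
  se <- exp(unlist(pars)) * se_log  # delta method back to natural scale
  names(se) <- sub("^log_", "", names(pars))
  structure(list(kind = kind, model = model, ssr = best_ssr,
                 aicc = aicc(best_ssr, n, p), se = se, n = n,
                 weighting = weighting),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  m <- x$model
  cat("<kinetics_fit> ", x$kind, ": Vmax ", signif(m$vmax, 4),
      ", Km ", signif(m$km, 4), " mM",
      if (!is.na(m$ki)) paste0(", Ki ", signif(m$ki, 4), " uM"),
      if (!is.na(m$ki_prime)) paste0(", Ki' ", signif(m$ki_prime, 4), " uM"),
      "; SSR ", signif(x$ssr, 4), ", AICc ", signif(x$aicc, 6),
      ", n ", x$n, "\n", sep = "")
  invisible(x)
}

#' Classify the inhibition mechanism by corrected AIC
#'
#' Fits the competitive, uncompetitive, noncompetitive and mixed models and
#' selects the minimum-AICc fit. The call is declared `"ambiguous"` when
#' the two best models differ by less than 2 AICc units (the conventional
#' evidence threshold), but `selected` still names the minimum.
#'
#' @param data data.frame with `S_mM`, `I_uM`, `v`; >= 2 inhibitor levels
#'   with at least one positive.
#' @param weighting Residual weighting passed to [fit_model()].
#' @return A `mechanism_call`: list with `selected` (kind), `ambiguous`
#'   (logical), `table` (data.frame of kind, ssr, aicc, delta_aicc, ranked)
#'   and `fits` (named list of `kinetics_fit`).
#' @export
classify_mechanism <- function(data, weighting = c("relative", "absolute")) {
  weighting <- match.arg(weighting)
  lvl <- sort(unique(data$I_uM))
  if (length(lvl) < 2 || !any(lvl > 0))
    stop("mechanism classification is unidentifiable: need >= 2 inhibitor ",
         "levels including a positive one", call. = FALSE)
  kinds <- c("competitive", "uncompetitive", "noncompetitive", "mixed")
  fits <- lapply(kinds, function(k) fit_model(data, k, weighting))
  names(fits) <- kinds
  tab <- data.frame(
    kind = kinds,
    ssr = vapply(fits, `[[`, 0, "ssr"),
    aicc = vapply(fits, `[[`, 0, "aicc")
  )
  tab <- tab[order(tab$aicc), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  structure(list(selected = tab$kind[1],
                 ambiguous = tab$delta_aicc[2] < 2,
                 table = tab, fits = fits),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism_call> selected: ", x$selected,
      if (x$ambiguous) " (ambiguous: delta AICc < 2)", "\n", sep = "")
  print(x$table, digits = 5)
  invisible(x)
}

#' Percent inhibition relative to an uninhibited control
#'
#' @param v_i Inhibited velocity (>= 0).
#' @param v_0 Control velocity (> 0).
#' @return 100 (1 - v_i/v_0), percent.
#' @export
percent_inhibition <- function(v_i, v_0) {
  if (any(v_0 <= 0)) stop("control velocity must be positive", call. = FALSE)
  if (any(v_i < 0)) stop("inhibited velocity must be non-negative", call. = FALSE)
  100 * (1 - v_i / v_0)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' y = bottom + (top - bottom) / (1 + (IC50/x)^hill), with bottom
#' constrained to [0, 100) and top to (0, 100]; IC50 is the inflection
#' concentration. Dose-response designs follow assay practice: at least
#' five concentrations chosen so the observed inhibition spans a wide
#' window (the fit refuses spans under 30 percentage points, where IC50 is
#' poorly identified). A warning is raised when inhibition decreases by
#' more than 10 points between successive concentrations (non-monotone
#' beyond plausible noise).
#'
#' @param concs Concentrations, uM (>= 5 values, > 0).
#' @param inhibition Percent inhibition at each concentration.
#' @return A `dose_response`: list with `ic50`, `hill`, `top`, `bottom`,
#'   `ssr`, `n`, `concs`, `inhibition`, `fitted`.
#' @export
fit_ic50 <- function(concs, inhibition) {
  if (length(concs) < 5)
    stop("need at least five concentrations", call. = FALSE)
  if (length(concs) != length(inhibition))
    stop("concs and inhibition must have equal length", call. = FALSE)
  if (any(concs <= 0)) stop("concentrations must be positive", call. = FALSE)
  span <- max(inhibition) - min(inhibition)
  if (span < 30)
    stop("inhibition span ", round(span, 1),
         " points is too small to identify an IC50 (need >= 30)", call. = FALSE)
  ord <- order(concs)
  if (any(diff(inhibition[ord]) < -10))
    warning("inhibition is non-monotone in concentration beyond noise tolerance")
  y <- inhibition
  ic50_0 <- tryCatch({
    i <- which(y[ord] >= 50)[1]
    if (is.na(i) || i == 1) exp(mean(log(concs)))
    else exp(stats::approx(y[ord][(i - 1):i], log(concs[ord][(i - 1):i]),
                           xout = 50)$y)
  }, error = function(e) exp(mean(log(concs))))
  if (!is.finite(ic50_0)) ic50_0 <- exp(mean(log(concs)))
  start <- c(log_ic50 = log(ic50_0), hill = 1,
             bottom = max(0, min(y)), top = min(100, max(y)))
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(log_ic50 = -Inf, hill = 0.05, bottom = 0, top = 1),
    upper = c(log_ic50 = Inf, hill = 20, bottom = 99, top = 100),
    fn = function(p) {
      y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
             (1 + exp(p[["hill"]] * (p[["log_ic50"]] - log(concs)))))
    },
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  p <- fit$par
  if (p[["bottom"]] >= p[["top"]])
    stop("degenerate dose-response fit: bottom >= top", call. = FALSE)
  fitted <- p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + exp(p[["hill"]] * (p[["log_ic50"]] - log(concs))))
  structure(list(ic50 = exp(p[["log_ic50"]]), hill = p[["hill"]],
                 top = p[["top"]], bottom = p[["bottom"]],
                 ssr = sum(fit$fvec^2), n = length(y),
                 concs = concs, inhibition = inhibition, fitted = fitted),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose_response> IC50 ", signif(x$ic50, 4), " uM, hill ",
      signif(x$hill, 3), ", top ", round(x$top, 1), ", bottom ",
      round(x$bottom, 1), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
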