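#' Single-site binding isotherm with ligand depletion
#'
#' Predicted normalized chemical shift perturbation for a protein at
#' concentration `P` titrated with ligand at total concentration `L`,
#' assuming a single binding site, fast exchange, and no free-ligand
#' approximation (ligand depletion):
#' \deqn{\Delta\delta = \Delta\delta_{max}\,
#'   \frac{([L]+[P]+K_d) - \sqrt{([L]+[P]+K_d)^2 - 4[P][L]}}{2[P]}}
#' The quadratic root is the exact bound fraction of protein, so the result
#' lies in `[0, dmax]` and reduces to the hyperbola `dmax*L/(L+kd)` as
#' `P -> 0`.
#'
#' @param P protein concentration (mM), scalar `> 0`.
#' @param L total ligand concentration (mM), scalar or vector, `>= 0`.
#' @param kd dissociation constant (mM), `> 0`.
#' @param dmax normalized CSP at saturation (ppm), `> 0`.
#' @return Predicted normalized CSP (ppm), same length as `L`.
#' @examples
#' predict_csp(P = 0.1, L = 0.1, kd = 0.1, dmax = 1)  # 0.381966
#' @export
predict_csp <- function(P, L, kd, dmax) {
  stopifnot(is.numeric(P), length(P) == 1L, is.finite(P), P > 0,
            is.numeric(L), all(is.finite(L)), all(L >= 0),
            is.numeric(kd), length(kd) == 1L, is.finite(kd), kd > 0,
            is.numeric(dmax), length(dmax) == 1L, is.finite(dmax), dmax > 0)
  s <- L + P + kd
  disc <- s^2 - 4 * P * L
  # exact roundoff can push the discriminant a hair below zero at kd -> 0
  neg <- disc < 0
  if (any(disc < -1e-9 * s^2)) {
    stop("predict_csp: negative discriminant; inputs are not a valid ",
         "single-site configuration", call. = FALSE)
  }
  disc[neg] <- 0
  dmax * (s - sqrt(disc)) / (2 * P)
}

#' Fit a per-residue dissociation constant to a CSP trajectory
#'
#' Nonlinear least squares of the ligand-depletion isotherm
#' ([predict_csp]) to one residue's normalized CSP trajectory across a
#' titration, estimating `kd` and `dmax`. Fitting uses bounded
#' Levenberg-Marquardt (`minpack.lm::nls.lm`) with `kd` in
#' `[1e-6, 1e3]` mM and `dmax` in `(0, 10 * max(delta)]` ppm.
#'
#' Starting values: `dmax0 = 1.2 * max(delta)`; `kd0` is the ligand
#' concentration at which the observed CSP first crosses half its maximum
#' (linear interpolation). If the first fit does not converge, one restart
#' is attempted from `(10 * kd0, 2 * dmax0)`. The procedure is
#' deterministic given the trajectory.
#'
#' @param trajectory data frame with columns `P` (mM), `L` (mM) and
#'   `delta` (normalized CSP, ppm), one row per titration point, including
#'   the reference point (`L = 0`, `delta = 0`).
#' @return A `residue_fit` list: `kd`, `dmax` (point estimates), `rss`
#'   (residual sum of squares, ppm^2), `n_points`, `converged`.
#' @examples
#' L <- c(0, 0.1, 0.2, 0.4, 0.7, 1.0)
#' traj <- data.frame(P = 0.1, L = L,
#'                    delta = predict_csp(0.1, L, kd = 0.5, dmax = 0.12))
#' fit_residue(traj)$kd
#' @export
fit_residue <- function(trajectory) {
  stopifnot(is.data.frame(trajectory),
            all(c("P", "L", "delta") %in% names(trajectory)))
  tr <- trajectory[is.finite(trajectory$delta) & is.finite(trajectory$L), ]
  if (length(unique(tr$L)) < 3L) {
    stop("fit_residue: need at least 3 points with distinct ligand ",
         "concentrations", call. = FALSE)
  }
  dmax_obs <- max(tr$delta)
  if (dmax_obs < 1e-6) {
    stop("fit_residue: non-binder (all CSPs below machine noise)",
         call. = FALSE)
  }

  # kd0: [L] at half-maximal observed CSP, by first linear crossing
  half <- dmax_obs / 2
  ord <- order(tr$L)
  Ls <- tr$L[ord]; ds <- tr$delta[ord]
  kd0 <- Ls[which(ds >= half)[1L]]
  i <- which(ds >= half)[1L]
  if (!is.na(i) && i > 1L && ds[i] > ds[i - 1L]) {
    kd0 <- Ls[i - 1L] +
      (half - ds[i - 1L]) / (ds[i] - ds[i - 1L]) * (Ls[i] - Ls[i - 1L])
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(Ls[Ls > 0])
  dmax0 <- 1.2 * dmax_obs

  lower <- c(kd = 1e-6, dmax = 1e-9)
  upper <- c(kd = 1e3, dmax = 10 * dmax_obs)
  resid_fn <- function(par) {
    tr$delta - predict_csp(tr$P[1L], tr$L, par[["kd"]], par[["dmax"]])
  }
  run <- function(start) {
    start <- pmin(pmax(start, lower), upper)
    minpack.lm::nls.lm(
      par = start, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxiter = 500))
  }
  fit <- run(c(kd = kd0, dmax = dmax0))
  converged <- fit$info %in% 1:3
  if (!converged) {
    fit2 <- run(c(kd = kd0 * 10, dmax = dmax0 * 2))
    if (fit2$info %in% 1:3) {
      fit <- fit2
      converged <- TRUE
    }
  }
  structure(list(kd = unname(fit$par[["kd"]]),
                 dmax = unname(fit$par[["dmax"]]),
                 rss = sum(fit$fvec^2),
                 n_points = nrow(tr),
                 converged = converged),
            class = "residue_fit")
}

#' Aggregate per-residue Kd values into a global Kd
#'
#' The global dissociation constant is the mean of the per-residue `kd`
#' estimates over converged fits of significantly perturbed resonances,
#' after a single outlier-removal pass: residues whose `kd` deviates from
#' the initial mean by more than `outlier_sd` standard deviations (SD of
#' the initial set, sample convention) are removed, and mean and SD are
#' recomputed over the retained set. If at least `lower_limit_fraction` of
#' the initial set is removed, the result is flagged as a lower limit and
#' rendered with a `">"` prefix.
#'
#' @param fits data frame of per-residue fits with columns `residue_index`,
#'   `kd` and `converged` (e.g. the `fits` component of [fit_series]), or a
#'   list of `residue_fit` objects named by residue index.
#' @param significant integer vector of residue indices classified as
#'   significantly perturbed (see [classify_significant]).
#' @param outlier_sd removal threshold in SD units (default 2).
#' @param lower_limit_fraction fraction of removals at or above which the
#'   global Kd is reported as a lower limit (default 0.5).
#' @return A `global_kd` list: `kd_mean`, `kd_sd` (mM), `retained`,
#'   `removed` (residue indices), `lower_limit` (logical), `reported`
#'   (display string, e.g. `"0.70 +/- 0.10 mM"` or `"> 0.80 mM"`).
#' @examples
#' fits <- data.frame(residue_index = 1:3, kd = c(0.6, 0.7, 0.8),
#'                    converged = TRUE)
#' aggregate_global_kd(fits, significant = 1:3)$kd_mean  # 0.7
#' @export
aggregate_global_kd <- function(fits, significant, outlier_sd = 2,
                                lower_limit_fraction = 0.5) {
  fits <- as_fit_frame(fits)
  use <- fits[fits$converged & fits$residue_index %in% significant, ]
  if (nrow(use) < 2L) {
    stop("aggregate_global_kd: need at least 2 converged fits among ",
         "significant residues", call. = FALSE)
  }
  mean0 <- mean(use$kd)
  sd0 <- stats::sd(use$kd)
  out <- abs(use$kd - mean0) > outlier_sd * sd0
  retained <- use[!out, ]
  removed <- use[out, ]
  kd_mean <- mean(retained$kd)
  kd_sd <- if (nrow(retained) > 1L) stats::sd(retained$kd) else NA_real_
  lower_limit <- nrow(removed) >= lower_limit_fraction * nrow(use)
  structure(list(kd_mean = kd_mean,
                 kd_sd = kd_sd,
                 retained = sort(retained$residue_index),
                 removed = sort(removed$residue_index),
                 lower_limit = lower_limit,
                 reported = format_global_kd(kd_mean, kd_sd, lower_limit)),
            class = "global_kd")
}

#' Render a global Kd for reporting
#'
#' @param kd_mean mean Kd (mM).
#' @param kd_sd SD of the retained Kd values (mM), may be `NA`.
#' @param lower_limit logical; if `TRUE` the value is rendered as a lower
#'   limit with a `">"` prefix (e.g. `"> 0.80 mM"`).
#' @return A display string.
#' @export
format_global_kd <- function(kd_mean, kd_sd, lower_limit = FALSE) {
  if (isTRUE(lower_limit)) {
    sprintf("> %s mM", signif(kd_mean, 2))
  } else if (is.na(kd_sd)) {
    sprintf("%s mM", signif(kd_mean, 2))
  } else {
    sprintf("%s ± %s mM", signif(kd_mean, 2), signif(kd_sd, 2))
  }
}

#' @export
print.global_kd <- function(x, ...) {
  cat("Global Kd:", x$reported, "\n")
  cat(sprintf("  retained %d residue(s), removed %d outlier(s)%s\n",
              length(x$retained), length(x$removed),
              if (x$lower_limit) " [lower limit]" else ""))
  invisible(x)
}

#' @export
print.residue_fit <- function(x, ...) {
  cat(sprintf("Residue fit: Kd = %.4g mM, dmax = %.4g ppm (rss %.3g, %d points%s)\n",
              x$kd, x$dmax, x$rss, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# Normalize a fits argument (data frame or list of residue_fit) to a frame.
as_fit_frame <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("residue_index", "kd", "converged") %in% names(fits)))
    return(fits)
  }
  stopifnot(is.list(fits), length(fits) > 0L, !is.null(names(fits)))
  data.frame(
    residue_index = as.integer(names(fits)),
    kd = vapply(fits, function(f) f$kd, numeric(1)),
    dmax = vapply(fits, function(f) f$dmax, numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    n_points = vapply(fits, function(f) f$n_points, integer(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    row.names = NULL)
}
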