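#' Normalized chemical shift perturbation
#'
#' Weighted Euclidean combination of the amide proton and nitrogen shift
#' changes between two states:
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 +
#'   (w_N\,\Delta\delta_N)^2}}
#' with nitrogen weight \eqn{w_N = 0.20} by default, the conventional
#' scaling that puts the 15N dimension on the 1H ppm scale.
#'
#' @param dH_ref,dN_ref reference-state 1H and 15N shifts (ppm).
#' @param dH_obs,dN_obs observed-state 1H and 15N shifts (ppm).
#' @param nitrogen_weight dimensionless weight on the 15N change
#'   (default 0.20).
#' @param residue optional residue label used in error messages.
#' @return Normalized CSP (ppm), `>= 0`; vectorized over the shifts.
#' @examples
#' normalized_csp(8.45, 121.3, 8.55, 121.3)        # 0.10
#' normalized_csp(8.0, 120.0, 8.03, 120.2)          # 0.05
#' @export
normalized_csp <- function(dH_ref, dN_ref, dH_obs, dN_obs,
                           nitrogen_weight = 0.20, residue = NULL) {
  stopifnot(is.numeric(nitrogen_weight), nitrogen_weight > 0)
  vals <- cbind(dH_ref, dN_ref, dH_obs, dN_obs)
  bad <- which(rowSums(!is.finite(vals)) > 0L)
  if (length(bad)) {
    who <- if (!is.null(residue)) paste(residue[bad], collapse = ", ")
           else paste("position", paste(bad, collapse = ", "))
    stop("normalized_csp: non-finite chemical shift for ", who,
         call. = FALSE)
  }
  sqrt((dH_obs - dH_ref)^2 + (nitrogen_weight * (dN_obs - dN_ref))^2)
}

#' Per-residue CSP profile between reference and endpoint
#'
#' Computes the normalized CSP of every residue between the series
#' reference point (apo state, or a pre-bound complex for ternary
#' titrations) and a chosen endpoint. Residues observed in both states get
#' status `"ok"` and a CSP value; residues broadened or missing at the
#' endpoint are carried with that status and no value; prolines (no
#' backbone amide) are carried as `"excluded"`.
#'
#' @param series a [titration_series].
#' @param endpoint_index index of the endpoint among `series$points`
#'   (default: the last point). Must differ from the reference.
#' @param nitrogen_weight passed to [normalized_csp].
#' @return A `csp_profile`: list with `series_id`, `endpoint_index`,
#'   `endpoint_ratio`, `data` (data frame: `residue_index`,
#'   `residue_label`, `delta`, `status`, `significant`), `threshold`
#'   (`NA` until [classify_significant] is applied).
#' @export
csp_profile <- function(series, endpoint_index = NULL,
                        nitrogen_weight = 0.20) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(endpoint_index)) endpoint_index <- length(series$points)
  ref_i <- series$reference_index
  if (endpoint_index == ref_i) {
    stop("csp_profile: endpoint must differ from the reference point",
         call. = FALSE)
  }
  stopifnot(endpoint_index >= 1L, endpoint_index <= length(series$points))
  ref <- series$points[[ref_i]]$peaks
  end <- series$points[[endpoint_index]]$peaks

  m <- merge(ref, end, by = c("residue_index", "residue_label"),
             suffixes = c("_ref", "_end"), all.x = TRUE)
  m <- m[order(m$residue_index), ]
  status <- ifelse(m$status_ref == "proline" | m$status_end %in% "proline",
                   "excluded",
            ifelse(m$status_ref == "observed" & m$status_end %in% "observed",
                   "ok",
            ifelse(m$status_end %in% "broadened", "broadened", "missing")))
  status[is.na(status)] <- "missing"
  ok <- status == "ok"
  if (!any(ok)) {
    stop("csp_profile: no residue observed in both reference and endpoint",
         call. = FALSE)
  }
  delta <- rep(NA_real_, nrow(m))
  delta[ok] <- normalized_csp(m$delta_H_ref[ok], m$delta_N_ref[ok],
                              m$delta_H_end[ok], m$delta_N_end[ok],
                              nitrogen_weight = nitrogen_weight,
                              residue = m$residue_label[ok])
  structure(list(
    series_id = series$series_id,
    endpoint_index = endpoint_index,
    endpoint_ratio = series$points[[endpoint_index]]$ratio,
    nitrogen_weight = nitrogen_weight,
    data = data.frame(residue_index = m$residue_index,
                      residue_label = m$residue_label,
                      delta = delta,
                      status = status,
                      significant = FALSE,
                      row.names = NULL),
    threshold = NA_real_),
    class = "csp_profile")
}

#' Classify significantly perturbed resonances (trimmed threshold)
#'
#' A resonance is significantly perturbed when its normalized CSP exceeds
#' the mean plus one standard deviation of the CSP distribution computed
#' after trimming the `trim_fraction` (default 10%) of observed residues
#' with the largest CSP. `k = ceiling(trim_fraction * n_ok)` residues are
#' trimmed (for the canonical 49 observed resonances, k = 5); ties in the
#' largest-CSP order are broken by trimming the higher residue index
#' first. Trimmed residues remain eligible to be classified significant:
#' trimming robustifies the threshold, it does not exclude binders.
#' Broadened, missing and excluded residues never enter the threshold
#' statistics.
#'
#' @param profile a `csp_profile` from [csp_profile].
#' @param trim_fraction fraction of observed residues trimmed from the top
#'   of the CSP distribution before computing mean and SD (default 0.10).
#' @return The profile with `threshold` set and the `significant` column
#'   filled (strict `delta > threshold` over `"ok"` residues).
#' @export
classify_significant <- function(profile, trim_fraction = 0.10) {
  stopifnot(inherits(profile, "csp_profile"),
            is.numeric(trim_fraction), trim_fraction >= 0,
            trim_fraction < 1)
  d <- profile$data
  ok <- which(d$status == "ok")
  n_ok <- length(ok)
  if (n_ok < 3L) {
    stop("classify_significant: need at least 3 observed residues",
         call. = FALSE)
  }
  k <- ceiling(trim_fraction * n_ok)
  # largest delta first; ties broken toward higher residue index
  ord <- ok[order(-d$delta[ok], -d$residue_index[ok])]
  kept <- if (k > 0L) ord[-seq_len(k)] else ord
  thr <- mean(d$delta[kept]) + stats::sd(d$delta[kept])
  # strict inequality, with a relative guard so roundoff in the CSP
  # computation cannot promote a residue sitting exactly at the threshold
  # (the all-equal profile must yield zero significant residues)
  d$significant <- d$status == "ok" & !is.na(d$delta) &
    d$delta > thr * (1 + 1e-9) + 1e-15
  profile$data <- d
  profile$threshold <- thr
  profile$trim_fraction <- trim_fraction
  profile$n_trimmed <- k
  profile
}

#' @export
print.csp_profile <- function(x, ...) {
  d <- x$data
  cat(sprintf("CSP profile '%s' (endpoint ratio 1:%.3g)\n",
              x$series_id, x$endpoint_ratio))
  cat(sprintf("  %d residues: %d ok, %d broadened, %d missing, %d excluded\n",
              nrow(d), sum(d$status == "ok"), sum(d$status == "broadened"),
              sum(d$status == "missing"), sum(d$status == "excluded")))
  if (!is.na(x$threshold)) {
    cat(sprintf("  threshold %.4g ppm (trim %d), %d significant\n",
                x$threshold, x$n_trimmed, sum(d$significant)))
  }
  invisible(x)
}

#' Export a CSP profile as a TSV table
#'
#' Writes `residue_index`, `residue_label`, `delta`, `status`,
#' `significant` as tab-separated text, for plotting per-residue CSP bars.
#'
#' @param profile a `csp_profile`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_csp_profile <- function(profile, path) {
  stopifnot(inherits(profile, "csp_profile"))
  utils::write.table(profile$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
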