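#' Configuration for a synthetic HSQC titration
#'
#' Defaults emulate a chromodomain-scale construct: 49 observed backbone
#' amides (a ~54-residue domain minus prolines and exchange-broadened
#' amides), protein at 0.1 mM, a peptide-style ratio ladder up to 1:10,
#' per-residue saturating CSPs of 0.05-0.25 ppm, and typical HSQC shift
#' precision (0.003 ppm 1H, 0.02 ppm 15N).
#'
#' @param true_kd generating dissociation constant (mM).
#' @param protein_conc protein concentration (mM).
#' @param ratios ligand:protein molar ratios, starting at 0 (the apo
#'   reference). Use `c(0, 0.25, 0.5, 1, 2)` for a DNA-like high-affinity
#'   ligand that saturates near 1:1.
#' @param n_residues number of residues in the observed universe.
#' @param n_responsive number of residues whose shifts respond to binding.
#' @param dmax_range range (ppm) of per-residue saturating normalized CSP,
#'   drawn uniformly.
#' @param noise_H,noise_N Gaussian noise SD (ppm) added to every observed
#'   1H / 15N shift at every point.
#' @param n_broadened number of responsive residues that broaden beyond
#'   detection at intermediate saturation (bound fraction 0.3-0.7).
#' @param direction_seeded if `TRUE` (default) each responsive residue
#'   moves along its own random unit direction in the weighted (1H,
#'   0.20 x 15N) shift plane; if `FALSE` all move along the 1H axis.
#' @param seed integer seed; identical seeds give bit-identical series.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(true_kd = 0.7,
                              protein_conc = 0.1,
                              ratios = c(0, 1, 2, 4, 7, 10),
                              n_residues = 49L,
                              n_responsive = 30L,
                              dmax_range = c(0.05, 0.25),
                              noise_H = 0.003,
                              noise_N = 0.02,
                              n_broadened = 2L,
                              direction_seeded = TRUE,
                              seed = 1L) {
  stopifnot(true_kd > 0, protein_conc > 0,
            length(ratios) >= 2L, ratios[1L] == 0, !is.unsorted(ratios),
            n_responsive <= n_residues, n_broadened <= n_responsive,
            noise_H >= 0, noise_N >= 0,
            length(dmax_range) == 2L, all(dmax_range > 0))
  structure(list(true_kd = true_kd, protein_conc = protein_conc,
                 ratios = ratios, n_residues = as.integer(n_residues),
                 n_responsive = as.integer(n_responsive),
                 dmax_range = dmax_range, noise_H = noise_H,
                 noise_N = noise_N, n_broadened = as.integer(n_broadened),
                 direction_seeded = isTRUE(direction_seeded),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a fast-exchange HSQC titration series
#'
#' Forward model: reference shifts are drawn uniformly within realistic
#' amide windows (1H 6.5-10.5 ppm, 15N 103-133 ppm). Each responsive
#' residue is assigned a saturating CSP `dmax_i` and a fixed unit
#' direction in the weighted (1H, 0.20 x 15N) plane; at ligand
#' concentration `L` its peak moves along that direction by
#' `predict_csp(P, L, true_kd, dmax_i)`, so the normalized CSP recovered
#' downstream equals the scalar isotherm exactly (before noise).
#' Non-responsive residues move only by noise. i.i.d. Gaussian noise is
#' added to every observed shift at every point, including the reference.
#' `n_broadened` responsive residues are marked broadened (peak lost) at
#' points where their bound fraction lies in `[0.3, 0.7]`, emulating
#' intermediate-exchange line broadening at mid-titration.
#'
#' @param config a [simulation_config].
#' @return List with `series` (a [titration_series]) and `ground_truth`
#'   (data frame: `residue_index`, `responsive`, `kd`, `dmax`,
#'   `broadened`).
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  c0 <- config
  set.seed(c0$seed)
  n <- c0$n_residues
  idx <- seq_len(n)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "Q", "R", "S", "T", "V", "W", "Y")  # no proline: no amide in HSQC
  labels <- paste0(sample(aa, n, replace = TRUE), idx)
  ref_H <- stats::runif(n, 6.5, 10.5)
  ref_N <- stats::runif(n, 103, 133)
  responsive <- sort(sample(idx, c0$n_responsive))
  dmax <- stats::runif(c0$n_responsive, c0$dmax_range[1L], c0$dmax_range[2L])
  theta <- if (c0$direction_seeded) {
    stats::runif(c0$n_responsive, 0, 2 * pi)
  } else {
    rep(0, c0$n_responsive)
  }
  broadened <- if (c0$n_broadened > 0L) {
    sort(sample(responsive, c0$n_broadened))
  } else {
    integer(0)
  }
  P <- c0$protein_conc
  L <- c0$ratios * P

  dH_sat <- dN_sat <- rep(0, n)
  dH_sat[responsive] <- dmax * cos(theta)
  dN_sat[responsive] <- dmax * sin(theta) / 0.20

  points <- lapply(seq_along(L), function(j) {
    fb <- if (L[j] > 0) predict_csp(P, L[j], c0$true_kd, 1) else 0
    H <- ref_H + fb * dH_sat + stats::rnorm(n, 0, c0$noise_H)
    N <- ref_N + fb * dN_sat + stats::rnorm(n, 0, c0$noise_N)
    status <- rep("observed", n)
    if (length(broadened) && fb >= 0.3 && fb <= 0.7) {
      status[broadened] <- "broadened"
      H[broadened] <- NA_real_
      N[broadened] <- NA_real_
    }
    list(ratio = c0$ratios[j], protein_conc = P, ligand_conc = L[j],
         peaks = data.frame(residue_index = idx, residue_label = labels,
                            delta_H = H, delta_N = N, status = status))
  })
  truth <- data.frame(residue_index = idx,
                      residue_label = labels,
                      responsive = idx %in% responsive,
                      kd = ifelse(idx %in% responsive, c0$true_kd, NA_real_),
                      dmax = NA_real_,
                      broadened = idx %in% broadened)
  truth$dmax[responsive] <- dmax
  list(series = titration_series(
         series_id = sprintf("sim_kd%g_seed%d", c0$true_kd, c0$seed),
         ligand_name = "synthetic ligand", points = points,
         reference_index = 1L),
       ground_truth = truth)
}

#' Simulate a ternary titration from a pre-bound reference
#'
#' Same forward model as [simulate_titration], but the reference state
#' represents the protein pre-bound to a first ligand (e.g. a short DNA
#' duplex) and the titrant is the second ligand. Because a fast-exchange
#' CSP trajectory measures displacement from whatever state the reference
#' spectrum captures, downstream profiling and fitting proceed unchanged,
#' with the reference index at the complex point; the recovered Kd is the
#' titrant's affinity for the pre-bound complex.
#'
#' @param config a [simulation_config]; `true_kd` is the titrant's
#'   affinity for the pre-formed complex.
#' @param reference_is_complex if `FALSE`, reduces exactly to
#'   [simulate_titration].
#' @return As [simulate_titration].
#' @export
simulate_ternary <- function(config, reference_is_complex = TRUE) {
  out <- simulate_titration(config)
  if (!isTRUE(reference_is_complex)) {
    return(out)
  }
  out$series$series_id <- paste0(out$series$series_id, "_ternary")
  out$series$ligand_name <- "synthetic titrant into pre-bound complex"
  out$series$reference_is_complex <- TRUE
  out
}

#' Write a simulated series as peak-list files plus manifest
#'
#' Emits one Sparky-style peak list per titration point, a YAML manifest
#' readable by [read_series_manifest], and (optionally) the ground truth
#' as JSON.
#'
#' @param sim result of [simulate_titration] / [simulate_ternary], or a
#'   bare [titration_series].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_series <- function(sim, dir) {
  series <- if (inherits(sim, "titration_series")) sim else sim$series
  truth <- if (inherits(sim, "titration_series")) NULL else sim$ground_truth
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pts <- lapply(seq_along(series$points), function(j) {
    pt <- series$points[[j]]
    f <- sprintf("point_%02d.list", j)
    write_peaklist(pt$peaks, file.path(dir, f))
    broad <- pt$peaks$residue_label[pt$peaks$status == "broadened"]
    out <- list(file = f, ratio = pt$ratio,
                ligand_conc_mM = pt$ligand_conc)
    if (length(broad)) out$broadened <- as.list(broad)
    out
  })
  prolines <- series$points[[1L]]$peaks$residue_label[
    series$points[[1L]]$peaks$status == "proline"]
  man <- list(series_id = series$series_id,
              ligand_name = series$ligand_name,
              protein_conc_mM = series$points[[1L]]$protein_conc,
              temperature_C = series$temperature,
              reference = series$reference_index,
              points = pts)
  if (length(prolines)) man$prolines <- as.list(prolines)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, manifest, precision = 17)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         digits = NA, na = "null")
  }
  invisible(manifest)
}
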