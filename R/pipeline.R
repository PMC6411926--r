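#' Full CSP-to-global-Kd analysis of a titration series
#'
#' Composition of the pipeline stages on an in-memory series:
#' [csp_profile] at the endpoint, [classify_significant] with the trimmed
#' threshold, [fit_residue] on each significant residue's trajectory
#' across all points, and [aggregate_global_kd] with the outlier-removal
#' and lower-limit rules.
#'
#' @param series a [titration_series].
#' @param endpoint_index endpoint for the significance profile (default:
#'   last point).
#' @param nitrogen_weight 15N weight in the normalized CSP
#'   (default 0.20).
#' @param trim_fraction top-trim fraction for the significance threshold
#'   (default 0.10).
#' @param outlier_sd,lower_limit_fraction passed to
#'   [aggregate_global_kd].
#' @param verbose emit progress messages (threshold, counts) to stderr.
#' @return List with `profile` (classified `csp_profile`), `fits`
#'   (data frame: residue, endpoint CSP, significance, kd, dmax, rss,
#'   n_points, converged, retained) and `global` (a `global_kd`).
#' @export
fit_series <- function(series, endpoint_index = NULL,
                       nitrogen_weight = 0.20, trim_fraction = 0.10,
                       outlier_sd = 2, lower_limit_fraction = 0.5,
                       verbose = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  profile <- csp_profile(series, endpoint_index,
                         nitrogen_weight = nitrogen_weight)
  profile <- classify_significant(profile, trim_fraction = trim_fraction)
  d <- profile$data
  if (verbose) {
    message(sprintf("CSP threshold %.4g ppm; %d of %d observed residues significant",
                    profile$threshold, sum(d$significant),
                    sum(d$status == "ok")))
  }
  sig <- d$residue_index[d$significant]
  if (length(sig) < 2L) {
    stop("fit_series: fewer than 2 significantly perturbed residues; ",
         "no global Kd can be estimated", call. = FALSE)
  }
  fits <- lapply(sig, function(i) fit_residue(residue_trajectory(series, i)))
  names(fits) <- sig
  fit_df <- as_fit_frame(fits)

  global <- aggregate_global_kd(fit_df, significant = sig,
                                outlier_sd = outlier_sd,
                                lower_limit_fraction = lower_limit_fraction)
  if (verbose) {
    message(sprintf("Global Kd %s (%d retained, %d removed%s)",
                    global$reported, length(global$retained),
                    length(global$removed),
                    if (global$lower_limit) ", lower limit" else ""))
  }
  table <- merge(
    data.frame(residue_index = d$residue_index,
               residue_label = d$residue_label,
               delta_endpoint = d$delta,
               status = d$status,
               significant = d$significant),
    fit_df, by = "residue_index", all.x = TRUE)
  table$retained <- table$residue_index %in% global$retained
  table <- table[order(table$residue_index), ]
  rownames(table) <- NULL
  list(profile = profile, fits = table, global = global)
}

#' Extract one residue's CSP trajectory across a series
#'
#' Normalized CSP of residue `residue_index` at every titration point
#' relative to the series reference, paired with the per-point protein
#' and ligand concentrations. Points where the residue is not observed
#' (broadened/missing) are dropped.
#'
#' @param series a [titration_series].
#' @param residue_index residue sequence position.
#' @param nitrogen_weight 15N weight (default 0.20).
#' @return Data frame with columns `P`, `L` (mM) and `delta` (ppm),
#'   suitable for [fit_residue].
#' @export
residue_trajectory <- function(series, residue_index,
                               nitrogen_weight = 0.20) {
  ref <- series$points[[series$reference_index]]$peaks
  r0 <- ref[ref$residue_index == residue_index, ]
  if (nrow(r0) != 1L || r0$status != "observed") {
    stop("residue_trajectory: residue ", residue_index,
         " not observed in the reference point", call. = FALSE)
  }
  rows <- lapply(series$points, function(pt) {
    r <- pt$peaks[pt$peaks$residue_index == residue_index, ]
    if (nrow(r) != 1L || r$status != "observed") return(NULL)
    data.frame(P = pt$protein_conc, L = pt$ligand_conc,
               delta = normalized_csp(r0$delta_H, r0$delta_N,
                                      r$delta_H, r$delta_N,
                                      nitrogen_weight = nitrogen_weight))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the titration-fitting pipeline on a manifest (CLI core)
#'
#' Reads a series manifest, runs [fit_series], writes the per-residue
#' table and global summary with [write_results], plus a provenance
#' block (`run_config.json`: configuration echo and package version)
#' sufficient to reproduce the run.
#'
#' @param manifest path to a YAML series manifest
#'   (see [read_series_manifest]).
#' @param out output directory.
#' @param endpoint_ratio choose the endpoint as the point with this
#'   ligand:protein ratio (default: the last point).
#' @param nitrogen_weight,trim_fraction,outlier_sd,lower_limit_fraction
#'   analysis parameters; defaults 0.20, 0.10, 2, 0.5.
#' @param quiet suppress progress messages.
#' @return Invisibly, the [fit_series] result.
#' @export
run_fit <- function(manifest, out, endpoint_ratio = NULL,
                    nitrogen_weight = 0.20, trim_fraction = 0.10,
                    outlier_sd = 2, lower_limit_fraction = 0.5,
                    quiet = FALSE) {
  series <- read_series_manifest(manifest)
  endpoint_index <- NULL
  if (!is.null(endpoint_ratio)) {
    ratios <- vapply(series$points, function(p) p$ratio, numeric(1))
    endpoint_index <- which(abs(ratios - endpoint_ratio) < 1e-9)[1L]
    if (is.na(endpoint_index)) {
      stop("run_fit: no titration point at ratio 1:", endpoint_ratio,
           call. = FALSE)
    }
  }
  res <- fit_series(series, endpoint_index = endpoint_index,
                    nitrogen_weight = nitrogen_weight,
                    trim_fraction = trim_fraction,
                    outlier_sd = outlier_sd,
                    lower_limit_fraction = lower_limit_fraction,
                    verbose = !quiet)
  write_results(res$fits, res$global, out)
  write_provenance(out, list(
    command = "fit", manifest = manifest, out = out,
    endpoint_ratio = endpoint_ratio, nitrogen_weight = nitrogen_weight,
    trim_fraction = trim_fraction, outlier_sd = outlier_sd,
    lower_limit_fraction = lower_limit_fraction))
  invisible(res)
}

#' Simulate a titration and write it to disk (CLI core)
#'
#' @param out output directory.
#' @param kd_mM generating Kd (mM).
#' @param seed integer seed.
#' @param ... further arguments to [simulation_config].
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(out, kd_mM = 0.7, seed = 1L, ...) {
  cfg <- simulation_config(true_kd = kd_mM, seed = seed, ...)
  sim <- simulate_titration(cfg)
  manifest <- write_series(sim, out)
  write_provenance(out, c(list(command = "simulate", out = out),
                          unclass(cfg)))
  invisible(manifest)
}

#' Run the peak-overlap analysis on BED files (CLI core)
#'
#' Computes pairwise maxgap overlap fractions for 2 or 3 BED files and,
#' for 3 sets, the per-anchor Venn region counts.
#'
#' @param beds character vector of 2 or 3 BED paths.
#' @param out output directory.
#' @param max_gap maximum gap in bp (default 150).
#' @param same_strand require matching strands (default `TRUE`).
#' @return Invisibly, list with `pairwise` (data frame) and `venn`
#'   (data frame or `NULL`).
#' @export
run_overlap <- function(beds, out, max_gap = 150, same_strand = TRUE) {
  stopifnot(length(beds) %in% 2:3)
  sets <- lapply(beds, read_bed)
  nm <- vapply(sets, function(s) s$name, "")
  if (anyDuplicated(nm)) {
    nm <- make.unique(nm)
    for (i in seq_along(sets)) sets[[i]]$name <- nm[i]
  }
  pairs <- utils::combn(seq_along(sets), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    rbind(
      pair_row(sets[[i]], sets[[j]], max_gap, same_strand),
      pair_row(sets[[j]], sets[[i]], max_gap, same_strand))
  }))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.table(pairwise, file.path(out, "pairwise_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  venn <- NULL
  if (length(sets) == 3L) {
    venn <- multiway_overlap(sets, max_gap = max_gap,
                             same_strand = same_strand)
    utils::write.table(venn, file.path(out, "venn_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_provenance(out, list(command = "overlap", beds = beds, out = out,
                             max_gap = max_gap, same_strand = same_strand))
  invisible(list(pairwise = pairwise, venn = venn))
}

pair_row <- function(q, s, max_gap, same_strand) {
  o <- overlap_fraction(q, s, max_gap = max_gap, same_strand = same_strand)
  data.frame(query = q$name, subject = s$name, n_query = o$n_query,
             n_overlapping = o$n_overlapping, fraction = o$fraction)
}

write_provenance <- function(out, config) {
  prov <- list(
    package = "cspfit",
    version = as.character(utils::packageVersion("cspfit")),
    config = config)
  jsonlite::write_json(prov, file.path(out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(NULL)
}
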