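#' Read an assigned Sparky-style peak list
#'
#' Parses a whitespace/tab-separated peak list with one row per assigned
#' backbone amide: an assignment label (e.g. `"V10N-H"`) followed by two
#' chemical shift columns. In the default Sparky column order the first
#' shift is 15N (w1) and the second 1H (w2).
#'
#' Assignment labels are parsed as one-letter residue code + sequence
#' position (an optional atom suffix such as `N-H` or `N-HN` is ignored).
#' Rows whose label cannot be parsed are kept with status `"unassigned"`
#' and trigger a warning; malformed numeric fields and duplicate residue
#' indices are errors naming the offending line.
#'
#' @param path file path.
#' @param format peak-list dialect; only `"sparky_tsv"` is supported.
#' @param shift_order order of the two shift columns, `c("N", "H")`
#'   (Sparky w1/w2 default) or `c("H", "N")`.
#' @return Data frame of resonance peaks: `residue_index`,
#'   `residue_label`, `delta_H`, `delta_N` (ppm), `status`
#'   (`"observed"` or `"unassigned"`).
#' @export
read_peaklist <- function(path, format = c("sparky_tsv"),
                          shift_order = c("N", "H")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  shift_order <- match.arg(paste(shift_order, collapse = ""),
                           c("NH", "HN"))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines) &
    !grepl("^\\s*Assignment\\b", lines, ignore.case = TRUE)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(empty_peaks())
  }
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    stop("read_peaklist: line ", lineno[which(n_fields < 3L)[1L]],
         " has fewer than 3 fields", call. = FALSE)
  }
  label <- vapply(fields, `[[`, "", 1L)
  w1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  w2 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad_num <- which(is.na(w1) | is.na(w2))
  if (length(bad_num)) {
    stop("read_peaklist: malformed numeric field on line ",
         lineno[bad_num[1L]], call. = FALSE)
  }
  parsed <- parse_assignment(label)
  if (anyNA(parsed$residue_index)) {
    warning("read_peaklist: unparseable assignment label(s): ",
            paste(label[is.na(parsed$residue_index)], collapse = ", "),
            call. = FALSE)
  }
  dup <- parsed$residue_index[!is.na(parsed$residue_index)]
  dup <- dup[duplicated(dup)]
  if (length(dup)) {
    stop("read_peaklist: duplicate residue index ", dup[1L], " in ", path,
         call. = FALSE)
  }
  if (shift_order == "NH") {
    dN <- w1; dH <- w2
  } else {
    dH <- w1; dN <- w2
  }
  data.frame(residue_index = parsed$residue_index,
             residue_label = parsed$residue_label,
             delta_H = dH, delta_N = dN,
             status = ifelse(is.na(parsed$residue_index),
                             "unassigned", "observed"),
             row.names = NULL)
}

parse_assignment <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)", label))
  idx <- vapply(m, function(g) {
    if (length(g) == 3L) as.integer(g[[3L]]) else NA_integer_
  }, integer(1))
  lab <- ifelse(is.na(idx), label,
                paste0(toupper(substr(label, 1L, 1L)), idx))
  list(residue_index = idx, residue_label = lab)
}

empty_peaks <- function() {
  data.frame(residue_index = integer(0), residue_label = character(0),
             delta_H = numeric(0), delta_N = numeric(0),
             status = character(0))
}

#' Write a peak list in Sparky column order
#'
#' Only observed resonances are written (broadened/missing residues have
#' no peak to write; prolines have no backbone amide). Shifts are
#' serialized with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param peaks resonance peak data frame (see [read_peaklist]).
#' @param path output path.
#' @param shift_order column order to write, default Sparky `c("N", "H")`.
#' @return The path, invisibly.
#' @export
write_peaklist <- function(peaks, path, shift_order = c("N", "H")) {
  shift_order <- match.arg(paste(shift_order, collapse = ""), c("NH", "HN"))
  obs <- peaks[peaks$status == "observed", ]
  lines <- c("# Assignment  w1(15N)  w2(1H)")
  if (shift_order == "HN") lines <- c("# Assignment  w1(1H)  w2(15N)")
  a <- if (shift_order == "NH") obs$delta_N else obs$delta_H
  b <- if (shift_order == "NH") obs$delta_H else obs$delta_N
  lines <- c(lines, sprintf("%sN-H\t%.17g\t%.17g", obs$residue_label, a, b))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a titration series
#'
#' @param series_id identifier string.
#' @param ligand_name name of the titrated ligand.
#' @param points list of titration points, each a list with `ratio`
#'   (ligand:protein molar ratio), `protein_conc` (mM), `ligand_conc`
#'   (mM) and `peaks` (resonance peak data frame covering the full
#'   residue universe, with per-residue `status`).
#' @param reference_index index into `points` as supplied, naming the
#'   point treated as the unbound reference state; it is remapped when the
#'   points are sorted by ligand concentration. For ternary titrations the
#'   reference is the pre-bound complex at zero added titrant.
#' @param temperature acquisition temperature, degrees C (metadata).
#' @return A `titration_series` object.
#' @export
titration_series <- function(series_id, ligand_name, points,
                             reference_index = 1L, temperature = 25) {
  stopifnot(is.character(series_id), length(points) >= 1L)
  lig <- vapply(points, function(p) p$ligand_conc, numeric(1))
  prot <- vapply(points, function(p) p$protein_conc, numeric(1))
  stopifnot(all(prot > 0), all(lig >= 0))
  ord <- order(lig)
  points <- points[ord]
  reference_index <- match(reference_index, ord)
  if (is.na(reference_index)) {
    stop("titration_series: reference point not among points",
         call. = FALSE)
  }
  if (lig[ord][reference_index] > min(lig)) {
    stop("titration_series: reference point must have the minimum ",
         "ligand concentration", call. = FALSE)
  }
  structure(list(series_id = series_id, ligand_name = ligand_name,
                 points = points, reference_index = reference_index,
                 temperature = temperature),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  lig <- vapply(x$points, function(p) p$ligand_conc, numeric(1))
  cat(sprintf("Titration series '%s': %s, %d points (ligand 0-%.3g mM), %d residues\n",
              x$series_id, x$ligand_name, length(x$points), max(lig),
              nrow(x$points[[1L]]$peaks)))
  cat(sprintf("  reference point %d, %g degC\n", x$reference_index,
              x$temperature))
  invisible(x)
}

#' Read a titration series manifest
#'
#' The manifest is a YAML document describing one titration series:
#' \preformatted{
#' series_id: h3k27me3
#' ligand_name: H3K27me3
#' protein_conc_mM: 0.1
#' temperature_C: 25
#' reference: 1          # 1-based index into the points list below
#' prolines: [P36]       # optional, no backbone amide
#' points:
#'   - {file: point1.list, ratio: 0}
#'   - {file: point2.list, ratio: 1, broadened: [V10]}
#' }
#' Each point needs `file` plus `ratio` and/or `ligand_conc_mM`
#' (`ligand_conc_uM` / `protein_conc_uM` are accepted and converted).
#' Points are sorted by ligand concentration ascending. Residues present
#' in the reference list but absent from a later point are inserted with
#' status `"broadened"` when the point's `broadened` list names them,
#' `"missing"` otherwise.
#'
#' @param path manifest path; peak-list files are resolved relative to it.
#' @return A [titration_series].
#' @export
read_series_manifest <- function(path) {
  stopifnot(file.exists(path))
  man <- yaml::read_yaml(path)
  dir <- dirname(path)
  req <- c("series_id", "points")
  if (!all(req %in% names(man))) {
    stop("read_series_manifest: manifest must contain ",
         paste(setdiff(req, names(man)), collapse = ", "), call. = FALSE)
  }
  if (is.null(man$reference)) {
    stop("read_series_manifest: no reference point listed", call. = FALSE)
  }
  p_mM <- conc_mM(man, "protein_conc")
  points <- lapply(seq_along(man$points), function(i) {
    pt <- man$points[[i]]
    prot <- conc_mM(pt, "protein_conc")
    if (is.null(prot)) prot <- p_mM
    if (is.null(prot)) {
      stop("read_series_manifest: no protein concentration for point ", i,
           call. = FALSE)
    }
    lig <- conc_mM(pt, "ligand_conc")
    if (is.null(lig) && is.null(pt$ratio)) {
      stop("read_series_manifest: point ", i,
           " has neither ratio nor ligand_conc", call. = FALSE)
    }
    if (is.null(lig)) lig <- pt$ratio * prot
    ratio <- if (!is.null(pt$ratio)) pt$ratio else lig / prot
    if (is.null(pt$file)) {
      stop("read_series_manifest: point ", i, " has no peak-list file",
           call. = FALSE)
    }
    f <- file.path(dir, pt$file)
    if (!file.exists(f)) {
      stop("read_series_manifest: peak-list file for point ", i,
           " not found: ", pt$file, call. = FALSE)
    }
    list(ratio = ratio, protein_conc = prot, ligand_conc = lig,
         peaks = read_peaklist(f),
         broadened = as.character(unlist(pt$broadened)))
  })
  ref_i <- as.integer(man$reference)
  if (is.na(ref_i) || ref_i < 1L || ref_i > length(points)) {
    stop("read_series_manifest: reference point ", man$reference,
         " not listed", call. = FALSE)
  }
  # complete each point against the reference residue universe
  universe <- points[[ref_i]]$peaks[, c("residue_index", "residue_label")]
  prolines <- as.character(unlist(man$prolines))
  points <- lapply(points, function(pt) {
    pk <- pt$peaks
    absent <- universe[!universe$residue_index %in% pk$residue_index, ]
    if (nrow(absent)) {
      pk <- rbind(pk, data.frame(
        residue_index = absent$residue_index,
        residue_label = absent$residue_label,
        delta_H = NA_real_, delta_N = NA_real_,
        status = ifelse(absent$residue_label %in% pt$broadened,
                        "broadened", "missing")))
    }
    if (length(prolines)) {
      pp <- parse_assignment(prolines)
      new <- !pp$residue_index %in% pk$residue_index
      if (any(new)) {
        pk <- rbind(pk, data.frame(
          residue_index = pp$residue_index[new],
          residue_label = pp$residue_label[new],
          delta_H = NA_real_, delta_N = NA_real_, status = "proline"))
      }
    }
    pt$peaks <- pk[order(pk$residue_index), ]
    pt$broadened <- NULL
    pt
  })
  titration_series(
    series_id = man$series_id,
    ligand_name = if (!is.null(man$ligand_name)) man$ligand_name else "",
    points = points, reference_index = ref_i,
    temperature = if (!is.null(man$temperature_C)) man$temperature_C else 25)
}

# Pull a concentration field in mM, accepting a _uM variant.
conc_mM <- function(x, stem) {
  if (!is.null(x[[paste0(stem, "_mM")]])) return(x[[paste0(stem, "_mM")]])
  if (!is.null(x[[paste0(stem, "_uM")]])) {
    return(x[[paste0(stem, "_uM")]] / 1000)
  }
  NULL
}

#' Write per-residue fit table and global-Kd summary
#'
#' Writes `residue_fits.tsv` (residue, endpoint CSP, significance flag,
#' Kd, dmax, residual sum of squares, retained flag) and `global_kd.json`
#' (global Kd, SD, counts, lower-limit flag, display string; a
#' lower-limit Kd is rendered with a `">"` prefix). Numbers carry at
#' least 6 significant digits.
#'
#' @param fits per-residue results data frame (the `fits` component of
#'   [fit_series]).
#' @param global_result a `global_kd` from [aggregate_global_kd].
#' @param path output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_results <- function(fits, global_result, path) {
  stopifnot(is.data.frame(fits), nrow(fits) > 0L,
            inherits(global_result, "global_kd"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_results: cannot create directory ", path,
                  call. = FALSE)
  }
  tsv <- file.path(path, "residue_fits.tsv")
  json <- file.path(path, "global_kd.json")
  out <- fits
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("residue_index", "n_points")
  out[num] <- lapply(out[num], function(v) signif(v, 8))
  tryCatch(
    utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"),
    error = function(e) stop("write_results: cannot write ", tsv, ": ",
                             conditionMessage(e), call. = FALSE))
  summary <- list(
    kd_mean_mM = global_result$kd_mean,
    kd_sd_mM = global_result$kd_sd,
    n_retained = length(global_result$retained),
    n_removed = length(global_result$removed),
    retained = as.integer(global_result$retained),
    removed = as.integer(global_result$removed),
    lower_limit = global_result$lower_limit,
    reported = global_result$reported)
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(table = tsv, summary = json))
}

#' Read back a results directory written by [write_results]
#'
#' @param path directory containing `residue_fits.tsv` and
#'   `global_kd.json`.
#' @return List with `fits` (data frame) and `summary` (list).
#' @export
read_results <- function(path) {
  list(fits = utils::read.delim(file.path(path, "residue_fits.tsv")),
       summary = jsonlite::read_json(file.path(path, "global_kd.json"),
                                     simplifyVector = TRUE))
}
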