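#' Construct a spectrum object
#'
#' @param wavelengths strictly increasing grid, nm.
#' @param intensities intensities (mdeg for CD, arbitrary units for
#'   fluorescence); same length as `wavelengths`.
#' @param kind `"cd"`, `"fluorescence_emission"` or `"fluorescence_excitation"`.
#' @param condition ionic condition: `"no_ion"`, `"K"` or `"Li"`.
#' @param ion_mM ion concentration, mM (0 for `no_ion`).
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, intensities, kind = "cd",
                     condition = "no_ion", ion_mM = 0) {
  kind <- match.arg(kind, c("cd", "fluorescence_emission", "fluorescence_excitation"))
  condition <- match.arg(condition, c("no_ion", "K", "Li"))
  if (length(wavelengths) != length(intensities) || length(wavelengths) < 2L) {
    stop("wavelengths and intensities must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (ion_mM < 0) stop("ion_mM must be >= 0", call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 kind = kind, condition = condition, ion_mM = ion_mM),
            class = "spectrum")
}

#' Read a spectrum CSV export
#'
#' Two-column CSV with header `wavelength_nm,intensity`.
#'
#' @param path CSV path.
#' @inheritParams spectrum
#' @return a [spectrum()] object.
#' @export
read_spectrum <- function(path, kind = "cd", condition = "no_ion", ion_mM = 0) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "intensity")
  if (!all(need %in% names(raw))) {
    stop(sprintf("spectrum CSV must have header %s", paste(need, collapse = ",")),
         call. = FALSE)
  }
  spectrum(raw$wavelength_nm, raw$intensity, kind, condition, ion_mM)
}

# Strongest signature amplitude inside a peak and a trough window: the
# signature is only as strong as its weaker band.
.signature_strength <- function(s, peak_window, trough_window) {
  pk <- s$intensities[s$wavelengths >= peak_window[1] & s$wavelengths <= peak_window[2]]
  tr <- s$intensities[s$wavelengths >= trough_window[1] & s$wavelengths <= trough_window[2]]
  min(max(pk), -min(tr))
}

#' Classify G-quadruplex topology from a CD spectrum
#'
#' A parallel quadruplex shows a positive CD band near 265 nm with a trough
#' near 240 nm; an antiparallel quadruplex a positive band near 295 nm with a
#' trough near 260 nm. Each signature is scored as the smaller of its peak and
#' trough amplitudes inside +/-5 nm windows and compared against a noise floor
#' of 3x the median absolute deviation of the 330-350 nm tail (where G4 CD
#' signals have decayed). Both signatures above the floor classify as
#' `mixed`; neither as `none`. Invariant under uniform positive scaling.
#'
#' @param s a [spectrum()] of kind `"cd"` covering at least 230-300 nm.
#' @return one of `"parallel"`, `"antiparallel"`, `"mixed"`, `"none"`.
#' @export
classify_cd_topology <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  wl <- s$wavelengths
  if (min(wl) > 230 || max(wl) < 300) {
    stop("CD spectrum must cover at least 230-300 nm", call. = FALSE)
  }
  tail_vals <- s$intensities[wl >= 330 & wl <= 350]
  floor_amp <- if (length(tail_vals) >= 3L) 3 * stats::mad(tail_vals, center = 0) else 0
  par_amp <- .signature_strength(s, c(260, 270), c(235, 245))
  anti_amp <- .signature_strength(s, c(290, 300), c(255, 265))
  par_ok <- par_amp > floor_amp && par_amp > 0
  anti_ok <- anti_amp > floor_amp && anti_amp > 0
  if (par_ok && anti_ok) "mixed"
  else if (par_ok) "parallel"
  else if (anti_ok) "antiparallel"
  else "none"
}

#' Fluorescence fold enhancement over blank
#'
#' Ratio of group means; replicate values are retained for significance
#' testing. Scale-covariant: scaling both groups by the same factor leaves the
#' fold unchanged.
#'
#' @param sample_replicates,blank_replicates numeric vectors (>= 1 value
#'   each); the blank mean must be positive.
#' @return list with `sample_mean`, `blank_mean`, `fold`, `sample_replicates`,
#'   `blank_replicates`.
#' @export
fold_enhancement <- function(sample_replicates, blank_replicates) {
  if (!length(sample_replicates) || !length(blank_replicates)) {
    stop("both groups need at least one replicate", call. = FALSE)
  }
  bm <- mean(blank_replicates)
  if (bm <= 0) stop("blank mean must be > 0", call. = FALSE)
  sm <- mean(sample_replicates)
  list(sample_mean = sm, blank_mean = bm, fold = sm / bm,
       sample_replicates = sample_replicates, blank_replicates = blank_replicates)
}

.p_stars <- function(p) {
  if (p <= 1e-4) "***" else if (p <= 1e-3) "**" else if (p <= 0.05) "*" else "ns"
}

#' Unpaired two-sample comparison with significance stars
#'
#' Welch (unequal-variance) unpaired t-test by default, pooled-variance mode
#' available; two-sided p-value. Stars follow the convention `*` p <= 0.05,
#' `**` p <= 0.001, `***` p <= 0.0001. Two groups with zero variance and
#' equal means return `t = 0, p = 1`.
#'
#' @param group_a,group_b numeric vectors with >= 2 replicates each.
#' @param var_equal use pooled variance (default FALSE = Welch).
#' @return list with `t_statistic`, `p_value`, `stars`.
#' @export
compare_conditions <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 replicates", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t_statistic = 0, p_value = 1, stars = "ns"))
    }
    stop("degenerate comparison: zero variance in both groups with unequal means",
         call. = FALSE)
  }
  fit <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t_statistic = unname(fit$statistic), p_value = fit$p.value,
       stars = .p_stars(fit$p.value))
}

#' Reverse-transcriptase stop fractions per lane
#'
#' The stop fraction `stop / (stop + full_length)` quantifies how often the
#' reverse transcriptase halted at a stable quadruplex relative to reading
#' through; it is comparable across ionic conditions. A lane with both
#' intensities zero is undefined and raises an error naming the lane.
#'
#' @param band_table data.frame with columns `lane`, `condition`,
#'   `full_length_intensity`, `stop_intensity` (schema `band_intensities`).
#' @return `band_table` with a `stop_fraction` column in `[0, 1]`.
#' @export
stop_fraction <- function(band_table) {
  if (any(band_table$full_length_intensity < 0 | band_table$stop_intensity < 0)) {
    stop("band intensities must be >= 0", call. = FALSE)
  }
  denom <- band_table$full_length_intensity + band_table$stop_intensity
  dead <- which(denom == 0)
  if (length(dead)) {
    stop(sprintf("stop fraction undefined for lane '%s': both intensities are zero",
                 band_table$lane[dead[1]]), call. = FALSE)
  }
  band_table$stop_fraction <- band_table$stop_intensity / denom
  band_table
}

#' Assemble a machine-readable assay report
#'
#' @param cd_spectra named list of [spectrum()] objects (CD).
#' @param tht_table data.frame with columns `group`, `replicate`,
#'   `intensity_488`; `blank_group` names the blank.
#' @param band_table RT-stop band table (see [stop_fraction()]), or NULL.
#' @param blank_group group label of the dye-only blank.
#' @return nested list with CD classifications, ThT folds with significance
#'   stars versus blank, and RT-stop fractions; serialize with
#'   [jsonlite::write_json()].
#' @export
assay_report <- function(cd_spectra = NULL, tht_table = NULL, band_table = NULL,
                         blank_group = "blank") {
  report <- list()
  if (!is.null(cd_spectra)) {
    report$cd <- lapply(cd_spectra, classify_cd_topology)
  }
  if (!is.null(tht_table)) {
    blank <- tht_table$intensity_488[tht_table$group == blank_group]
    if (!length(blank)) stop(sprintf("no '%s' group in ThT table", blank_group),
                             call. = FALSE)
    groups <- setdiff(unique(tht_table$group), blank_group)
    report$tht <- lapply(stats::setNames(groups, groups), function(g) {
      vals <- tht_table$intensity_488[tht_table$group == g]
      fe <- fold_enhancement(vals, blank)
      cmp <- if (length(vals) >= 2L && length(blank) >= 2L) {
        compare_conditions(vals, blank)
      } else NULL
      list(fold = fe$fold, n = length(vals),
           stars = if (is.null(cmp)) NA_character_ else cmp$stars,
           p_value = if (is.null(cmp)) NA_real_ else cmp$p_value)
    })
  }
  if (!is.null(band_table)) {
    sf <- stop_fraction(band_table)
    report$rt_stop <- lapply(seq_len(nrow(sf)), function(i) {
      list(lane = sf$lane[i], condition = sf$condition[i],
           stop_fraction = sf$stop_fraction[i])
    })
  }
  report
}
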