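#' Carbon-normalized substrate concentration
#'
#' Concentration (mM) of a substrate delivering a target carbon concentration
#' (default 16 mM C): `target / carbons`, rounded half away from zero to two
#' decimals — e.g. 16 mM methanol (1 C), 2.29 mM p-hydroxybenzoate (7 C),
#' 2 mM vanillate (8 C), 1.6 mM ferulate (10 C).
#'
#' @param carbons Carbons per molecule (positive integer).
#' @param target_mM Target carbon concentration in mM (default 16).
#' @return Concentration in mM, 2 decimals.
#' @export
substrate_concentration <- function(carbons, target_mM = 16) {
  if (!is.numeric(carbons) || carbons < 1 || carbons != round(carbons)) {
    stop("carbons must be a positive integer")
  }
  if (!is.numeric(target_mM) || target_mM <= 0) stop("target_mM must be > 0")
  round_half_away(target_mM / carbons, 2)
}

#' Collate plate-reader growth curves
#'
#' Splits a long (well, time, OD) table into one time series per well, checks
#' time monotonicity, and summarizes biological replicates per strain and
#' condition: mean and range of maximum OD, and mean time to half-max (the
#' first time OD reaches min + (max - min)/2; undefined for a flat curve).
#' No growth model is fitted.
#'
#' @param raw data.frame with columns `well`, `time`, `od`.
#' @param replicate_map data.frame with columns `well`, `strain`,
#'   `condition`.
#' @return List with `curves` (list of per-well data.frames) and `summary`
#'   (one row per strain x condition).
#' @export
collate_growth <- function(raw, replicate_map) {
  stopifnot(all(c("well", "time", "od") %in% names(raw)),
            all(c("well", "strain", "condition") %in% names(replicate_map)))
  if (nrow(raw) == 0) {
    return(list(curves = list(),
                summary = data.frame(strain = character(),
                                     condition = character(),
                                     n_replicates = integer(),
                                     max_od_mean = numeric(),
                                     max_od_min = numeric(),
                                     max_od_max = numeric(),
                                     t_half_mean = numeric())))
  }
  curves <- split(raw[c("time", "od")], raw$well)
  curves <- lapply(names(curves), function(w) {
    cu <- curves[[w]][order(curves[[w]]$time), ]
    if (any(diff(cu$time) <= 0)) {
      stop("non-monotone time points in well ", w)
    }
    cu$well <- w
    cu
  })
  names(curves) <- vapply(curves, function(cu) cu$well[1], "")
  per_well <- do.call(rbind, lapply(curves, function(cu) {
    mx <- max(cu$od); mn <- min(cu$od)
    thr <- mn + (mx - mn) / 2
    t_half <- if (mx == mn) NA_real_ else cu$time[which(cu$od >= thr)[1]]
    data.frame(well = cu$well[1], max_od = mx, t_half = t_half)
  }))
  per_well <- merge(per_well, replicate_map, by = "well")
  groups <- split(per_well, paste(per_well$strain, per_well$condition, sep = "\r"))
  summary <- do.call(rbind, lapply(groups, function(g) {
    data.frame(strain = g$strain[1], condition = g$condition[1],
               n_replicates = nrow(g),
               max_od_mean = mean(g$max_od),
               max_od_min = min(g$max_od), max_od_max = max(g$max_od),
               t_half_mean = if (all(is.na(g$t_half))) NA_real_ else
                 mean(g$t_half, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  list(curves = curves, summary = summary)
}

#' Summarize a formaldehyde time series
#'
#' Peak concentration and time, whether formaldehyde was detected (peak above
#' the detection limit), and the first time after the peak at which the
#' concentration returns to or below the limit (NA if it never does). Values
#' at or below the limit are reported censored at the limit.
#'
#' @param time Strictly increasing time points (h).
#' @param formaldehyde Concentrations (mM), same length as `time`.
#' @param detection_limit Detection limit in mM (default 0.01).
#' @return List with `peak_mM`, `peak_time`, `return_time`, `detected`, and
#'   `censored` (the series with sub-limit values set to the limit).
#' @export
summarize_formaldehyde <- function(time, formaldehyde,
                                   detection_limit = 0.01) {
  if (is.null(formaldehyde) || length(formaldehyde) == 0) {
    stop("no formaldehyde channel")
  }
  stopifnot(length(time) == length(formaldehyde))
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  peak_idx <- which.max(formaldehyde)
  peak <- formaldehyde[peak_idx]
  detected <- peak > detection_limit
  ret <- NA_real_
  if (detected && peak_idx < length(time)) {
    after <- (peak_idx + 1L):length(time)
    below <- after[formaldehyde[after] <= detection_limit]
    if (length(below) > 0) ret <- time[below[1]]
  }
  list(peak_mM = peak, peak_time = time[peak_idx], return_time = ret,
       detected = detected,
       censored = pmax(formaldehyde, detection_limit))
}
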