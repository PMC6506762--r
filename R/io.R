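## Readers and writers.  The on-disk schema is a plain wide CSV with
## unit-tagged column names:
##   time_s, T_leaf_C, T_black_C, T_white_C, PPFD_umol_m2_s, T_air_C,
##   RH_percent (or RH_frac), P_atm_Pa
## Temperatures are degC and humidity percent on disk; kelvin and
## fractions internally.

.bundle_cols <- c(time = "time_s", leaf = "T_leaf_C", black = "T_black_C",
                  white = "T_white_C", ppfd = "PPFD_umol_m2_s",
                  t_air = "T_air_C", rh = "RH_percent", p_atm = "P_atm_Pa")

#' Read an experiment bundle from CSV
#'
#' Validates the schema, converts degC to K and percent RH to a fraction,
#' and returns the environmental trace together with the object
#' temperature traces.  An `RH_frac` column is accepted as an already
#' fractional humidity; values above 1.5 in such a column are rejected as
#' a unit ambiguity.
#'
#' @param path CSV file path.
#' @param ppfd_factor radiation conversion factor, J umol-1.
#' @return A list of class `experiment_bundle` with `env`
#'   ([environment_trace()]), `objects` (named list of [eb_trace()]s, K)
#'   and `metadata`.
#' @export
read_bundle <- function(path, ppfd_factor = 0.22) {
  df <- utils::read.csv(path, check.names = TRUE)
  rh_col <- if ("RH_percent" %in% names(df)) "RH_percent"
            else if ("RH_frac" %in% names(df)) "RH_frac" else NA
  need <- c("time_s", "PPFD_umol_m2_s", "T_air_C", "P_atm_Pa")
  missing <- setdiff(need, names(df))
  if (is.na(rh_col)) missing <- c(missing, "RH_percent")
  if (length(missing))
    stop("read_bundle: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("read_bundle: time_s must be strictly increasing")
  rh <- df[[rh_col]]
  if (rh_col == "RH_percent") rh <- rh / 100
  else if (any(rh > 1.5))
    stop("read_bundle: RH_frac column contains values > 1.5; ",
         "unit ambiguity (is it actually percent?)")
  env <- environment_trace(df$time_s, df$PPFD_umol_m2_s,
                           t_air = df$T_air_C + 273.15, rh = rh,
                           p_atm = df$P_atm_Pa, ppfd_factor = ppfd_factor)
  objects <- list()
  for (ob in c("leaf", "black", "white")) {
    col <- .bundle_cols[[ob]]
    if (col %in% names(df) && !all(is.na(df[[col]])))
      objects[[ob]] <- eb_trace(df$time_s, df[[col]] + 273.15)
  }
  structure(list(env = env, objects = objects,
                 metadata = list(path = path, ppfd_factor = ppfd_factor,
                                 rh_column = rh_col)),
            class = "experiment_bundle")
}

#' Write an experiment bundle to CSV
#'
#' Inverse of [read_bundle()]: all traces must share the environmental
#' time grid.  Values round-trip at full double precision.
#'
#' @param bundle an `experiment_bundle`, or a list with `env` and
#'   `objects` in internal units.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  env <- bundle$env
  stopifnot(inherits(env, "env_trace"))
  df <- data.frame(time_s = env$time)
  for (ob in c("leaf", "black", "white")) {
    tr <- bundle$objects[[ob]]
    if (is.null(tr)) next
    if (!isTRUE(all.equal(tr$time, env$time)))
      stop("write_bundle: trace '", ob, "' is not on the environmental ",
           "time grid")
    df[[.bundle_cols[[ob]]]] <- tr$value - 273.15
  }
  df$PPFD_umol_m2_s <- env$ppfd
  df$T_air_C <- env$t_air - 273.15
  df$RH_percent <- env$rh * 100
  df$P_atm_Pa <- env$p_atm
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle a synthetic experiment for writing
#'
#' @param sim output of [simulate_experiment()].
#' @return An `experiment_bundle`.
#' @export
as_bundle <- function(sim) {
  structure(list(env = sim$env,
                 objects = sim[intersect(c("leaf", "black", "white"),
                                         names(sim))],
                 metadata = list(seed = sim$truth$seed)),
            class = "experiment_bundle")
}

#' Reduce a multi-frame thermal stack to a region-of-interest mean trace
#'
#' @param stack a numeric array (rows x cols x frames), a list of frame
#'   matrices, or a path to a multi-frame TIFF (requires the tiff
#'   package).
#' @param roi either a logical mask matrix matching the frame dimensions
#'   or an integer vector `c(row0, row1, col0, col1)`.
#' @param timestamps one time (s) per frame.
#' @param offset added to pixel values to reach kelvin (use 273.15 for
#'   stacks stored in degC, 0 for kelvin stacks).
#' @return An [eb_trace()] of per-frame ROI means.
#' @export
extract_roi_means <- function(stack, roi, timestamps, offset = 0) {
  if (is.character(stack)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF stacks requires the 'tiff' package")
    stack <- tiff::readTIFF(stack, all = TRUE, as.is = FALSE)
  }
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  stopifnot(is.list(stack), length(stack) >= 1)
  dims <- dim(stack[[1]])
  if (!all(vapply(stack, function(f) identical(dim(f), dims), logical(1))))
    stop("extract_roi_means: frames differ in dimensions")
  if (length(timestamps) != length(stack))
    stop("extract_roi_means: ", length(stack), " frames but ",
         length(timestamps), " timestamps")
  mask <- if (is.logical(roi)) {
    if (!identical(dim(roi), dims))
      stop("extract_roi_means: mask dimensions do not match the frames")
    roi
  } else {
    stopifnot(length(roi) == 4)
    if (roi[1] < 1 || roi[2] > dims[1] || roi[3] < 1 || roi[4] > dims[2]
        || roi[1] > roi[2] || roi[3] > roi[4])
      stop("extract_roi_means: rectangle out of frame bounds")
    m <- matrix(FALSE, dims[1], dims[2])
    m[roi[1]:roi[2], roi[3]:roi[4]] <- TRUE
    m
  }
  if (!any(mask)) stop("extract_roi_means: empty ROI")
  vals <- vapply(stack, function(f) mean(f[mask]), numeric(1))
  eb_trace(timestamps, vals + offset)
}
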