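#' Construct an electropherogram object
#'
#' An electropherogram is a fluorescence trace over a migration
#' coordinate, with annotated coordinate windows for the lower marker and
#' the 18S and 28S ribosomal bands. Windows are caller-supplied intervals
#' (the instrument software's peak model is proprietary); they must not
#' overlap.
#'
#' @param coordinate strictly increasing numeric vector.
#' @param fluorescence nonnegative numeric vector, parallel to
#'   `coordinate`.
#' @param windows data.frame with columns `name`, `start`, `end`; names
#'   conventionally include `"marker"`, `"18S"`, `"28S"` (a hidden-break
#'   second 28S fragment may be annotated as an extra ribosomal window,
#'   e.g. `"28Sa"`/`"28Sb"`).
#' @return object of class `electropherogram`.
#' @export
electropherogram <- function(coordinate, fluorescence, windows) {
  stopifnot(length(coordinate) == length(fluorescence),
            all(diff(coordinate) > 0), all(fluorescence >= 0),
            all(c("name", "start", "end") %in% names(windows)))
  w <- windows[order(windows$start), ]
  if (any(w$end[-nrow(w)] > w$start[-1])) stop("windows overlap")
  structure(list(coordinate = coordinate, fluorescence = fluorescence,
                 windows = windows), class = "electropherogram")
}

window_mask <- function(trace, names_) {
  w <- trace$windows[trace$windows$name %in% names_, , drop = FALSE]
  m <- rep(FALSE, length(trace$coordinate))
  for (i in seq_len(nrow(w)))
    m <- m | (trace$coordinate >= w$start[i] & trace$coordinate <= w$end[i])
  m
}

area_under <- function(x, y, mask = rep(TRUE, length(x))) {
  if (sum(mask) < 2L) return(0)
  pracma::trapz(x[mask], y[mask])
}

ribosomal_window_names <- function(trace) {
  nm <- trace$windows$name
  nm[grepl("18S|28S", nm) & nm != "marker"]
}

#' Ribosomal fraction of an electropherogram
#'
#' The fraction of total RNA signal area occupied by the 18S and 28S
#' ribosomal bands: trapezoidal area inside the annotated ribosomal
#' windows divided by the area of the whole trace excluding the marker
#' window, after subtracting a flat baseline equal to the global minimum
#' fluorescence. In species with the 28S "hidden break", both annotated
#' 28S fragment windows count toward the ribosomal area. Degraded RNA
#' moves signal out of the ribosomal bands into a low-molecular-weight
#' smear, lowering the fraction.
#'
#' @param trace an [electropherogram()] with 18S and 28S windows
#'   annotated.
#' @return fraction in \[0, 1\]. A trace with zero total signal area after
#'   baseline subtraction (e.g. a flat trace) yields 0 with a warning.
#' @export
ribosomal_fraction <- function(trace) {
  ribo <- ribosomal_window_names(trace)
  if (length(ribo) == 0L) stop("no 18S/28S windows annotated")
  y <- trace$fluorescence - min(trace$fluorescence)
  x <- trace$coordinate
  total <- area_under(x, y) - area_under(x, y, window_mask(trace, "marker"))
  ribo_area <- sum(vapply(ribo, function(nm)
    area_under(x, y, window_mask(trace, nm)), numeric(1)))
  if (total <= 0) {
    warning("zero total signal area after baseline subtraction")
    return(0)
  }
  max(0, min(1, ribo_area / total))
}

#' Fit a RIN calibration model
#'
#' Ordinary least squares of known RIN values on ribosomal fractions,
#' the calibration used to infer integrity numbers for samples where the
#' instrument's own (vertebrate-trained) algorithm fails.
#'
#' @param calibration data.frame with columns `fraction` and `rin`
#'   (>= 3 rows; fractions must not be all equal).
#' @return object of class `rin_model`: `slope`, `intercept`,
#'   `r_squared`, `n_calibration`, and the underlying `lm` fit.
#' @export
fit_rin_model <- function(calibration) {
  stopifnot(all(c("fraction", "rin") %in% names(calibration)))
  if (nrow(calibration) < 3L)
    stop("calibration needs at least 3 points")
  if (stats::sd(calibration$fraction) == 0)
    stop("degenerate calibration: all fractions equal")
  fit <- stats::lm(rin ~ fraction, data = calibration)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_calibration = nrow(calibration), fit = fit),
            class = "rin_model")
}

#' @export
print.rin_model <- function(x, ...) {
  cat(sprintf("RIN model: RIN = %.3f + %.3f x fraction (r^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n_calibration))
  invisible(x)
}

#' Infer a RIN value from a ribosomal fraction
#' @param model a [fit_rin_model()] fit.
#' @param fraction ribosomal fraction(s).
#' @return predicted RIN, clamped to the instrument scale \[1, 10\].
#' @export
infer_rin <- function(model, fraction) {
  pmin(10, pmax(1, model$intercept + model$slope * fraction))
}

#' Simulate a Bioanalyzer-style electropherogram
#'
#' Builds a synthetic trace from Gaussian peaks: a lower marker, the 18S
#' and 28S ribosomal bands scaled by `intactness`, and a broad
#' low-molecular-weight degradation smear carrying the remaining signal.
#' With `hidden_break = TRUE` the 28S band is replaced by two 18S-sized
#' fragments (annotated `28Sa`/`28Sb`), emulating the natural 28S
#' scission of many invertebrates that deflates instrument-reported RIN
#' without true degradation.
#'
#' @param intactness fraction in \[0, 1\] of (non-marker) signal in the
#'   ribosomal bands.
#' @param hidden_break logical.
#' @param n_points trace resolution.
#' @param seed integer seed for measurement noise; `NA` for a noiseless
#'   trace.
#' @param noise_sd fluorescence noise sd.
#' @return an [electropherogram()].
#' @export
simulate_electropherogram <- function(intactness = 0.8, hidden_break = FALSE,
                                      n_points = 1200L, seed = NA,
                                      noise_sd = 0.1) {
  stopifnot(intactness >= 0, intactness <= 1)
  x <- seq(20, 70, length.out = n_points)
  gauss <- function(mu, sd, area) area * stats::dnorm(x, mu, sd)
  y <- gauss(23, 0.35, 20)                             # lower marker
  smear <- gauss(32, 4.5, 100 * (1 - intactness))      # degradation smear
  if (hidden_break) {
    ribo <- gauss(41, 0.8, 40 * intactness) +          # 18S
      gauss(44.5, 0.8, 30 * intactness) +              # 28S fragment a
      gauss(47.5, 0.8, 30 * intactness)                # 28S fragment b
    win <- data.frame(name = c("marker", "18S", "28Sa", "28Sb"),
                      start = c(21.5, 38, 42.2, 45.7),
                      end = c(24.5, 44 - 1.8, 45.6, 50.5))
  } else {
    ribo <- gauss(41, 0.8, 40 * intactness) +          # 18S
      gauss(47, 1.0, 60 * intactness)                  # 28S
    win <- data.frame(name = c("marker", "18S", "28S"),
                      start = c(21.5, 38, 43.5),
                      end = c(24.5, 43.4, 51))
  }
  y <- y + smear + ribo
  if (!is.na(seed)) {
    set.seed(seed)
    y <- pmax(0, y + stats::rnorm(n_points, 0, noise_sd))
  }
  electropherogram(x, y, win)
}

#' Read/write electropherogram traces
#'
#' The trace is a two-column CSV (`coordinate`, `fluorescence`); windows
#' are a TSV sidecar (`name`, `start`, `end`).
#'
#' @param trace an [electropherogram()].
#' @param trace_path,windows_path file paths.
#' @return `write_trace` invisibly returns the paths; `read_trace`
#'   returns an [electropherogram()].
#' @export
write_trace <- function(trace, trace_path, windows_path) {
  utils::write.csv(data.frame(coordinate = trace$coordinate,
                              fluorescence = trace$fluorescence),
                   trace_path, row.names = FALSE)
  utils::write.table(trace$windows, windows_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(trace_path, windows_path))
}

#' @rdname write_trace
#' @export
read_trace <- function(trace_path, windows_path) {
  tr <- utils::read.csv(trace_path)
  w <- utils::read.delim(windows_path)
  electropherogram(tr$coordinate, tr$fluorescence, w)
}
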