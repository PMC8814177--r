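#' Concentration time series of a run
#'
#' A `conc_series` (built by [run_simulation()]) records, at every sampled
#' tick: free-molecule counts per species, counts of molecules bound inside
#' complexes, partial and saturated complex counts per reaction, and the
#' cumulative number of completed catalytic events per reaction and
#' direction.  Concentrations report free molecules only; molecules inside
#' complexes appear in the complex columns, which is what makes stalled
#' states (constant complex counts with flat metabolite curves) visible.
#'
#' @param series a `conc_series`.
#' @param species species id(s); default all.
#' @return matrix (species x time) of concentrations in mmol/l.
#' @export
concentrations <- function(series, species = NULL) {
  stopifnot(inherits(series, "conc_series"))
  m <- series$free / (1e-3 * .NA_CONST * series$volume)
  if (!is.null(species)) m <- m[species, , drop = FALSE]
  m
}

#' @export
print.conc_series <- function(x, ...) {
  cat("<conc_series> ", length(x$species), " species, ",
      length(x$times), " snapshots over ",
      format(max(x$times)), " s (d = ",
      x$meta$perception_distance, " A, seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.conc_series <- function(x, ...) {
  conc <- concentrations(x)
  data.frame(
    time = rep(x$times, each = length(x$species)),
    species = rep(x$species, times = length(x$times)),
    free_count = as.vector(x$free),
    bound_count = as.vector(x$bound),
    concentration = as.vector(conc),
    stringsAsFactors = FALSE)
}

#' First time a species is (and stays) depleted
#'
#' The earliest recorded time at which the free count reaches zero and
#' remains zero until the end of the series; `NA` if the species is never
#' durably depleted.
#'
#' @param series a `conc_series`.
#' @param species one species id.
#' @return time in seconds, or `NA`.
#' @export
depletion_time <- function(series, species) {
  stopifnot(inherits(series, "conc_series"), species %in% series$species)
  x <- series$free[species, ]
  nz <- which(x != 0)
  if (length(nz) == 0) return(series$times[1])
  k <- max(nz) + 1
  if (k > length(x)) return(NA_real_)
  series$times[k]
}

.detrend <- function(x, t) {
  residuals(lm(x ~ t))
}

#' Dominant oscillation frequency of a species trajectory
#'
#' Frequency of the largest periodogram ordinate of the linearly detrended
#' series (zero bin excluded).  The peak must exceed `min_power_ratio`
#' times the median periodogram power to count as significant; otherwise
#' `NA` is returned (constant or trend-only series have no dominant
#' frequency).
#'
#' @param series a `conc_series`, or a numeric vector (then supply `times`).
#' @param species species id when `series` is a `conc_series`.
#' @param window optional `c(t0, t1)` restricting the analysis window (s).
#' @param times sampling times when `series` is a bare vector.
#' @param min_power_ratio significance threshold on peak/median power.
#' @return frequency in Hz, or `NA` if no significant peak.
#' @export
dominant_frequency <- function(series, species = NULL, window = NULL,
                               times = NULL, min_power_ratio = 4) {
  if (inherits(series, "conc_series")) {
    stopifnot(species %in% series$species)
    x <- series$free[species, ]
    t <- series$times
  } else {
    x <- as.numeric(series)
    t <- times
    if (is.null(t)) stop("supply sampling times for a bare numeric series")
  }
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    x <- x[keep]; t <- t[keep]
  }
  n <- length(x)
  if (n < 32) stop("need at least 32 samples in the window")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) stop("sampling must be uniform")
  dt <- dt[1]
  scale0 <- sd(x)
  x <- .detrend(x, t)
  # constant or trend-only series: residuals are numerical noise
  if (sd(x) <= 1e-9 * (1 + scale0)) return(NA_real_)
  pw <- Mod(fft(x))^2 / n
  m <- floor(n / 2)
  pw <- pw[2:(m + 1)]                      # exclude the zero bin
  freqs <- (1:m) / (n * dt)
  if (all(pw <= 0)) return(NA_real_)
  peak <- which.max(pw)
  if (pw[peak] <= min_power_ratio * median(pw)) return(NA_real_)
  freqs[peak]
}

#' Zero-lag synchrony of two species trajectories
#'
#' Pearson correlation of the linearly detrended series; `NA` when either
#' series has zero variance after detrending.
#'
#' @param series a `conc_series`.
#' @param species_a,species_b species ids.
#' @param window optional `c(t0, t1)` window (s).
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
synchrony <- function(series, species_a, species_b, window = NULL) {
  stopifnot(inherits(series, "conc_series"),
            species_a %in% series$species, species_b %in% series$species)
  t <- series$times
  a <- series$free[species_a, ]
  b <- series$free[species_b, ]
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    a <- a[keep]; b <- b[keep]; t <- t[keep]
  }
  sa <- sd(a); sb <- sd(b)
  a <- .detrend(a, t); b <- .detrend(b, t)
  if (sd(a) <= 1e-9 * (1 + sa) || sd(b) <= 1e-9 * (1 + sb))
    return(NA_real_)
  cor(a, b)
}

#' Write / read a concentration series
#'
#' `"csv"` writes a plain long-format table (time, quantity, name, count)
#' with the metadata as a single `# meta:` JSON comment line, readable by
#' any CSV tool that skips `#` comments; `"rds"` is the binary container.
#' Round trips through either format reproduce the series exactly.
#'
#' @param series a `conc_series`.
#' @param path output file.
#' @param format `"csv"` or `"rds"` (default from the file extension).
#' @return `path` invisibly.
#' @export
write_series <- function(series, path, format = c("auto", "csv", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  stopifnot(inherits(series, "conc_series"))
  if (format == "rds") {
    saveRDS(series, path)
    return(invisible(path))
  }
  long <- function(mat, quantity) {
    if (nrow(mat) == 0) return(NULL)
    data.frame(time = rep(series$times, each = nrow(mat)),
               quantity = quantity,
               name = rep(rownames(mat), times = ncol(mat)),
               count = as.vector(mat), stringsAsFactors = FALSE)
  }
  R <- length(series$reactions)
  comp <- series$completions
  df <- rbind(long(series$free, "free"),
              long(series$bound, "bound"),
              long(series$complex_partial, "complex_partial"),
              long(series$complex_saturated, "complex_saturated"),
              long(comp[seq(1, 2 * R, by = 2), , drop = FALSE],
                   "completions_fwd"),
              long(comp[seq(2, 2 * R, by = 2), , drop = FALSE],
                   "completions_rev"))
  meta <- series$meta
  meta$volume <- series$volume
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# meta: ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                 digits = NA)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    out <- readRDS(path)
    if (!inherits(out, "conc_series")) stop("not a conc_series container")
    return(out)
  }
  first <- readLines(path, n = 1)
  if (!grepl("^# meta: ", first)) stop("missing series metadata header")
  meta <- jsonlite::fromJSON(sub("^# meta: ", "", first))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "quantity", "name", "count")
  if (!all(need %in% names(df))) stop("series file lacks columns: ",
                                      paste(setdiff(need, names(df)),
                                            collapse = ", "))
  times <- sort(unique(df$time))
  wide <- function(q) {
    sub <- df[df$quantity == q, ]
    if (nrow(sub) == 0)
      return(matrix(numeric(0), 0, length(times)))
    names_u <- unique(sub$name)
    m <- matrix(0, length(names_u), length(times),
                dimnames = list(names_u, NULL))
    m[cbind(match(sub$name, names_u), match(sub$time, times))] <- sub$count
    m
  }
  free <- wide("free"); bound <- wide("bound")
  partial <- wide("complex_partial"); saturated <- wide("complex_saturated")
  cf <- wide("completions_fwd"); cr <- wide("completions_rev")
  R <- nrow(cf)
  comp <- matrix(0, 2 * R, length(times))
  if (R > 0) {
    comp[seq(1, 2 * R, by = 2), ] <- cf
    comp[seq(2, 2 * R, by = 2), ] <- cr
    rownames(comp) <- c(rbind(paste0(rownames(cf), ":fwd"),
                              paste0(rownames(cf), ":rev")))
  }
  volume <- meta$volume
  meta$volume <- NULL
  structure(list(
    times = times, ticks = times / meta$tick,
    free = free, bound = bound,
    complex_partial = partial, complex_saturated = saturated,
    completions = comp,
    species = rownames(free), reactions = rownames(partial),
    volume = volume, meta = meta), class = "conc_series")
}

#' @importFrom stats median sd cor
NULL
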