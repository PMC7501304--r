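#' Standardize an RR series
#'
#' Maps a tachogram to the dimensionless series
#' \deqn{z_n = (r_n - \langle r\rangle) / \mathrm{std}[r],}
#' where \eqn{\langle r\rangle} is the temporal mean and
#' \eqn{\mathrm{std}[r]} the *population* (divisor \eqn{N}) standard
#' deviation. The population convention is essential: it makes the
#' standardized series have second moment exactly 1, so that its lag-0
#' autocorrelation is exactly 1 and the Lagrange multiplier on the second
#' moment is pinned at \eqn{-1/2}.
#'
#' @param x an [rr_series()] object or a numeric vector.
#' @param patient_id optional identifier override.
#'
#' @return A `"std_series"` object: the numeric vector `z` with
#'   attributes `mean_ms`, `sd_ms` (for inversion), `patient_id` and
#'   `class_label`.
#' @examples
#' z <- standardize(rr_series(c(800, 1000), "p1", "H"))
#' as.numeric(z)  # -1, 1
#' @export
standardize <- function(x, patient_id = NULL) {
  if (inherits(x, "std_series")) return(std_series(as.numeric(x),
    patient_id = patient_id %||% attr(x, "patient_id"),
    class_label = attr(x, "class_label")))
  if (inherits(x, "rr_series")) {
    vals <- x$intervals
    pid <- patient_id %||% x$patient_id
    cl <- x$class_label
  } else {
    vals <- as.numeric(x)
    pid <- patient_id %||% "unknown"
    cl <- "UNKNOWN"
  }
  std_series(vals, patient_id = pid, class_label = cl)
}

std_series <- function(vals, patient_id = "unknown", class_label = "UNKNOWN") {
  n <- length(vals)
  if (n < 2L) stop("need at least 2 values to standardize")
  m <- mean(vals)
  s <- sqrt(mean(vals^2) - m^2)  # population sd, divisor N
  if (!is.finite(s) || s <= 0)
    stop("degenerate input: zero variance, cannot standardize")
  z <- (vals - m) / s
  structure(z, mean_ms = m, sd_ms = s, patient_id = patient_id,
            class_label = class_label, class = "std_series")
}

#' @export
print.std_series <- function(x, ...) {
  cat(sprintf("standardized series '%s' [%s]: %d points (mean %.3g ms, sd %.3g ms)\n",
              attr(x, "patient_id"), attr(x, "class_label"), length(x),
              attr(x, "mean_ms"), attr(x, "sd_ms")))
  invisible(x)
}

#' Invert a standardization
#'
#' Recovers physical-unit intervals `z * sd_ms + mean_ms` from a
#' standardized series (or any z vector plus explicit scale).
#'
#' @param z a `"std_series"` (uses stored scale) or numeric vector.
#' @param mean_ms,sd_ms scale overrides (required for plain vectors).
#' @return numeric vector in milliseconds.
#' @export
unstandardize <- function(z, mean_ms = attr(z, "mean_ms"),
                          sd_ms = attr(z, "sd_ms")) {
  if (is.null(mean_ms) || is.null(sd_ms))
    stop("mean_ms and sd_ms required when z carries no stored scale")
  as.numeric(z) * sd_ms + mean_ms
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beat-lag autocorrelation of a standardized series
#'
#' Computes \deqn{C(\tau) = \frac{1}{N-\tau}\sum_{n=1}^{N-\tau} z_n
#' z_{n+\tau},} the edge-normalized raw second moment at lag \eqn{\tau}.
#' For a standardized series \eqn{C(0)=1} identically. The sub-series
#' offset means (negligible for a series standardized over its whole
#' length) are not subtracted unless `subtract_offsets = TRUE`.
#'
#' @param z a `"std_series"` (or numeric vector).
#' @param lag_max largest lag; must be `< length(z)`. Default
#'   `min(1e4, length(z) %/% 10)`.
#' @param subtract_offsets subtract the leading/trailing window means
#'   before multiplying (sensitivity option; off by default).
#' @return data frame with columns `tau` (0..`lag_max`) and `C`.
#' @export
autocorrelation <- function(z, lag_max = NULL, subtract_offsets = FALSE) {
  zv <- as.numeric(z)
  n <- length(zv)
  if (is.null(lag_max)) lag_max <- max(1L, min(1e4L, n %/% 10L))
  lag_max <- as.integer(lag_max)
  if (lag_max >= n) stop("lag_max must be smaller than the series length")
  if (subtract_offsets) {
    C <- vapply(0:lag_max, function(tau) {
      a <- zv[1:(n - tau)]; b <- zv[(1 + tau):n]
      mean((a - mean(a)) * (b - mean(b)))
    }, numeric(1))
  } else {
    # divisor-N acf rescaled to the divisor-(N - tau) estimator
    raw <- stats::acf(zv, lag.max = lag_max, type = "covariance",
                      demean = FALSE, plot = FALSE)$acf[, 1, 1]
    C <- raw * n / (n - 0:lag_max)
  }
  data.frame(tau = 0:lag_max, C = C)
}

#' Class-level moments
#'
#' Arithmetic means over a set of patients' standardized series of the
#' first moment, second moment and autocorrelation function; the sample
#' analogue of averaging over the members of one clinical class.
#'
#' @param members list of `"std_series"` objects.
#' @param lag_max largest autocorrelation lag (must be valid for the
#'   shortest member).
#' @return list with `class_label`, `n_members`, `mean_z`, `mean_z2`,
#'   and `mean_acf` (data frame `tau`, `C`).
#' @export
class_moments <- function(members, lag_max = 100L) {
  if (length(members) == 0L) stop("empty collection of series")
  m1 <- vapply(members, function(z) mean(as.numeric(z)), numeric(1))
  m2 <- vapply(members, function(z) mean(as.numeric(z)^2), numeric(1))
  acfs <- vapply(members, function(z) autocorrelation(z, lag_max)$C,
                 numeric(lag_max + 1L))
  acfs <- matrix(acfs, nrow = lag_max + 1L)
  labs <- unique(vapply(members, function(z)
    attr(z, "class_label") %||% "UNKNOWN", character(1)))
  list(class_label = if (length(labs) == 1L) labs else "MIXED",
       n_members = length(members),
       mean_z = mean(m1),
       mean_z2 = mean(m2),
       mean_acf = data.frame(tau = 0:lag_max, C = rowMeans(acfs)))
}
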