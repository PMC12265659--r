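#' Autocovariances of a standardized scan track
#'
#' For each lag k = 1..floor(max_lag_cm/step_cm), averages the mean-zero
#' products \code{z[m] * z[m + k]} over all within-chromosome position pairs
#' exactly k steps apart with both positions unmasked. Pairs never straddle a
#' chromosome boundary and pairs touching a masked position are skipped. The
#' lag cap defaults to 4.0 cM, beyond which the exponential-decay signal is
#' typically indistinguishable from noise.
#'
#' @param track an \code{ibd_scan} track, or any list with elements
#'   \code{z_diff}, \code{chrom} and optionally \code{excluded}.
#' @param step_cm grid spacing in cM; defaults to the track's own spacing.
#' @param max_lag_cm maximum lag in cM (default 4.0).
#' @param values which track column to use (default \code{"z_diff"}).
#' @return data.table with columns \code{lag_cm}, \code{lag_morgans},
#'   \code{acov}, \code{n_pairs}; lags with no valid pairs are omitted.
#' @export
autocovariances <- function(track, step_cm = attr(track, "step_cm"),
                            max_lag_cm = 4.0, values = "z_diff") {
  if (is.null(step_cm)) stop("step_cm not supplied and not found on track")
  z <- track[[values]]
  chrom <- track[["chrom"]] %||% rep("1", length(z))
  excluded <- track[["excluded"]] %||% rep(FALSE, length(z))
  ok <- !excluded & is.finite(z)
  K <- floor(max_lag_cm / step_cm + 1e-9)
  if (K < 1L) stop("max_lag_cm smaller than the grid spacing")
  M <- length(z)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    if (k >= M) break
    i <- seq_len(M - k)
    valid <- ok[i] & ok[i + k] & chrom[i] == chrom[i + k]
    n <- sum(valid)
    if (n == 0L) next
    out[[k]] <- data.table(
      lag_cm = k * step_cm, lag_morgans = k * step_cm / 100,
      acov = mean(z[i][valid] * z[i + k][valid]), n_pairs = n)
  }
  res <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (!nrow(res)) stop("no valid position pairs at any lag")
  res
}

#' Estimate the exponential decay parameter by log-linear regression
#'
#' The autocovariance of the standardized track at genetic distance d Morgans
#' is modeled as \code{exp(-theta * d)}. Ordinary least squares of
#' \code{log(acov)} on lag (in Morgans) through the origin yields the decay
#' estimate \code{theta = -slope} (per Morgan). Non-positive autocovariances
#' are dropped before the log, the only choice compatible with the log-linear
#' model.
#'
#' @param acovs data.table from \code{\link{autocovariances}} (columns
#'   \code{lag_morgans}, \code{acov}).
#' @return An \code{ou_fit} list: \code{theta}, \code{n_lags_used},
#'   \code{lags_used} (the retained lag/acov pairs).
#' @export
estimate_theta <- function(acovs) {
  keep <- is.finite(acovs$acov) & acovs$acov > 0
  if (!any(keep)) stop("no positive autocovariances; cannot fit log-linear decay")
  x <- acovs$lag_morgans[keep]
  y <- log(acovs$acov[keep])
  slope <- sum(x * y) / sum(x^2)
  theta <- -slope
  if (!is.finite(theta)) stop("decay estimation failed")
  structure(list(theta = theta, n_lags_used = sum(keep),
                 lags_used = acovs[keep]),
            class = "ou_fit")
}

#' Cross-correlation of the standardized case and control tracks
#'
#' Sample correlation of \code{z_case} and \code{z_control} over unmasked
#' positions; used by the simulation-based threshold to couple the two
#' marginal OU processes.
#'
#' @param track an \code{ibd_scan} track from a two-sample scan.
#' @return Correlation estimate in \[-1, 1\].
#' @export
estimate_rho <- function(track) {
  if (is.null(track$z_case) || is.null(track$z_control) ||
      all(is.na(track$z_control)))
    stop("both case and control standardized tracks are required")
  ok <- !track$excluded & is.finite(track$z_case) & is.finite(track$z_control)
  if (sum(ok) < 3L) stop("fewer than 3 unmasked positions")
  cor(track$z_case[ok], track$z_control[ok])
}

#' Fit the OU model for a scan track
#'
#' Convenience wrapper estimating the decay parameter of the difference track
#' (used by the analytic threshold), the per-group decay parameters, and the
#' case-control cross-correlation.
#'
#' @param track an \code{ibd_scan} track.
#' @param step_cm grid spacing in cM (defaults to the track's).
#' @param max_lag_cm autocovariance lag cap in cM.
#' @return An \code{ou_model} list with elements \code{theta} (difference
#'   track, per Morgan), \code{theta_case}, \code{theta_control}, \code{rho},
#'   \code{delta} (Morgans), \code{lags_used}.
#' @export
fit_ou_model <- function(track, step_cm = attr(track, "step_cm"),
                         max_lag_cm = 4.0) {
  fit_d <- estimate_theta(autocovariances(track, step_cm, max_lag_cm, "z_diff"))
  two_sample <- !is.null(track$z_control) && !all(is.na(track$z_control))
  fit1 <- fit0 <- NULL
  rho <- NA_real_
  if (two_sample) {
    fit1 <- try(estimate_theta(autocovariances(track, step_cm, max_lag_cm, "z_case")),
                silent = TRUE)
    fit0 <- try(estimate_theta(autocovariances(track, step_cm, max_lag_cm, "z_control")),
                silent = TRUE)
    rho <- estimate_rho(track)
  }
  structure(list(
    theta = fit_d$theta,
    theta_case = if (inherits(fit1, "ou_fit")) fit1$theta else NA_real_,
    theta_control = if (inherits(fit0, "ou_fit")) fit0$theta else NA_real_,
    rho = rho,
    delta = step_cm / 100,
    lags_used = fit_d$lags_used), class = "ou_model")
}

#' @export
print.ou_model <- function(x, ...) {
  cat("OU model: theta =", format(x$theta, digits = 4), "per Morgan",
      "(case", format(x$theta_case, digits = 4),
      ", control", format(x$theta_control, digits = 4), ")",
      "rho =", format(x$rho, digits = 3),
      "delta =", x$delta, "Morgans\n")
  invisible(x)
}
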