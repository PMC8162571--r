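# Voxelwise baseline relaxometry: T1 from variable flip angle SPGR,
# T2/T2* from mono-exponential multi-echo decay, fat fraction from a
# two-point Dixon pair. All fitters accept either a matrix
# (voxels x measurements) or an array whose LAST dimension indexes the
# measurement (flip angle / echo), and return maps in the input's
# spatial shape with non-physical voxels masked to NA.

.flatten_last <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("signals must be a matrix or array")
  k <- d[length(d)]
  list(mat = matrix(x, ncol = k), spatial = d[-length(d)])
}

.reshape_map <- function(v, spatial) {
  if (length(spatial) > 1) dim(v) <- spatial
  v
}

#' Variable-flip-angle T1 mapping
#'
#' Per voxel, the SPGR signal equation is linearized as
#' `S/sin(a) = E1 * S/tan(a) + M0' (1 - E1)` and fitted by ordinary
#' least squares of `y = S/sin(a)` on `x = S/tan(a)`. The slope `m`
#' estimates `E1 = exp(-TR/T1)`, so `T1 = -TR / log(m)`; the intercept
#' `b` gives `M0' = b / (1 - m)`. `M0'` absorbs the fixed echo-time
#' decay factor `exp(-TE/T2*)`, which cancels in T1.
#'
#' Voxels whose slope falls outside (0, 1), whose signals are all zero,
#' or whose T1 falls outside the physical window (1, 10000) ms are
#' masked (NA), never clamped.
#'
#' @param signals Magnitude signals; matrix (voxels x flips) or array
#'   with flip angle as the last dimension.
#' @param flip_angles Flip angles in degrees (>= 2 distinct values).
#' @param TR Repetition time, ms.
#' @return List with `T1` (ms), `M0` (a.u., including the TE decay
#'   factor), `mask` (logical, TRUE where the fit is valid) and
#'   `n_masked`.
#' @export
fit_vfa_t1 <- function(signals, flip_angles, TR) {
  if (length(unique(flip_angles)) < 2)
    stop("need at least 2 distinct flip angles")
  if (TR <= 0) stop("TR must be > 0")
  f <- .flatten_last(signals)
  S <- f$mat
  if (ncol(S) != length(flip_angles))
    stop("last dimension of signals must match flip_angles")
  if (any(S < 0)) stop("signals must be non-negative")
  a <- flip_angles * pi / 180
  X <- sweep(S, 2, tan(a), "/")
  Y <- sweep(S, 2, sin(a), "/")
  n <- length(a)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X * X); sxy <- rowSums(X * Y)
  denom <- sxx - sx * sx / n
  m <- (sxy - sx * sy / n) / denom
  b <- (sy - m * sx) / n
  T1 <- -TR / log(m)
  M0 <- b / (1 - m)
  ok <- is.finite(m) & m > 0 & m < 1 & is.finite(T1) &
    T1 > 1 & T1 < 10000 & rowSums(S) > 0
  T1[!ok] <- NA_real_; M0[!ok] <- NA_real_
  list(T1 = .reshape_map(T1, f$spatial),
       M0 = .reshape_map(M0, f$spatial),
       mask = .reshape_map(ok, f$spatial),
       n_masked = sum(!ok))
}

#' Mono-exponential decay fitting (T2 or T2*)
#'
#' Per voxel, fits `S(TE) = A exp(-TE/T)` to a multi-echo series. The
#' default is a signal-weighted log-linear least-squares fit (weights
#' `S^2`, which de-biases the log transform under additive noise); a
#' nonlinear least-squares route (`method = "nls"`, Gauss-Newton on the
#' exponential model seeded by the log-linear fit) is available and is
#' used as the cross-check oracle in the test suite.
#'
#' Input from a multi-echo GRE yields a T2* map; input from a multi-echo
#' spin echo yields a T2 map. Voxels with any non-positive signal or a
#' non-finite/non-physical fit (outside (0.1, 2000) ms) are masked.
#'
#' @param signals Matrix (voxels x echoes) or array with echo as the
#'   last dimension; positive inside the tissue.
#' @param TE_list Echo times in ms, strictly increasing, length >= 2.
#' @param method `"loglin"` (default) or `"nls"`.
#' @return List with `T` (decay time, ms), `A` (amplitude), `mask`,
#'   `n_masked`.
#' @export
fit_monoexp_decay <- function(signals, TE_list,
                              method = c("loglin", "nls")) {
  method <- match.arg(method)
  if (length(TE_list) < 2) stop("need at least 2 echoes")
  if (any(diff(TE_list) <= 0)) stop("TE_list must be strictly increasing")
  f <- .flatten_last(signals)
  S <- f$mat
  if (ncol(S) != length(TE_list))
    stop("last dimension of signals must match TE_list")
  pos <- rowSums(S <= 0) == 0
  L <- log(pmax(S, .Machine$double.xmin))
  W <- S * S
  sw <- rowSums(W)
  te <- TE_list
  swx <- W %*% te
  swy <- rowSums(W * L)
  swxx <- W %*% (te * te)
  swxy <- (W * L) %*% te
  xb <- swx / sw; yb <- swy / sw
  slope <- (swxy - sw * xb * yb) / (swxx - sw * xb * xb)
  slope <- as.numeric(slope)
  intercept <- as.numeric(yb - slope * xb)
  Tm <- -1 / slope
  A <- exp(intercept)

  if (method == "nls") {
    for (i in which(pos & is.finite(Tm) & Tm > 0)) {
      fit <- tryCatch(
        stats::nls(y ~ A * exp(-te / T2), data = list(y = S[i, ], te = te),
                   start = list(A = A[i], T2 = Tm[i]),
                   control = stats::nls.control(warnOnly = TRUE)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        A[i] <- cf[["A"]]; Tm[i] <- cf[["T2"]]
      }
    }
  }

  ok <- pos & is.finite(Tm) & is.finite(A) & Tm > 0.1 & Tm < 2000
  Tm[!ok] <- NA_real_; A[!ok] <- NA_real_
  list(T = .reshape_map(Tm, f$spatial),
       A = .reshape_map(A, f$spatial),
       mask = .reshape_map(ok, f$spatial),
       n_masked = sum(!ok))
}

#' Two-point Dixon fat fraction
#'
#' From co-registered in-phase (water + fat) and opposed-phase
#' (|water - fat|) magnitude volumes, the fat fraction is
#' `FF = (IP - OP) / (2 IP)`, clipped to \[0, 1\]. Water-dominant voxels
#' are assumed (no fat-water swap resolution). Background voxels, where
#' the in-phase signal falls below `threshold` times the robust maximum
#' (99th percentile) of IP, are masked.
#'
#' @param in_phase,opposed_phase Non-negative magnitude arrays of equal
#'   shape.
#' @param threshold Background threshold as a fraction of the robust IP
#'   maximum (default 0.05).
#' @return List with `fat_fraction` (in \[0,1\], NA in background),
#'   `mask`, `n_masked`.
#' @examples
#' dixon_fat_fraction(100, 60)$fat_fraction  # W = 80, F = 20 -> 0.2
#' @export
dixon_fat_fraction <- function(in_phase, opposed_phase, threshold = 0.05) {
  if (!identical(dim(in_phase), dim(opposed_phase)) ||
      length(in_phase) != length(opposed_phase))
    stop("in-phase and opposed-phase volumes must have identical shape")
  if (any(in_phase < 0) || any(opposed_phase < 0))
    stop("magnitude volumes must be non-negative")
  floor_ip <- threshold * stats::quantile(in_phase, 0.99, names = FALSE)
  ok <- in_phase > floor_ip
  ff <- (in_phase - opposed_phase) / (2 * in_phase)
  ff <- pmin(pmax(ff, 0), 1)
  ff[!ok] <- NA_real_
  if (!is.null(dim(in_phase))) dim(ff) <- dim(in_phase)
  list(fat_fraction = ff, mask = ok, n_masked = sum(!ok))
}
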