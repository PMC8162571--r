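#' Build the digital calf phantom
#'
#' Lays out the requested tissues on a voxel grid and fills voxelwise
#' ground-truth parameter maps. The five calf muscles are drawn as
#' angular sectors of a circular "leg" cross-section (anterior sectors
#' for TA/PL, posterior for TP/MG/LG), each a connected region;
#' everything outside the leg is background. Sector boundaries receive a
#' small seeded jitter so distinct geometry seeds give distinct (but
#' reproducible) geometries.
#'
#' Maps are piecewise constant by default. An optional smooth
#' multiplicative within-tissue variation field (a low-frequency seeded
#' sinusoidal modulation) can be switched on via `variation_amp`.
#'
#' @param tissues List of [tissue_spec()] objects; at most one may be the
#'   background. Label ids must be unique.
#' @param grid_shape Integer vector of 3 voxel counts, e.g. `c(64, 64, 8)`.
#' @param geometry_seed Integer seed controlling sector jitter and the
#'   variation field.
#' @param variation_amp Amplitude of the within-tissue multiplicative
#'   variation (0 = piecewise-constant truth, the default).
#' @return Object of class `muscle_phantom`: list with `labels` (integer
#'   3-D array), `maps` (named list of 3-D arrays `T1`, `T2`, `T2star`,
#'   `fat_fraction`, `trate`, `M0`), `tissues`, `grid_shape`,
#'   `geometry_seed`, `variation_amp`.
#' @examples
#' ph <- build_phantom(calf_tissues("healthy"), c(32, 32, 4), geometry_seed = 1)
#' table(ph$labels)
#' @export
build_phantom <- function(tissues, grid_shape = c(64, 64, 8),
                          geometry_seed = 1L, variation_amp = 0) {
  if (length(tissues) < 1) stop("need at least one tissue")
  if (inherits(tissues, "tissue_spec")) tissues <- list(tissues)
  ids <- vapply(tissues, function(t) t$label_id, integer(1))
  if (anyDuplicated(ids)) stop("overlapping label ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop("grid_shape must be 3 positive voxel counts")

  names(tissues) <- vapply(tissues, function(t) t$name, character(1))
  is_bg <- names(tissues) == "background"
  muscles <- tissues[!is_bg]
  n_mus <- length(muscles)

  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  labels <- array(if (any(is_bg)) tissues[[which(is_bg)[1]]]$label_id else 0L,
                  dim = grid_shape)

  if (n_mus > 0) {
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    R <- 0.45 * min(nx, ny)
    xs <- matrix(seq_len(nx) - cx, nx, ny)
    ys <- matrix(seq_len(ny) - cy, nx, ny, byrow = TRUE)
    r <- sqrt(xs^2 + ys^2)
    theta <- atan2(ys, xs)                       # (-pi, pi]
    set.seed(as.integer(geometry_seed) %% .Machine$integer.max)
    cuts <- seq(-pi, pi, length.out = n_mus + 1)
    if (n_mus > 1) {
      jit <- stats::runif(n_mus - 1, -0.5, 0.5) * (pi / n_mus) * 0.4
      cuts[2:n_mus] <- cuts[2:n_mus] + jit
    }
    sector <- findInterval(theta, cuts, rightmost.closed = TRUE)
    sector[sector < 1] <- 1L; sector[sector > n_mus] <- n_mus
    slice <- array(0L, dim = c(nx, ny))
    inside <- r <= R
    slice[inside] <- vapply(muscles, function(t) t$label_id,
                            integer(1))[sector[inside]]
    for (z in seq_len(nz)) labels[, , z][slice > 0] <- slice[slice > 0]

    counts <- table(factor(labels, levels = ids))
    small <- counts < 27
    if (any(small[!is_bg]))
      stop("grid too small: tissue(s) ",
           paste(names(muscles)[small[!is_bg]], collapse = ", "),
           " received fewer than 27 voxels")
  }

  fields <- c("T1", "T2", "T2star", "fat_fraction", "trate", "M0")
  maps <- lapply(fields, function(f) {
    m <- array(NA_real_, dim = grid_shape)
    for (t in tissues) m[labels == t$label_id] <- t[[f]]
    m
  })
  names(maps) <- fields

  if (variation_amp > 0) {
    ph <- stats::runif(4, 0, 2 * pi)
    gx <- array(rep(seq_len(nx), times = ny * nz), dim = grid_shape)
    gy <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = grid_shape)
    field <- 1 + variation_amp *
      sin(2 * pi * gx / nx + ph[1]) * sin(2 * pi * gy / ny + ph[2])
    for (f in c("T1", "T2", "T2star", "trate", "M0"))
      maps[[f]] <- maps[[f]] * field
    # keep the physical ordering and FF bounds intact under modulation
    maps$T2star <- pmin(maps$T2star, maps$T2)
  }

  structure(list(labels = labels, maps = maps, tissues = tissues,
                 grid_shape = grid_shape,
                 geometry_seed = as.integer(geometry_seed),
                 variation_amp = variation_amp),
            class = "muscle_phantom")
}

#' @export
print.muscle_phantom <- function(x, ...) {
  cat("Digital calf phantom:", paste(x$grid_shape, collapse = " x "),
      "voxels\n")
  cnt <- table(x$labels)
  for (t in x$tissues)
    cat(sprintf("  %-10s label %d: %6d voxels, TRATE %.2f mM^-1 s^-1\n",
                t$name, t$label_id,
                as.integer(cnt[as.character(t$label_id)]), t$trate))
  invisible(x)
}

#' Ground-truth contrast-agent concentration curve
#'
#' Evaluates the wash-in kinetic model on a time axis:
#' zero before `t_arrival`, then a mono-exponential rise
#' `C_eq * (1 - exp(-k_washin * (t - t_arrival)))` towards the plateau.
#'
#' @param model A [kinetic_model()].
#' @param time_axis Strictly increasing non-negative times, seconds.
#' @return Numeric vector of concentrations in mM, one per time point.
#' @examples
#' km <- kinetic_model(t_arrival = 90, C_eq = 0.08, k_washin = 0.02)
#' concentration_truth(km, c(0, 90, 140, 700))
#' @export
concentration_truth <- function(model, time_axis) {
  stopifnot(inherits(model, "kinetic_model"))
  if (any(time_axis < 0)) stop("negative times are not allowed")
  if (length(time_axis) > 1 && any(diff(time_axis) <= 0))
    stop("time axis must be strictly increasing")
  ct <- ifelse(time_axis < model$t_arrival, 0,
               model$C_eq *
                 (1 - exp(-model$k_washin * (time_axis - model$t_arrival))))
  as.numeric(ct)
}

#' Spoiled gradient-echo steady-state signal
#'
#' The standard SPGR magnitude signal,
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a)) exp(-TE/T2*)` with
#' `E1 = exp(-TR/T1)`. This is the forward model that variable-flip-angle
#' T1 fitting inverts, and (with time-varying R1 and R2*) the per-frame
#' model of the dynamic series.
#'
#' All arguments vectorize.
#'
#' @param T1,T2star Relaxation times, ms (> 0).
#' @param M0 Equilibrium magnetization, arbitrary units.
#' @param TR,TE Repetition/echo time, ms.
#' @param flip_angle Flip angle in degrees, in (0, 180).
#' @return Magnitude signal, arbitrary units.
#' @examples
#' spgr_signal(T1 = 1000, T2star = 30, M0 = 1, TR = 7.7, TE = 4.6,
#'             flip_angle = 20)
#' @export
spgr_signal <- function(T1, T2star, M0, TR, TE, flip_angle) {
  if (any(T1 <= 0) || any(T2star <= 0) || any(TR <= 0))
    stop("T1, T2star and TR must be > 0")
  if (any(flip_angle <= 0) || any(flip_angle >= 180))
    stop("flip_angle must be in (0, 180) degrees")
  a <- flip_angle * pi / 180
  E1 <- exp(-TR / T1)
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a)) * exp(-TE / T2star)
}

#' Add Rician noise to a magnitude image
#'
#' Gaussian noise of the given standard deviation is added independently
#' to the two quadrature channels (the signal is taken to lie on the real
#' channel) and the magnitude is returned. At zero signal this gives the
#' Rayleigh floor with mean `sd * sqrt(pi/2)`; no Gaussian approximation
#' is made, so low-SNR bias is representable.
#'
#' @param signal Noise-free magnitude array.
#' @param sd Noise standard deviation per channel (>= 0).
#' @return Array of noisy magnitudes, same shape as `signal`.
#' @export
rician_noise <- function(signal, sd) {
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(signal)
  n <- length(signal)
  re <- signal + stats::rnorm(n, sd = sd)
  im <- stats::rnorm(n, sd = sd)
  out <- sqrt(re^2 + im^2)
  dim(out) <- dim(signal)
  out
}

#' Simulate one acquisition protocol on the phantom
#'
#' Applies the protocol's forward signal model voxelwise to the phantom's
#' ground-truth maps and (optionally) adds Rician noise:
#' \describe{
#'   \item{spgr_vfa}{[spgr_signal()] at each flip angle (4-D output:
#'     x, y, z, flip).}
#'   \item{multi_echo_gre}{[spgr_signal()] at each echo, T2* decay
#'     (x, y, z, echo).}
#'   \item{multi_echo_se}{`S(TE) = M0 exp(-TE/T2)` (x, y, z, echo).}
#'   \item{dixon_pair}{in-phase `W + F` and opposed-phase `|W - F|`
#'     magnitudes with `F = fat_fraction * M0` (x, y, z, 2).}
#'   \item{dual_echo_dynamic}{per-frame SPGR with time-varying rates
#'     `R1(t) = 1/T1 + r1 Ct(t)` and `R2*(t) = 1/T2* + TRATE Ct(t)`
#'     (x, y, z, echo, time). Requires `kinetics`.}
#' }
#'
#' @param phantom A [build_phantom()] result.
#' @param protocol An [mr_protocol()].
#' @param kinetics A [kinetic_model()]; required iff the protocol is the
#'   dual-echo dynamic, ignored otherwise.
#' @param agent A [contrast_agent()] (dynamic protocol only).
#' @param noise_sd Rician noise sd in signal units (0 = noise-free).
#' @param seed Integer seed for the noise stream.
#' @return Object of class `mr_series`: list with `data` (the magnitude
#'   array), `protocol`, `noise_sd`, `seed`, and for the dynamic protocol
#'   `time_axis` (s), `injection_time` (s) and `agent`. The dynamic
#'   series additionally has class `dynamic_series`.
#' @export
simulate_acquisition <- function(phantom, protocol, kinetics = NULL,
                                 agent = contrast_agent(), noise_sd = 0,
                                 seed = 1L) {
  stopifnot(inherits(phantom, "muscle_phantom"),
            inherits(protocol, "mr_protocol"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  m <- phantom$maps
  kind <- protocol$sequence_kind
  dyn <- kind == "dual_echo_dynamic"
  if (dyn && is.null(kinetics))
    stop("dual_echo_dynamic protocol requires a kinetic model")
  if (!dyn && !is.null(kinetics))
    warning("kinetics ignored for non-dynamic protocol")

  gs <- phantom$grid_shape
  data <- switch(kind,
    spgr_vfa = {
      fa <- protocol$flip_angles
      out <- array(0, dim = c(gs, length(fa)))
      for (i in seq_along(fa))
        out[, , , i] <- spgr_signal(m$T1, m$T2star, m$M0, protocol$TR,
                                    protocol$TE_list[1], fa[i])
      out
    },
    multi_echo_gre = {
      te <- protocol$TE_list
      out <- array(0, dim = c(gs, length(te)))
      for (i in seq_along(te))
        out[, , , i] <- spgr_signal(m$T1, m$T2star, m$M0, protocol$TR,
                                    te[i], protocol$flip_angles[1])
      out
    },
    multi_echo_se = {
      te <- protocol$TE_list
      out <- array(0, dim = c(gs, length(te)))
      for (i in seq_along(te))
        out[, , , i] <- m$M0 * exp(-te[i] / m$T2)
      out
    },
    dixon_pair = {
      W <- (1 - m$fat_fraction) * m$M0
      Fm <- m$fat_fraction * m$M0
      out <- array(0, dim = c(gs, 2))
      out[, , , 1] <- W + Fm
      out[, , , 2] <- abs(W - Fm)
      out
    },
    dual_echo_dynamic = {
      nt <- protocol$n_dynamics
      tax <- (seq_len(nt) - 1) * protocol$dt_dynamic
      ct <- concentration_truth(kinetics, tax)
      te_s <- protocol$TE_list / 1000
      tr_s <- protocol$TR / 1000
      a <- protocol$flip_angles[1] * pi / 180
      R1_0 <- 1000 / m$T1        # s^-1
      R2s_0 <- 1000 / m$T2star   # s^-1
      out <- array(0, dim = c(gs, 2, nt))
      for (ti in seq_len(nt)) {
        R1 <- R1_0 + agent$r1 * ct[ti]
        R2s <- R2s_0 + m$trate * ct[ti]
        E1 <- exp(-tr_s * R1)
        core <- m$M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
        out[, , , 1, ti] <- core * exp(-te_s[1] * R2s)
        out[, , , 2, ti] <- core * exp(-te_s[2] * R2s)
      }
      out
    })

  if (noise_sd > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    data <- rician_noise(data, noise_sd)
  }

  out <- list(data = data, protocol = protocol, noise_sd = noise_sd,
              seed = as.integer(seed))
  cls <- "mr_series"
  if (dyn) {
    out$time_axis <- (seq_len(protocol$n_dynamics) - 1) * protocol$dt_dynamic
    out$injection_time <- kinetics$t_arrival
    out$agent <- agent
    out$kinetics <- kinetics
    cls <- c("dynamic_series", cls)
  }
  structure(out, class = cls)
}

#' @export
print.mr_series <- function(x, ...) {
  cat("MR series (", x$protocol$sequence_kind, "): dims ",
      paste(dim(x$data), collapse = " x "),
      if (x$noise_sd > 0) sprintf(", Rician noise sd %.3g", x$noise_sd)
      else ", noise-free", "\n", sep = "")
  invisible(x)
}
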