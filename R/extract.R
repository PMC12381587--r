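# Kinematic angle extraction from 3-D landmark tracks.

track_point_matrix <- function(track, name) {
  tab <- track$points[track$points$point == name, ]
  if (nrow(tab) == 0) {
    stop("landmark track is missing point `", name, "`", call. = FALSE)
  }
  tab <- tab[order(tab$frame), ]
  m <- cbind(tab$x_m, tab$y_m, tab$z_m)
  if (any(!is.finite(m))) {
    stop("non-finite coordinates for point `", name, "`", call. = FALSE)
  }
  m
}

# local maxima of a series with parabolic sub-sample refinement;
# returns fractional frame indices
find_peaks_refined <- function(y, min_sep = 3L) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) >= min_sep)]
  vapply(idx, function(i) {
    if (i <= 1L || i >= n) return(as.numeric(i))
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (den >= 0) return(as.numeric(i))
    i + 0.5 * (y[i - 1] - y[i + 1]) / den
  }, numeric(1))
}

# least-squares plane through the origin: unit normal (z >= 0) of the
# plane minimising sum((n . w)^2)
origin_plane_normal <- function(W) {
  Mmat <- crossprod(W)
  eg <- eigen(Mmat, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], .Machine$double.eps)) {
    stop("no stroke plane: wingtip path is (near-)collinear", call. = FALSE)
  }
  nrm <- eg$vectors[, 3]
  # orient the normal: a forward-flight stroke plane is inclined by
  # beta in (0, ~180) deg, so its normal points backwards (nx < 0);
  # for a near-horizontal stroke plane fall back to "normal up"
  if (abs(nrm[1]) > 0.2) {
    if (nrm[1] > 0) nrm <- -nrm
  } else if (nrm[3] < 0) {
    nrm <- -nrm
  }
  nrm
}

plane_angles <- function(nrm) {
  # normal of the stroke frame z-axis: (-sin(b) cos(br), -sin(br),
  # cos(b) cos(br)) for the right wing
  beta_r <- asin(pmin(pmax(-nrm[2], -1), 1))
  beta <- atan2(-nrm[1], nrm[3])
  c(beta = beta, beta_r = beta_r)
}

#' Extract body and wing kinematic angles from a landmark track
#'
#' Per frame, purely geometric quantities: body pitch `chi` (angle of the
#' head-to-abdomen-tip axis above the horizontal), sweep `phi` and
#' deviation `theta` (azimuth and elevation of the hinge-to-wingtip vector
#' in the stroke-plane frame) and feathering `alpha` (angle of the wing
#' plane, spanned by the hinge, wingtip and inner-angle points, measured
#' from the stroke plane). Per wingstroke: the stroke plane is the
#' least-squares plane of the hinge-relative wingtip path, giving the
#' stroke-plane angle `beta` and roll `beta_r`. Wingstroke boundaries sit
#' at the (sub-sample refined) maxima of the sweep angle, i.e. at dorsal
#' stroke reversal; the wingbeat frequency is refined by minimising the
#' sweep-waveform fit residual. Body velocities `u`, `w` come from the
#' analytic derivative of a Fourier-plus-drift fit to the centre-of-mass
#' proxy (default: the thorax-abdomen junction), not from raw frame
#' differences.
#'
#' @param track A `landmark_track` (see [synth_landmarks()],
#'   [read_landmarks()]).
#' @param f Optional known wingbeat frequency (Hz); estimated from the
#'   track when `NULL`.
#' @param com_frac Position of the centre-of-mass proxy along the
#'   thorax-abdomen-junction to abdomen-tip segment (0 = junction).
#' @param K Fourier order for the velocity fit (default 3).
#' @return A tibble with columns `t_s`, `chi_deg`, `beta_deg`,
#'   `betar_deg`, `phi_deg`, `theta_deg`, `alpha_deg`, `u_ms`, `w_ms`,
#'   `stroke`, with the estimated frequency in attribute `f_hz`.
#' @export
extract_kinematics <- function(track, f = NULL, com_frac = 0, K = 3L) {
  stopifnot(inherits(track, "landmark_track"))
  head_m <- track_point_matrix(track, "head")
  ta <- track_point_matrix(track, "thorax_abdomen")
  abd <- track_point_matrix(track, "abdomen_tip")
  hinge <- track_point_matrix(track, "hinge_R")
  tip <- track_point_matrix(track, "wingtip_R")
  inner <- track_point_matrix(track, "inner_angle_R")
  n <- nrow(head_m)
  t <- (seq_len(n) - 1) / track$frame_rate

  ax <- head_m - abd
  chi <- atan2(ax[, 3], sqrt(ax[, 1]^2 + ax[, 2]^2))

  W <- tip - hinge
  angles_on_plane <- function(W, nrm) {
    pa <- plane_angles(nrm)
    Rs <- rot_y(-pa[["beta"]]) %*% rot_x(pa[["beta_r"]])
    Ws <- W %*% Rs  # rows: W in stroke frame (W %*% Rs = t(t(Rs) %*% t(W)))
    phi <- atan2(Ws[, 1], -Ws[, 2])
    theta <- asin(pmin(pmax(Ws[, 3] / sqrt(rowSums(W^2)), -1), 1))
    list(beta = pa[["beta"]], beta_r = pa[["beta_r"]], Rs = Rs,
         phi = phi, theta = theta)
  }
  glob <- angles_on_plane(W, origin_plane_normal(W))

  # stroke segmentation at sweep maxima (dorsal reversal)
  pk <- find_peaks_refined(glob$phi)
  stroke <- rep(1L, n)
  if (length(pk) >= 1L) {
    stroke <- findInterval(seq_len(n), pk) + 1L
    stroke[stroke < 2L] <- 2L  # lead-in frames join the first full stroke
    stroke <- stroke - 1L
  }
  n_strokes <- max(stroke)

  # frequency: peak spacing, refined by sweep-fit residual
  if (is.null(f)) {
    if (length(pk) >= 2L) {
      f0 <- track$frame_rate / mean(diff(pk))
      rss <- function(ff) {
        wf <- fit_fourier(t, glob$phi, ff, K = K)
        sum((glob$phi - eval_waveform(wf, t))^2)
      }
      f <- stats::optimize(rss, f0 * c(0.95, 1.05),
                           tol = .Machine$double.eps^0.5 * f0)$minimum
    } else {
      stop("cannot estimate wingbeat frequency: fewer than two sweep maxima",
           call. = FALSE)
    }
  }

  # per-stroke stroke planes, then final per-frame wing angles
  beta_fr <- numeric(n); betar_fr <- numeric(n)
  phi_fr <- numeric(n); theta_fr <- numeric(n); alpha_fr <- numeric(n)
  for (s in seq_len(n_strokes)) {
    sel <- stroke == s
    res <- angles_on_plane(W[sel, , drop = FALSE],
                           origin_plane_normal(W[sel, , drop = FALSE]))
    beta_fr[sel] <- res$beta
    betar_fr[sel] <- res$beta_r
    phi_fr[sel] <- res$phi
    theta_fr[sel] <- res$theta
    # feathering from the wing plane (hinge, wingtip, inner angle)
    Wsel <- W[sel, , drop = FALSE]
    shat <- Wsel / sqrt(rowSums(Wsel^2))
    q <- inner[sel, , drop = FALSE] - hinge[sel, , drop = FALSE]
    qperp <- q - rowSums(q * shat) * shat
    qn <- sqrt(rowSums(qperp^2))
    bhat <- -qperp / qn
    bs <- bhat %*% res$Rs
    cp <- cos(res$phi); sp <- sin(res$phi); st <- sin(res$theta)
    ct <- cos(res$theta)
    # b_s = cos(a) c0 - sin(a) m0, c0 = (cp, sp, 0), m0 = (-sp st, cp st, ct)
    proj_c0 <- bs[, 1] * cp + bs[, 2] * sp
    proj_m0 <- -bs[, 1] * sp * st + bs[, 2] * cp * st + bs[, 3] * ct
    alpha_fr[sel] <- atan2(-proj_m0, proj_c0)
  }

  # body velocity from a Fourier + linear-drift fit of the COM proxy
  proxy <- ta + com_frac * (abd - ta)
  Xd <- matrix(1, n, 2L * K + 2L)
  Xd[, 2] <- t
  for (k in seq_len(K)) {
    th <- 2 * pi * k * f * t
    Xd[, 2L * k + 1L] <- cos(th)
    Xd[, 2L * k + 2L] <- sin(th)
  }
  dXd <- matrix(0, n, 2L * K + 2L)
  dXd[, 2] <- 1
  for (k in seq_len(K)) {
    wk <- 2 * pi * k * f
    dXd[, 2L * k + 1L] <- -wk * sin(wk * t)
    dXd[, 2L * k + 2L] <- wk * cos(wk * t)
  }
  qrX <- qr(Xd)
  vel_of <- function(y) {
    beta <- qr.coef(qrX, y)
    beta[is.na(beta)] <- 0
    drop(dXd %*% beta)
  }
  u <- vel_of(proxy[, 1])
  w <- vel_of(proxy[, 3])

  out <- tibble::tibble(
    t_s = t,
    chi_deg = chi / DEG, beta_deg = beta_fr / DEG, betar_deg = betar_fr / DEG,
    phi_deg = phi_fr / DEG, theta_deg = theta_fr / DEG,
    alpha_deg = alpha_fr / DEG,
    u_ms = u, w_ms = w, stroke = stroke)
  attr(out, "f_hz") <- f
  out
}

#' Fit Fourier waveforms to an extracted kinematics table
#'
#' Convenience wrapper: fits order-`K` series to each angle and velocity
#' column of an [extract_kinematics()] table at its estimated (or given)
#' frequency, returning ready-to-use kinematics objects.
#'
#' @param kin A tibble from [extract_kinematics()].
#' @param f Wingbeat frequency; defaults to the table's `f_hz` attribute.
#' @param K Fourier order (default 3).
#' @return A list with `wing_kin` ([wing_kinematics()]), `body_kin`
#'   ([body_kinematics()]) and `f`.
#' @export
fit_kinematics <- function(kin, f = NULL, K = 3L) {
  f <- f %||% attr(kin, "f_hz")
  if (is.null(f)) stop("supply `f` or use a table with an `f_hz` attribute",
                       call. = FALSE)
  fitw <- function(col) fit_fourier(kin$t_s, kin[[col]], f, K = K)
  wing <- wing_kinematics(
    phi = fitw("phi_deg"), theta = fitw("theta_deg"),
    alpha = fitw("alpha_deg"), beta = fitw("beta_deg"),
    beta_r = mean(kin$betar_deg))
  body <- body_kinematics(chi = fitw("chi_deg"), u = fitw("u_ms"),
                          w = fitw("w_ms"))
  list(wing_kin = wing, body_kin = body, f = f)
}
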