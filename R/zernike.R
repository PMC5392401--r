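#' OSA/ANSI Zernike index table
#'
#' Enumerates the (n, m) double indices up to a maximal radial order in
#' OSA/ANSI single-index order `j = (n(n+2)+m)/2`.
#'
#' @param max_order maximal radial order n.
#' @return data.frame with columns `j`, `n`, `m`.
#' @export
zernike_index_table <- function(max_order = 6) {
  out <- do.call(rbind, lapply(0:max_order, function(n) {
    m <- seq(-n, n, by = 2)
    data.frame(j = (n * (n + 2) + m) / 2, n = n, m = m)
  }))
  out[order(out$j), , drop = FALSE]
}

# radial polynomial R_n^{|m|}(rho), vectorized in rho
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  smax <- (n - m) / 2
  out <- 0
  for (s in 0:smax) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

#' Evaluate the orthonormal Zernike basis
#'
#' OSA/ANSI-ordered Zernike polynomials, normalized to unit RMS over the
#' unit disc (`N = sqrt(2(n+1)/(1+delta_m0))`), evaluated at normalized
#' pupil coordinates.
#'
#' @param u,v normalized pupil coordinates (rho <= 1).
#' @param max_order maximal radial order.
#' @return matrix (length(u) x n_terms); the index table is attached as
#'   `attr(, "index")`.
#' @export
zernike_basis <- function(u, v, max_order = 6) {
  tab <- zernike_index_table(max_order)
  rho <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  Z <- matrix(0, length(u), nrow(tab))
  for (i in seq_len(nrow(tab))) {
    n <- tab$n[i]; m <- tab$m[i]
    nrm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
    R <- zernike_radial(n, m, rho)
    Z[, i] <- if (m > 0) nrm * R * cos(m * th)
              else if (m < 0) nrm * R * sin(-m * th)
              else nrm * R
  }
  attr(Z, "index") <- tab
  Z
}

#' Least-squares Zernike decomposition of a wavefront map
#'
#' Fits the orthonormal OSA/ANSI basis (radial order <= `max_order`) to
#' the valid OPD samples. With unit-RMS-normalized polynomials, each
#' coefficient is the RMS contribution of its mode in waves.
#'
#' @param map a `wavefront_map` (or compatible list with `u`, `v`, `opd`,
#'   `mask`).
#' @param max_order maximal radial order (default 6).
#' @return object of class `zernike_spectrum`: `coefficients` (waves),
#'   `index` table, `residual_rms` (waves), `pupil_radius_mm`.
#' @export
fit_zernike <- function(map, max_order = 6) {
  ok <- map$mask
  tab <- zernike_index_table(max_order)
  if (sum(ok) < 3 * nrow(tab))
    stop("too few valid samples for a stable Zernike fit")
  Z <- zernike_basis(map$u[ok], map$v[ok], max_order)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("rank-deficient Zernike design matrix (catastrophic vignetting)")
  co <- qr.coef(qrz, map$opd[ok])
  res <- map$opd[ok] - Z %*% co
  out <- list(coefficients = as.numeric(co), index = tab,
              residual_rms = sqrt(mean(res^2)),
              pupil_radius_mm = map$pupil_radius_mm %||% NA_real_)
  class(out) <- "zernike_spectrum"
  out
}

#' @export
print.zernike_spectrum <- function(x, ...) {
  cat("zernike_spectrum (waves):\n")
  df <- cbind(x$index, coefficient = x$coefficients)
  print(df[abs(df$coefficient) > 1e-6, ], row.names = FALSE)
  cat(sprintf("fit residual RMS: %.2e waves\n", x$residual_rms))
  invisible(x)
}

#' RMS wavefront error of a map
#'
#' Root-mean-square of the OPD samples after removing the least-squares
#' piston (and, by default, tilt — tilt encodes image displacement, which
#' the decentration study reports separately as retinal image shift).
#'
#' @param map a `wavefront_map`.
#' @param remove terms to remove: `c("piston","tilt")` or `"piston"`.
#' @return RMS in waves.
#' @export
rms_wavefront <- function(map, remove = c("piston", "tilt")) {
  remove <- match.arg(remove, c("piston", "tilt"), several.ok = TRUE)
  ok <- map$mask
  w <- map$opd[ok]
  X <- if ("tilt" %in% remove) cbind(1, map$u[ok], map$v[ok]) else
    matrix(1, length(w), 1)
  res <- stats::lm.fit(X, w)$residuals
  sqrt(mean(res^2))
}

#' Synthesize a wavefront map from Zernike coefficients
#'
#' Builds an OPD map on the standard pupil grid from given coefficients
#' of the orthonormal OSA/ANSI basis — the injected-wavefront fixture
#' that exercises the Zernike fit and the Fourier metric chain with
#' analytically known input.
#'
#' @param coefficients numeric vector of coefficients in waves, indexed by
#'   OSA index j starting at j = 0 (position 1 = piston).
#' @param n_grid grid points per side.
#' @param pupil_radius_mm nominal pupil radius carried in metadata.
#' @param wavelength_nm wavelength carried in metadata.
#' @return a `wavefront_map`.
#' @export
make_injected_zernike <- function(coefficients, n_grid = 64,
                                  pupil_radius_mm = 1.5,
                                  wavelength_nm = 587.6) {
  g <- seq(-1, 1, length.out = n_grid)
  gg <- expand.grid(iu = seq_len(n_grid), iv = seq_len(n_grid))
  u <- g[gg$iu]; v <- g[gg$iv]
  keep <- u^2 + v^2 <= 1 + 1e-12
  u <- u[keep]; v <- v[keep]
  max_order <- 0
  while ((max_order + 1) * (max_order + 2) / 2 < length(coefficients))
    max_order <- max_order + 1
  Z <- zernike_basis(u, v, max_order)
  co <- rep(0, ncol(Z))
  co[seq_along(coefficients)] <- coefficients
  wf <- list(n_grid = n_grid, u = u, v = v,
             iu = gg$iu[keep], iv = gg$iv[keep],
             opd = as.numeric(Z %*% co), mask = rep(TRUE, length(u)),
             pupil_radius_mm = pupil_radius_mm,
             wavelength_nm = wavelength_nm)
  class(wf) <- "wavefront_map"
  wf
}
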