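#' Van Genuchten-Mualem hydraulic parameter set
#'
#' @param theta_r,theta_s Residual and saturated water contents (cm3 cm-3),
#'   with 0 <= theta_r < theta_s <= 1.
#' @param alpha Inverse air-entry pressure (cm-1), > 0.
#' @param n Shape parameter (-), > 1.  Mualem closure uses m = 1 - 1/n and
#'   tortuosity L = 0.5.
#' @param ks Saturated hydraulic conductivity (cm d-1), > 0.
#' @param pwp_measured Optional laboratory wilting-point water content
#'   (cm3 cm-3).  An independent datum: it is stored, never derived from the
#'   retention curve (the two need not agree).
#' @return List of class `vg_params`.
#' @export
vg_params <- function(theta_r, theta_s, alpha, n, ks, pwp_measured = NA) {
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1))
    stop("vg_params: need 0 <= theta_r < theta_s <= 1")
  if (alpha <= 0) stop("vg_params: alpha must be > 0")
  if (n <= 1) stop("vg_params: n must be > 1")
  if (ks <= 0) stop("vg_params: ks must be > 0")
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n = n, ks = ks, pwp_measured = pwp_measured),
            class = "vg_params")
}

#' Van Genuchten water retention
#'
#' theta(h) = theta_r + (theta_s - theta_r) * (1 + (alpha*|h|)^n)^(-m) for
#' h < 0, theta_s at or above saturation.
#'
#' @param h Matric head in cm (negative when unsaturated); vectorized.
#' @param p A [vg_params()].
#' @return Volumetric water content (cm3 cm-3).
#' @export
vg_theta <- function(h, p) {
  se <- vg_se(h, p)
  p$theta_r + se * (p$theta_s - p$theta_r)
}

#' Effective saturation Se(h)
#' @inheritParams vg_theta
#' @return Se in \[0, 1\].
#' @export
vg_se <- function(h, p) {
  m <- 1 - 1 / p$n
  ifelse(h >= 0, 1, (1 + (p$alpha * abs(h))^p$n)^(-m))
}

#' Mualem-van Genuchten unsaturated hydraulic conductivity
#'
#' K(h) = Ks * Se^0.5 * (1 - (1 - Se^(1/m))^m)^2 with m = 1 - 1/n.
#'
#' @inheritParams vg_theta
#' @return Conductivity in cm d-1.
#' @export
vg_k <- function(h, p) {
  m <- 1 - 1 / p$n
  se <- vg_se(h, p)
  vg_k_se(se, p)
}

#' Mualem conductivity from effective saturation
#' @param se Effective saturation in \[0, 1\].
#' @param p A [vg_params()].
#' @return Conductivity in cm d-1.
#' @export
vg_k_se <- function(se, p) {
  m <- 1 - 1 / p$n
  se <- pmin(pmax(se, 0), 1)
  p$ks * sqrt(se) * (1 - (1 - se^(1 / m))^m)^2
}

#' Matric head from water content (inverse retention)
#' @param theta Water content (cm3 cm-3), within (theta_r, theta_s\].
#' @param p A [vg_params()].
#' @return Matric head in cm (<= 0).
#' @export
vg_h <- function(theta, p) {
  m <- 1 - 1 / p$n
  se <- (theta - p$theta_r) / (p$theta_s - p$theta_r)
  se <- pmin(pmax(se, 1e-12), 1)
  ifelse(se >= 1, 0, -(1 / p$alpha) * (se^(-1 / m) - 1)^(1 / p$n))
}

#' A soil horizon
#'
#' @param top,bottom Horizon boundaries (cm, depth positive downward),
#'   top < bottom.
#' @param vg A [vg_params()].
#' @param bulk_density Bulk density (g cm-3).
#' @param sand,silt,clay Texture percentages; must sum to 100 +/- 0.5 if all
#'   are given.
#' @param name Optional horizon label.
#' @return List of class `soil_horizon`.
#' @export
soil_horizon <- function(top, bottom, vg, bulk_density = NA,
                         sand = NA, silt = NA, clay = NA, name = NA) {
  if (!(top < bottom)) stop("soil_horizon: need top < bottom")
  if (!inherits(vg, "vg_params")) stop("soil_horizon: vg must be vg_params")
  if (!anyNA(c(sand, silt, clay)) && abs(sand + silt + clay - 100) > 0.5)
    stop("soil_horizon: texture fractions must sum to 100 +/- 0.5")
  structure(list(top = top, bottom = bottom, vg = vg,
                 bulk_density = bulk_density, sand = sand, silt = silt,
                 clay = clay, name = name),
            class = "soil_horizon")
}

#' Build a 1-D finite-difference soil grid
#'
#' Cell-centered grid from the surface down to `domain_depth`.  Horizons must
#' be contiguous from 0; below the deepest described horizon its parameters
#' extend to the bottom of the domain.
#'
#' @param horizons List of [soil_horizon()] objects ordered by depth.
#' @param dz Cell thickness in cm (default 1).
#' @param domain_depth Domain depth in cm (default 150).
#' @return List of class `soil_grid` with node depths `z` (cell centers, cm),
#'   `dz`, `n` nodes, `horizon` index per node, and per-node hydraulic
#'   parameter vectors.
#' @export
build_grid <- function(horizons, dz = 1, domain_depth = 150) {
  if (dz <= 0) stop("build_grid: dz must be positive")
  tops <- vapply(horizons, `[[`, numeric(1), "top")
  bots <- vapply(horizons, `[[`, numeric(1), "bottom")
  o <- order(tops)
  tops <- tops[o]; bots <- bots[o]; horizons <- horizons[o]
  if (tops[1] != 0) stop("build_grid: profile error, first horizon must start at 0")
  if (length(tops) > 1 && any(abs(tops[-1] - bots[-length(bots)]) > 1e-9))
    stop("build_grid: profile error, horizons overlap or leave a gap")
  n <- round(domain_depth / dz)
  if (abs(n * dz - domain_depth) > 1e-9)
    stop("build_grid: dz must divide the domain depth")
  z <- (seq_len(n) - 0.5) * dz
  hidx <- findInterval(z, c(tops, domain_depth + dz), rightmost.closed = TRUE)
  hidx <- pmin(hidx, length(horizons))  # deepest horizon extends to the bottom
  field <- function(what) vapply(horizons, function(hh) hh$vg[[what]], numeric(1))[hidx]
  structure(list(
    z = z, dz = dz, n = n, domain_depth = domain_depth,
    horizon = hidx, n_horizons = length(horizons), horizons = horizons,
    theta_r = field("theta_r"), theta_s = field("theta_s"),
    alpha = field("alpha"), vg_n = field("n"), ks = field("ks")
  ), class = "soil_grid")
}

#' Map sensor depths to grid node indices
#' @param grid A [soil_grid()].
#' @param depths Depths in cm.
#' @return Integer node indices of the nearest cell centers.
#' @export
sensor_nodes <- function(grid, depths) {
  vapply(depths, function(d) which.min(abs(grid$z - d)), integer(1))
}
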