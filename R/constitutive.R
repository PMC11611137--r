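#' Constitutive parameters of the fiber-reinforced wall model
#'
#' Parameters of the Holzapfel--Gasser--Ogden (HGO) strain-energy function
#' used to describe radial compression of the aneurysmal wall: an isotropic
#' neo-Hookean ground matrix of stiffness `c` plus two symmetric families of
#' collagen fibers inclined at +/- `phi` from the circumferential direction,
#' with initial stiffness `k` and exponential stiffening exponent `k2`.
#'
#' `c` and `k` carry units of kPa, consistent with contact pressures in kPa.
#' `phi` and `k2` are dimensionless constants held fixed for all patients
#' (defaults 0.546 rad and 15).
#'
#' @param c Ground-matrix stiffness \[kPa\], `c >= 0`.
#' @param k Fiber initial stiffness \[kPa\], `k >= 0`.
#' @param k2 Fiber stiffening exponent (dimensionless), `k2 >= 0`.
#' @param phi Fiber declination from the circumferential direction
#'   \[radians\], in `[0, pi/2]`.
#' @return An object of class `hgo_params`.
#' @examples
#' hgo_params(c = 5, k = 20)
#' @export
hgo_params <- function(c, k, k2 = 15, phi = 0.546) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(k2), length(k2) == 1L, is.finite(k2),
            is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (c < 0 || k < 0 || k2 < 0) {
    stop("stiffness parameters 'c', 'k', 'k2' must be non-negative")
  }
  if (phi < 0 || phi > pi / 2) {
    stop("'phi' must lie in [0, pi/2]")
  }
  structure(list(c = c, k = k, k2 = k2, phi = phi), class = "hgo_params")
}

#' @export
print.hgo_params <- function(x, ...) {
  cat(sprintf(
    "HGO parameters: c = %g kPa, k = %g kPa, k2 = %g, phi = %g rad\n",
    x$c, x$k, x$k2, x$phi))
  invisible(x)
}

#' Incompressible triaxial deformation state
#'
#' Principal stretches of a homogeneous deformation of an incompressible
#' specimen, in the circumferential / axial / radial frame of the vessel
#' wall.  Incompressibility (`lambda_c * lambda_a * lambda_r = 1`, volume
#' ratio `J = 1`) is enforced at construction to within `1e-10`.
#'
#' @param lambda_c,lambda_a,lambda_r Circumferential, axial and radial
#'   stretches (dimensionless, positive).
#' @return An object of class `deformation_state` with fields `lambda_c`,
#'   `lambda_a`, `lambda_r` and `J`.
#' @export
deformation_state <- function(lambda_c, lambda_a, lambda_r) {
  l <- c(lambda_c, lambda_a, lambda_r)
  stopifnot(is.numeric(l), length(l) == 3L, all(is.finite(l)))
  if (any(l <= 0)) stop("all stretches must be positive")
  J <- lambda_c * lambda_a * lambda_r
  if (abs(J - 1) > 1e-10) {
    stop(sprintf("deformation is not incompressible: J = %.12g", J))
  }
  structure(list(lambda_c = lambda_c, lambda_a = lambda_a,
                 lambda_r = lambda_r, J = 1),
            class = "deformation_state")
}

# Fiber pseudo-invariant I4 = I6 = a0 . C a0 for the symmetric +/- phi
# families under a principal-stretch deformation (C diagonal).
fiber_invariant <- function(params, lambda_c, lambda_a) {
  lambda_c^2 * cos(params$phi)^2 + lambda_a^2 * sin(params$phi)^2
}

# d(Psi_aniso per family)/dI4 = k (I4 - 1) exp(k2 (I4 - 1)^2), with the
# tension-compression switch: fibers carry load only when extended (I4 > 1).
# The exponent is capped to keep the root-finder's bracket values finite;
# the cap is far beyond any equilibrium solution.
fiber_dpsi <- function(params, I4) {
  e <- I4 - 1
  H <- ifelse(e > 0, e * exp(pmin(params$k2 * e^2, 500)), 0)
  params$k * H
}

#' Strain-energy density of the wall model
#'
#' Evaluates the incompressible HGO strain-energy density
#' `Psi = c/2 (I1 - 3) + k/(2 k2) * sum_{i=4,6} (exp(k2 (I_i - 1)^2) - 1)`
#' at a given deformation state, with fiber pseudo-invariants
#' `I4 = a01 . C a01`, `I6 = a02 . C a02` for undeformed fiber directions
#' `a01 = (cos phi, sin phi, 0)`, `a02 = (-cos phi, sin phi, 0)`.
#' Each anisotropic term contributes only when its fiber family is extended
#' (`I_i > 1`); under radial compression with in-plane expansion the fibers
#' are extended, so the switch is a robustness guard rather than an active
#' regime.
#'
#' @param params An [hgo_params()] object.
#' @param state A [deformation_state()] object.
#' @return Energy density \[kPa\] (zero at the undeformed reference).
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "hgo_params"),
            inherits(state, "deformation_state"))
  lc <- state$lambda_c; la <- state$lambda_a; lr <- state$lambda_r
  I1 <- lc^2 + la^2 + lr^2
  I4 <- fiber_invariant(params, lc, la)   # = I6 by symmetry of +/- phi
  psi_iso <- params$c / 2 * (I1 - 3)
  psi_one <- function(I) {
    if (I <= 1) return(0)
    if (params$k2 == 0) return(params$k / 2 * (I - 1)^2)
    params$k / (2 * params$k2) * expm1(params$k2 * (I - 1)^2)
  }
  psi_iso + psi_one(I4) + psi_one(I4)
}

# Partial derivatives of Psi w.r.t. the principal stretches (both fiber
# families folded in; I4 = I6).
dpsi_dstretch <- function(params, lc, la, lr) {
  I4 <- fiber_invariant(params, lc, la)
  dW <- 2 * fiber_dpsi(params, I4)        # both families
  list(dc = params$c * lc + 2 * dW * lc * cos(params$phi)^2,
       da = params$c * la + 2 * dW * la * sin(params$phi)^2,
       dr = params$c * lr)
}

# In-plane equilibrium residual for prescribed radial stretch lr:
# P_c = P_a = 0 with a common hydrostatic pressure requires
#   g(lc) = la dPsi/dla - lc dPsi/dlc = 0,  la = 1/(lc lr).
# Written in a factored form that keeps the sign correct when the fiber
# exponential saturates.
inplane_residual <- function(params, lc, lr) {
  la <- 1 / (lc * lr)
  I4 <- fiber_invariant(params, lc, la)
  dW <- 2 * fiber_dpsi(params, I4)
  params$c * (la^2 - lc^2) +
    2 * dW * (la^2 * sin(params$phi)^2 - lc^2 * cos(params$phi)^2)
}

# Solve the in-plane equilibrium for lambda_c at prescribed lambda_r.
# Returns list(lc, la).  The isotropic solution lc = la = lr^(-1/2) seeds
# the bracket, which is expanded geometrically until the residual changes
# sign.
solve_inplane <- function(params, lambda_r) {
  if (params$c == 0 && params$k == 0) {
    # degenerate zero-stiffness material: any in-plane state is an
    # equilibrium; return the isotropic one
    s <- lambda_r^(-0.5)
    return(list(lc = s, la = s))
  }
  f <- function(lc) inplane_residual(params, lc, lambda_r)
  s <- lambda_r^(-0.5)
  lo <- s * 0.999; hi <- s * 1.001
  flo <- f(lo); fhi <- f(hi)
  n_expand <- 0L
  # f is decreasing in lc near the root: f(lo) > 0 > f(hi) at the solution
  while (flo < 0 && n_expand < 200L) {
    lo <- lo * 0.99; flo <- f(lo); n_expand <- n_expand + 1L
  }
  while (fhi > 0 && n_expand < 400L) {
    hi <- hi * 1.01; fhi <- f(hi); n_expand <- n_expand + 1L
  }
  if (!(flo >= 0 && fhi <= 0)) {
    stop(sprintf(paste0(
      "in-plane equilibrium bracket failed at lambda_r = %.6g ",
      "(c = %g, k = %g): residuals %.3g / %.3g"),
      lambda_r, params$c, params$k, flo, fhi))
  }
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  lc <- r$root
  list(lc = lc, la = 1 / (lc * lambda_r))
}

#' Radial first Piola--Kirchhoff stress under uniaxial radial compression
#'
#' For a prescribed radial stretch `lambda_r <= 1`, solves the in-plane
#' equilibrium (zero circumferential and axial first Piola--Kirchhoff
#' stress, traction-free lateral faces, incompressibility) for the in-plane
#' stretches, eliminates the hydrostatic pressure through the in-plane
#' boundary conditions, and returns the magnitude of the compressive radial
#' first Piola--Kirchhoff stress, which equals the applied contact pressure.
#' `radial_stress(params, 1) == 0`, and the stress increases strictly as
#' `lambda_r` decreases.
#'
#' @param params An [hgo_params()] object.
#' @param lambda_r Radial stretch(es) in `(0, 1]`; vectorized.
#' @param full If `TRUE`, return a data frame with the equilibrium
#'   in-plane stretches as well.
#' @return Contact pressure(s) \[kPa\], or a data frame when `full = TRUE`.
#' @export
radial_stress <- function(params, lambda_r, full = FALSE) {
  stopifnot(inherits(params, "hgo_params"), is.numeric(lambda_r))
  if (any(!is.finite(lambda_r)) || any(lambda_r <= 0) || any(lambda_r > 1)) {
    stop("'lambda_r' must lie in (0, 1]")
  }
  one <- function(lr) {
    eq <- solve_inplane(params, lr)
    d <- dpsi_dstretch(params, eq$lc, eq$la, lr)
    p_h <- eq$lc * d$dc                   # from P_c = 0
    p_r <- p_h / lr - d$dr                # contact pressure = -P_r
    c(p_r = p_r, lc = eq$lc, la = eq$la)
  }
  out <- vapply(lambda_r, one, numeric(3))
  if (full) {
    data.frame(lambda_r = lambda_r, p_r = out["p_r", ],
               lambda_c = out["lc", ], lambda_a = out["la", ])
  } else {
    unname(out["p_r", ])
  }
}

#' Radial stretch at a given contact pressure
#'
#' Inverts [radial_stress()]: finds the radial stretch `lambda_r` at which
#' the compressive radial stress equals the applied contact pressure `p_r`,
#' by bracketed root-finding (Brent) on `lambda_r` in `lambda_range`.
#' `p_r = 0` returns 1 exactly.
#'
#' @param params An [hgo_params()] object.
#' @param p_r Contact pressure(s) \[kPa\], `>= 0`; vectorized.
#' @param lambda_range Admissible radial-stretch interval, default
#'   `c(0.61, 1)` (the deformation range over which the compression model
#'   is calibrated).
#' @param tol Root tolerance on `lambda_r`.
#' @return Radial stretch(es) in `lambda_range`.
#' @export
invert_pressure <- function(params, p_r, lambda_range = c(0.61, 1),
                            tol = 1e-8) {
  stopifnot(inherits(params, "hgo_params"), is.numeric(p_r),
            length(lambda_range) == 2L, lambda_range[1] > 0,
            lambda_range[2] <= 1, lambda_range[1] < lambda_range[2])
  if (any(!is.finite(p_r)) || any(p_r < 0)) {
    stop("'p_r' must be non-negative and finite")
  }
  p_max <- radial_stress(params, lambda_range[1])
  one <- function(p) {
    if (p == 0) return(1)
    if (p > p_max) {
      stop(sprintf(paste0(
        "contact pressure %.4g kPa exceeds the model's range at these ",
        "parameters: admissible pressures are [0, %.4g] kPa ",
        "(lambda_r in [%.3g, %.3g])"),
        p, p_max, lambda_range[1], lambda_range[2]))
    }
    f <- function(lr) radial_stress(params, lr) - p
    stats::uniroot(f, lambda_range, tol = tol,
                   f.lower = p_max - p, f.upper = -p)$root
  }
  vapply(p_r, one, numeric(1))
}

#' Small-strain equibiaxial stiffness implied by the wall model
#'
#' Initial tangent moduli of the equibiaxial tension response: the slope of
#' the circumferential and axial first Piola--Kirchhoff stresses with
#' respect to stretch at the undeformed state, along the equibiaxial path
#' `lambda_c = lambda_a = lambda`, `lambda_r = lambda^-2`, with the radial
#' face traction-free.  Closed form:
#' `E0_circ = 6 c + 8 k cos^2(phi)`, `E0_axial = 6 c + 8 k sin^2(phi)`.
#' Applied per posterior draw this yields stiffness quantiles comparable
#' with planar-biaxial literature values.
#'
#' @param params An [hgo_params()] object.
#' @return Named numeric vector `c(E0_circ, E0_axial)` \[kPa\].
#' @export
equibiaxial_initial_stiffness <- function(params) {
  stopifnot(inherits(params, "hgo_params"))
  c(E0_circ = 6 * params$c + 8 * params$k * cos(params$phi)^2,
    E0_axial = 6 * params$c + 8 * params$k * sin(params$phi)^2)
}

# Equibiaxial FPK stresses along lambda_c = lambda_a = lambda,
# lambda_r = lambda^-2, radial face traction-free (used as the independent
# finite-difference oracle for the initial stiffness).
equibiaxial_stress <- function(params, lambda) {
  vapply(lambda, function(l) {
    lr <- l^-2
    d <- dpsi_dstretch(params, l, l, lr)
    p_h <- lr * d$dr                      # from P_r = 0
    c(P_circ = d$dc - p_h / l, P_axial = d$da - p_h / l)
  }, numeric(2))
}
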