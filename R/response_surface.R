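#' Build a response surface for the radial stretch
#'
#' Precomputes the radial stretch `lambda_r(c, k, p)` of the compression
#' model on a (non-uniform) grid of ground-matrix and fiber stiffnesses,
#' one layer per contact pressure, and wraps it in a smooth tensor-product
#' cubic-spline interpolant.  The emulator makes the stretch (and hence the
#' deformed-thickness likelihood) cheap and continuously differentiable in
#' `(c, k)` inside the Markov chain Monte Carlo loop.
#'
#' The grid is refined toward low stiffness where the stretch varies
#' fastest (spacing `~ u^grid_power`).  Node inversion uses exact nested
#' root-finding ([invert_pressure()]) down to an internal build range
#' wider than `lambda_range`, so the stored surface stays smooth near the
#' boundary of the reporting range; evaluations falling below
#' `lambda_range[1]` are flagged invalid by consumers.  Nodes whose
#' material cannot support the pressure at all (only possible on the
#' `k = 0` line) are stored as `NA` and excluded from the interpolant.
#'
#' After building, the emulator is checked against exact inversion at
#' `n_check` random off-grid feasible points; the achieved maximum
#' absolute stretch error is recorded in the result and the build fails
#' if it exceeds `tol_check`.
#'
#' @param c_range,k_range Stiffness intervals \[kPa\]; defaults
#'   `c(0, 10)` and `c(0, 40)`.
#' @param pressures Contact pressures \[kPa\] at which layers are built;
#'   must include every distinct pressure in the data to be fitted.
#'   A zero layer is implicit (`lambda_r = 1` exactly).
#' @param resolution Nodes per stiffness axis, `c(nc, nk)`.
#' @param k2,phi Fixed constitutive constants, see [hgo_params()].
#' @param lambda_range Reporting radial-stretch range, default
#'   `c(0.61, 1)`.
#' @param lambda_build_min Lower end of the internal build range.
#' @param grid_power Grid-refinement exponent (1 = uniform spacing).
#' @param n_check,tol_check Fidelity-check size and tolerance.
#' @param check_seed Seed for the (deterministic) fidelity check; the RNG
#'   state of the session is preserved.
#' @return An object of class `aawt_surface`.
#' @export
build_response_surface <- function(c_range = c(0, 10), k_range = c(0, 40),
                                   pressures = c(0, 1, 16, 25),
                                   resolution = c(41, 81),
                                   k2 = 15, phi = 0.546,
                                   lambda_range = c(0.61, 1),
                                   lambda_build_min = 0.35,
                                   grid_power = c(2.5, 3),
                                   n_check = 100, tol_check = 1e-3,
                                   check_seed = 1L) {
  stopifnot(length(c_range) == 2L, length(k_range) == 2L,
            c_range[1] >= 0, k_range[1] >= 0,
            diff(c_range) > 0, diff(k_range) > 0,
            length(resolution) == 2L, all(resolution >= 8),
            all(pressures >= 0), lambda_build_min < lambda_range[1])
  pressures <- sort(unique(pressures))
  pos_p <- pressures[pressures > 0]
  grid_power <- rep_len(grid_power, 2L)
  ngrid <- function(rng, n, pow) {
    rng[1] + diff(rng) * seq(0, 1, length.out = n)^pow
  }
  c_grid <- ngrid(c_range, resolution[1], grid_power[1])
  k_grid <- ngrid(k_range, resolution[2], grid_power[2])

  lam <- array(NA_real_,
               dim = c(length(c_grid), length(k_grid), length(pos_p)),
               dimnames = list(NULL, NULL, paste0("p", pos_p)))
  build_rng <- c(lambda_build_min, 1)
  for (i in seq_along(c_grid)) {
    for (j in seq_along(k_grid)) {
      par_ij <- hgo_params(c_grid[i], k_grid[j], k2 = k2, phi = phi)
      if (par_ij$c == 0 && par_ij$k == 0) next
      p_max <- radial_stress(par_ij, lambda_build_min)
      for (q in seq_along(pos_p)) {
        if (pos_p[q] <= p_max) {
          lam[i, j, q] <- invert_pressure(par_ij, pos_p[q],
                                          lambda_range = build_rng)
        }
      }
    }
  }

  surf <- structure(
    list(c_grid = c_grid, k_grid = k_grid, pressures = pressures,
         lambda = lam, k2 = k2, phi = phi,
         lambda_range = lambda_range,
         lambda_build_min = lambda_build_min,
         resolution = resolution, grid_power = grid_power,
         achieved_error = NA_real_, n_check = n_check),
    class = "aawt_surface")
  surf <- surface_attach_splines(surf)

  err <- surface_check_error(surf, n_check = n_check, seed = check_seed)
  surf$achieved_error <- err
  if (is.finite(err) && err > tol_check) {
    stop(sprintf(paste0(
      "response-surface build failed its fidelity contract: measured ",
      "max |delta lambda_r| = %.3g > %.3g; increase 'resolution'"),
      err, tol_check))
  }
  surf
}

# Precompute per-pressure, per-c-column cubic splines over k (valid nodes
# only).  Stored in an environment so the object remains serializable via
# its plain grids.
surface_attach_splines <- function(surf) {
  sp <- lapply(seq_len(dim(surf$lambda)[3]), function(q) {
    lapply(seq_along(surf$c_grid), function(i) {
      v <- surf$lambda[i, , q]
      ok <- !is.na(v)
      if (sum(ok) < 4) return(NULL)
      stats::splinefun(surf$k_grid[ok], v[ok], method = "natural")
    })
  })
  surf$splines <- sp
  surf
}

#' Evaluate a response surface
#'
#' Returns the emulated radial stretch at stiffness `(c, k)` for contact
#' pressure `p`.  `p = 0` returns exactly 1.  `p` must be one of the
#' pressures the surface was built for.  Queries in the infeasible corner
#' (material unable to support the pressure) return `NA`.
#'
#' @param surface An `aawt_surface` object.
#' @param c,k Stiffness values \[kPa\] inside the build ranges; `c`, `k`
#'   are recycled to a common length.
#' @param p A single contact pressure \[kPa\].
#' @return Radial stretch(es); `NA` where the query is infeasible.
#' @export
surface_lambda <- function(surface, c, k, p) {
  stopifnot(inherits(surface, "aawt_surface"), length(p) == 1L, p >= 0)
  n <- max(length(c), length(k))
  c <- rep_len(c, n); k <- rep_len(k, n)
  if (p == 0) return(rep(1, n))
  q <- which(abs(surface$pressures[surface$pressures > 0] - p) < 1e-9)
  if (length(q) != 1L) {
    stop(sprintf(
      "pressure %g kPa is not covered by this surface (built for: %s)",
      p, paste(surface$pressures, collapse = ", ")))
  }
  if (any(c < surface$c_grid[1] - 1e-12) ||
      any(c > surface$c_grid[length(surface$c_grid)] + 1e-12) ||
      any(k < surface$k_grid[1] - 1e-12) ||
      any(k > surface$k_grid[length(surface$k_grid)] + 1e-12)) {
    stop("(c, k) query outside the surface build range")
  }
  cols <- surface$splines[[q]]
  valid <- !vapply(cols, is.null, logical(1))
  cg <- surface$c_grid[valid]
  vapply(seq_len(n), function(m) {
    vals <- vapply(cols[valid], function(f) f(k[m]), numeric(1))
    stats::spline(cg, vals, xout = c[m], method = "fmm")$y
  }, numeric(1))
}

# Max |emulator - exact inversion| over n_check random off-grid feasible
# triples (c, k, p) with p drawn from the built positive pressures and the
# exact stretch inside the reporting range.  Deterministic; restores the
# session RNG state.
surface_check_error <- function(surf, n_check = 100, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  pos_p <- surf$pressures[surf$pressures > 0]
  if (length(pos_p) == 0L) return(0)
  cr <- range(surf$c_grid); kr <- range(surf$k_grid)
  err <- numeric(0); tries <- 0L
  while (length(err) < n_check && tries < 50L * n_check) {
    tries <- tries + 1L
    cc <- stats::runif(1, cr[1], cr[2])
    kk <- stats::runif(1, kr[1], kr[2])
    pp <- pos_p[sample.int(length(pos_p), 1L)]
    par <- hgo_params(cc, kk, k2 = surf$k2, phi = surf$phi)
    exact <- tryCatch(
      invert_pressure(par, pp, lambda_range = surf$lambda_range),
      error = function(e) NA_real_)
    if (is.na(exact)) next
    emu <- surface_lambda(surf, cc, kk, pp)
    if (is.na(emu)) next
    err <- c(err, abs(emu - exact))
  }
  if (length(err) == 0L) return(NA_real_)
  max(err)
}

#' @export
print.aawt_surface <- function(x, ...) {
  cat(sprintf(paste0(
    "Radial-stretch response surface: %d x %d stiffness nodes, ",
    "pressures {%s} kPa\n  c in [%g, %g] kPa, k in [%g, %g] kPa, ",
    "k2 = %g, phi = %g\n  achieved emulator error: %.2e (n = %d checks)\n"),
    length(x$c_grid), length(x$k_grid),
    paste(x$pressures, collapse = ", "),
    min(x$c_grid), max(x$c_grid), min(x$k_grid), max(x$k_grid),
    x$k2, x$phi, x$achieved_error, x$n_check))
  invisible(x)
}

#' Serialize a response surface to a portable JSON file
#'
#' Stores grids, stretch values and build metadata (including the achieved
#' emulator error) so inference runs can reuse a surface without
#' rebuilding it.
#'
#' @param surface An `aawt_surface` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "aawt_surface"))
  obj <- surface[c("c_grid", "k_grid", "pressures", "k2", "phi",
                   "lambda_range", "lambda_build_min", "resolution",
                   "grid_power", "achieved_error", "n_check")]
  obj$lambda <- as.vector(surface$lambda)
  obj$lambda_dim <- dim(surface$lambda)
  obj$format <- "aawt_surface"
  obj$package_version <- as.character(utils::packageVersion("aawt"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a response surface written by [write_surface()]
#'
#' @param path File path.
#' @return An `aawt_surface` object with interpolants rebuilt.
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "aawt_surface") {
    stop("'", path, "' is not a serialized aawt response surface")
  }
  lam <- array(obj$lambda, dim = obj$lambda_dim)
  surf <- structure(
    list(c_grid = obj$c_grid, k_grid = obj$k_grid,
         pressures = obj$pressures, lambda = lam, k2 = obj$k2,
         phi = obj$phi, lambda_range = obj$lambda_range,
         lambda_build_min = obj$lambda_build_min,
         resolution = obj$resolution, grid_power = obj$grid_power,
         achieved_error = obj$achieved_error, n_check = obj$n_check),
    class = "aawt_surface")
  surface_attach_splines(surf)
}
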