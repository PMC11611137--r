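# Tensor-product cubic-spline interpolation on a rectangular grid.
# Built as a spline-of-splines: one cubic spline over y per grid row,
# then a cubic spline across x of the row values.  C2 in each variable,
# reproduces the grid nodes exactly.

make_tensor_spline <- function(x_grid, y_grid, z) {
  stopifnot(is.matrix(z), length(x_grid) == nrow(z),
            length(y_grid) == ncol(z),
            all(diff(x_grid) > 0), all(diff(y_grid) > 0))
  row_funs <- lapply(seq_along(x_grid), function(i) {
    stats::splinefun(y_grid, z[i, ], method = "natural")
  })
  xr <- range(x_grid); yr <- range(y_grid)
  function(x, y) {
    n <- max(length(x), length(y))
    x <- rep_len(x, n); y <- rep_len(y, n)
    vapply(seq_len(n), function(m) {
      if (x[m] < xr[1] || x[m] > xr[2] || y[m] < yr[1] || y[m] > yr[2]) {
        return(NA_real_)
      }
      v <- vapply(row_funs, function(f) f(y[m]), numeric(1))
      stats::spline(x_grid, v, xout = x[m], method = "fmm")$y
    }, numeric(1))
  }
}
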