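# Separable 2-D decimated discrete wavelet transform with periodized
# boundaries and an orthogonal near-symmetric 8-tap filter (sym4, the
# least-asymmetric Daubechies family). Periodization with orthonormal
# filters makes the transform exactly orthogonal, so inverse(forward(x))
# reconstructs x to machine precision for even-length sides.

SYM4_LO <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427)

wavelet_filters <- function(wavelet = "sym4") {
  if (!identical(wavelet, "sym4")) {
    abort("only the 'sym4' wavelet is packaged")
  }
  lo <- SYM4_LO
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  list(lo = lo, hi = hi)
}

# one analysis step along columns of x (periodized): returns list(a, d)
# with n/2 rows each. a[k, ] = sum_i lo[i] * x[(2k - 2 + i - 1) mod n + 1, ]
dwt_step_cols <- function(x, lo, hi) {
  n <- nrow(x)
  half <- n %/% 2
  L <- length(lo)
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- 2 * (seq_len(half) - 1)  # 0-based start of each window
  for (i in seq_len(L)) {
    rows <- (base + i - 1) %% n + 1
    a <- a + lo[i] * x[rows, , drop = FALSE]
    d <- d + hi[i] * x[rows, , drop = FALSE]
  }
  list(a = a, d = d)
}

# inverse of dwt_step_cols (transpose of the orthogonal analysis operator)
idwt_step_cols <- function(a, d, lo, hi) {
  half <- nrow(a)
  n <- 2 * half
  L <- length(lo)
  x <- matrix(0, n, ncol(a))
  base <- 2 * (seq_len(half) - 1)
  for (i in seq_len(L)) {
    rows <- (base + i - 1) %% n + 1
    # scatter-add; rows repeat across k when L > 2, accumulate per target row
    contrib <- lo[i] * a + hi[i] * d
    x <- x + rowsum_scatter(contrib, rows, n)
  }
  x
}

# add each row of `contrib` (half x m) into row `rows[k]` of an n x m zero
# matrix; rows may repeat across different k.
rowsum_scatter <- function(contrib, rows, n) {
  out <- matrix(0, n, ncol(contrib))
  agg <- rowsum(contrib, group = rows)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# single-level 2-D analysis: returns list(LL, LH, HL, HH).
# Naming: first letter = row (vertical) filtering, second = column.
dwt2_level <- function(x, f) {
  cstep <- dwt_step_cols(x, f$lo, f$hi)          # along rows (dim 1)
  a_r <- t(cstep$a); d_r <- t(cstep$d)
  aa <- dwt_step_cols(a_r, f$lo, f$hi)           # along original dim 2
  dd <- dwt_step_cols(d_r, f$lo, f$hi)
  list(LL = t(aa$a), LH = t(aa$d), HL = t(dd$a), HH = t(dd$d))
}

idwt2_level <- function(bands, f) {
  a_r <- t(idwt_step_cols(t(bands$LL), t(bands$LH), f$lo, f$hi))
  d_r <- t(idwt_step_cols(t(bands$HL), t(bands$HH), f$lo, f$hi))
  idwt_step_cols(a_r, d_r, f$lo, f$hi)
}

#' Multi-level 2-D wavelet decomposition
#'
#' Periodized orthogonal transform (sym4). The pyramid holds the coarsest
#' approximation plus, per level, three oriented detail bands: `LH`
#' (horizontal structure), `HL` (vertical structure), `HH` (diagonal).
#' Because the filters are orthonormal, [idwt2()] reconstructs the input to
#' machine precision and white noise keeps its variance in every band.
#'
#' @param x numeric matrix; both sides must be divisible by `2^levels` and
#'   at least the filter length at the coarsest level.
#' @param levels decomposition depth.
#' @param wavelet wavelet name (packaged: `"sym4"`).
#' @return A list of class `wavelet_pyramid`: `approx`, `detail` (list per
#'   level of `LH`, `HL`, `HH`, finest first), `levels`, `wavelet`.
#' @export
dwt2 <- function(x, levels = 3, wavelet = "sym4") {
  f <- wavelet_filters(wavelet)
  if (any(dim(x) %% 2^levels != 0)) {
    abort("image sides must be divisible by 2^levels for the periodized transform")
  }
  if (min(dim(x)) / 2^(levels - 1) < length(f$lo)) {
    abort("image too small for the requested number of levels")
  }
  detail <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    b <- dwt2_level(cur, f)
    detail[[l]] <- b[c("LH", "HL", "HH")]
    cur <- b$LL
  }
  structure(list(approx = cur, detail = detail, levels = levels, wavelet = wavelet),
            class = "wavelet_pyramid")
}

#' @rdname dwt2
#' @param pyramid a `wavelet_pyramid`.
#' @export
idwt2 <- function(pyramid) {
  f <- wavelet_filters(pyramid$wavelet)
  cur <- pyramid$approx
  for (l in rev(seq_len(pyramid$levels))) {
    b <- pyramid$detail[[l]]
    cur <- idwt2_level(list(LL = cur, LH = b$LH, HL = b$HL, HH = b$HH), f)
  }
  cur
}
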