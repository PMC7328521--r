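#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Stop with a classed condition so callers/tests can be specific.
pcg_abort <- function(msg, class = "pcgloop_error") {
  rlang::abort(msg, class = class)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pcg_abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) pcg_abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed (< 2^31) from a parent seed and a tag.
child_seed <- function(seed, tag) {
  stopifnot_scalar_number(seed, "seed")
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

#' Bilinear resize of a numeric matrix
#'
#' Deterministic bilinear interpolation of a matrix onto a `nr x nc` grid,
#' used to rescale variable-length region windows to a common pileup size.
#' `NA` cells are handled by renormalising against an interpolated validity
#' mask, so missing pixels dilute rather than poison their neighbourhood.
#'
#' @param m numeric matrix.
#' @param nr,nc target dimensions.
#' @return numeric `nr x nc` matrix; cells with no valid support are `NA`.
#' @keywords internal
bilinear_resize <- function(m, nr, nc = nr) {
  sr <- nrow(m); sc <- ncol(m)
  if (sr == 0L || sc == 0L) pcg_abort("cannot resize an empty matrix")
  valid <- !is.na(m)
  m0 <- ifelse(valid, m, 0)
  # map target pixel centres onto source pixel-centre coordinates
  coord <- function(n_to, n_from) {
    if (n_from == 1L) rep(1, n_to) else (seq_len(n_to) - 0.5) / n_to * n_from + 0.5
  }
  ri <- pmin(pmax(coord(nr, sr), 1), sr)
  ci <- pmin(pmax(coord(nc, sc), 1), sc)
  r0 <- pmin(floor(ri), sr - ifelse(sr > 1, 1, 0)); r1 <- pmin(r0 + 1, sr)
  c0 <- pmin(floor(ci), sc - ifelse(sc > 1, 1, 0)); c1 <- pmin(c0 + 1, sc)
  wr <- ri - r0; wc <- ci - c0
  interp <- function(x) {
    a <- x[r0, c0, drop = FALSE] * outer(1 - wr, 1 - wc) +
      x[r1, c0, drop = FALSE] * outer(wr, 1 - wc) +
      x[r0, c1, drop = FALSE] * outer(1 - wr, wc) +
      x[r1, c1, drop = FALSE] * outer(wr, wc)
    a
  }
  num <- interp(m0)
  den <- interp(valid * 1)
  out <- num / den
  out[den < 1e-12] <- NA_real_
  out
}

fmt_bp <- function(x) {
  ifelse(x >= 1e6, sprintf("%.4g Mb", x / 1e6),
         ifelse(x >= 1e3, sprintf("%.4g kb", x / 1e3), sprintf("%g bp", x)))
}
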