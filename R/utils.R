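# small shared helpers

#' Round half away from zero
#'
#' Printed-style percentage rounding: 0.5 always rounds away from zero,
#' unlike base [round()] which rounds half to even.
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# union-find over 1..n, used for single-linkage components
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

# stop() with call.=FALSE everywhere
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
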