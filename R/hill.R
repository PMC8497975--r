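#' Hill-number diversity of a community
#'
#' The Hill number of order `q` is the effective number of equally abundant
#' species: `^qD = (sum_i p_i^q)^(1/(1-q))` over the relative abundances
#' `p_i > 0`, with the `q -> 1` limit `^1D = exp(-sum_i p_i ln p_i)` (the
#' exponential of Shannon entropy) evaluated in closed form. `q = 0` gives the
#' richness, `q = 2` the reciprocal of the Simpson concentration. Abundances
#' are normalized internally, so any positive rescaling of the input leaves
#' the result unchanged; zeros are excluded from the sum.
#'
#' @param abundances numeric vector of non-negative abundances (counts or
#'   relative abundances) with at least one positive entry.
#' @param q non-negative diversity order.
#' @return the diversity `^qD`, a number in `[1, S]` where `S` is the number
#'   of positive entries.
#' @examples
#' hillNumber(c(0.25, 0.25, 0.25, 0.25), 0)   # richness: 4
#' hillNumber(c(0.5, 0.3, 0.2), 1)            # exp(Shannon)
#' hillNumber(c(0.5, 0.3, 0.2), 2)            # 1 / sum(p^2)
#' @export
hillNumber <- function(abundances, q) {
  stopifnot(is.numeric(abundances), length(q) == 1L, is.finite(q), q >= 0)
  if (any(abundances < 0)) stop("negative abundances are not allowed")
  p <- abundances[abundances > 0]
  if (!length(p)) stop("empty community: all abundances are zero")
  p <- p / sum(p)
  if (q == 0) return(as.numeric(length(p)))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Diversity profile across orders q
#'
#' Evaluates [hillNumber()] on a grid of diversity orders. The profile is
#' non-increasing in `q` for any fixed community.
#'
#' @inheritParams hillNumber
#' @param qGrid numeric vector of non-negative diversity orders
#'   (default `c(0, 1, 2, 3)`).
#' @return named numeric vector of `^qD` values, one per order.
#' @examples
#' diversityProfile(c(5, 5, 5, 5, 5))     # uniform: all equal to 5
#' diversityProfile(c(0.9, 0.1), c(0, 2))
#' @export
diversityProfile <- function(abundances, qGrid = c(0, 1, 2, 3)) {
  vapply(qGrid, function(q) hillNumber(abundances, q), numeric(1)) |>
    setNames(paste0("q", qGrid))
}

## Vectorized Hill numbers over the rows of a non-negative matrix
## (rows = pooled communities). Hot path for accrual curves.
.hillRows <- function(m, q) {
  rs <- rowSums(m)
  if (q == 0) return(rowSums(m > 0))
  p <- m / rs
  if (q == 1) {
    lp <- p * log(p)
    lp[!is.finite(lp)] <- 0          # 0 * log(0) := 0
    return(exp(-rowSums(lp)))
  }
  rowSums(p^q)^(1 / (1 - q))
}
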