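#' Bar panels of the DAR parameter profiles
#'
#' Plots the three headline profiles of one or more
#' [DARProfileSet][DARProfileSet-class]s as grouped bars against the
#' diversity order `q`: the scaling parameter `z` (DAR profile), the maximal
#' accrual diversity `Dmax` (MAD profile) and the individual-to-population
#' ratio `RIP` (RIP profile), faceted by panel with groups side by side.
#'
#' @param profiles a `DARProfileSet` or list of them.
#' @param which subset of `c("z", "Dmax", "RIP")`.
#' @return a `ggplot` object (headless-safe; nothing is drawn until printed).
#' @export
plotProfiles <- function(profiles, which = c("z", "Dmax", "RIP")) {
  which <- match.arg(which, several.ok = TRUE)
  tab <- profileTable(profiles)
  long <- do.call(rbind, lapply(which, function(w) {
    col <- switch(w, z = "mean_z", Dmax = "mean_Dmax", RIP = "mean_RIP")
    data.frame(grouping = tab$grouping, q = factor(tab$q),
               panel = factor(w, levels = which), value = tab[[col]])
  }))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$grouping, y = .data$value,
                               fill = .data$q)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "q") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Log-log accrual curve with its fitted model
#'
#' Scatter of `ln D` against `ln A` with the fitted PL line (or PLEC curve)
#' overlaid — the standard visual check of a diversity-area fit.
#'
#' @param curve an [AccrualCurve-class].
#' @param fit a [PLFit][PLFit-class] or [PLECFit][PLFit-class] of that curve.
#' @return a `ggplot` object.
#' @export
plotAccrualFit <- function(curve, fit) {
  stopifnot(is(curve, "AccrualCurve"), is(fit, "PLFit"))
  a <- as.numeric(curve@areas)
  df <- data.frame(lnA = log(a), lnD = log(curve@diversities))
  grid <- seq(min(a), max(a), length.out = 200)
  pred <- fit@lnC + fit@z * log(grid) +
    if (is(fit, "PLECFit")) fit@d * grid else 0
  line <- data.frame(lnA = log(grid), lnD = pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lnA, y = .data$lnD)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::labs(x = "ln A", y = "ln D",
                  title = sprintf("%s fit, q = %g: z = %.3f, R = %.3f",
                                  if (is(fit, "PLECFit")) "PLEC" else "PL",
                                  fit@q, fit@z, fit@R)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 .data
NULL
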