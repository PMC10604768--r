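# diverging blue <-> yellow map over a symmetric t range: u = 0 deep blue
# (strong under-connectivity), u = 0.5 neutral grey, u = 1 yellow (over-)
divergence_color <- function(t, t_max) {
  u <- (pmin(pmax(t / t_max, -1), 1) + 1) / 2
  ramp <- grDevices::colorRamp(c("#08306B", "#6BAED6", "#BFBFBF",
                                 "#FEC44F", "#F0A500"))
  cols <- ramp(u)
  grDevices::rgb(cols[, 1], cols[, 2], cols[, 3], maxColorValue = 255)
}

#' Chord diagram of significant network-pair divergences
#'
#' Places the networks on a circle and draws one chord (a Bezier curve bent
#' toward the center) per significant between-network pair.  Chord color
#' encodes the Welch t value on a diverging blue-to-yellow map over a
#' symmetric range: blue shades mark negative t (under-connectivity of the
#' input group relative to the neurotypical-like reference), yellow hues
#' positive t (over-connectivity).  Within-network (diagonal) results are
#' computed upstream but not drawn.  The output format follows the file
#' extension (`.svg`, `.png` or `.pdf`).
#'
#' @param result An `fc_divergence` data frame.
#' @param path Output file path.
#' @param title Optional plot title.
#' @param t_range Symmetric color range; defaults to the largest significant
#'   absolute t (minimum 1).
#' @return `path`, invisibly.
#' @export
chord_diagram <- function(result, path, title = NULL, t_range = NULL) {
  nets <- unique(c(result$network_a, result$network_b))
  sig <- result[result$significant & result$network_a != result$network_b, ,
                drop = FALSE]
  t_max <- t_range %||% max(1, if (nrow(sig)) max(abs(sig$welch_t)))
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  switch(ext,
         svg = grDevices::svg(path, width = 6, height = 6),
         png = grDevices::png(path, width = 900, height = 900, res = 150),
         pdf = grDevices::pdf(path, width = 6, height = 6),
         stop_fc("unsupported figure extension: .", ext))
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(c(-1.45, 1.45), c(-1.45, 1.45), asp = 1)
  K <- length(nets)
  ang <- pi / 2 - (seq_len(K) - 1) * 2 * pi / K
  px <- cos(ang); py <- sin(ang)
  theta <- seq(0, 2 * pi, length.out = 241)
  graphics::lines(1.12 * cos(theta), 1.12 * sin(theta), col = "grey80")
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      i <- match(sig$network_a[r], nets); j <- match(sig$network_b[r], nets)
      tt <- seq(0, 1, length.out = 60)
      # quadratic Bezier with the control point pulled toward the center
      bx <- (1 - tt)^2 * px[i] + tt^2 * px[j]
      by <- (1 - tt)^2 * py[i] + tt^2 * py[j]
      graphics::lines(bx, by, lwd = 1.5 + 2.5 * min(1, abs(sig$welch_t[r]) / t_max),
                      col = divergence_color(sig$welch_t[r], t_max))
    }
  } else {
    graphics::text(0, 0, "no significant pairs", col = "grey40", cex = 0.9)
  }
  graphics::symbols(px, py, circles = rep(0.09, K), inches = FALSE,
                    add = TRUE, bg = "grey25", fg = NA)
  graphics::text(1.3 * px, 1.3 * py, nets, cex = 0.85)
  graphics::title(main = title %||% "Network divergence (Welch t, p < 0.05)")
  invisible(path)
}
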