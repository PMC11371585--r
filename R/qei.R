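#' Quality evaluation index (QEI) for a CBF map
#'
#' Scores the physiological plausibility of a CBF map on `[0, 1]` from three
#' components: (1) `structural_correlation`, the Pearson correlation between
#' the CBF map and a segmentation-derived pseudo-CBF template (GM:WM contrast
#' 2.5:1, zero outside tissue) over the head mask; (2) `spatial_cv`, the
#' coefficient of variation of GM CBF; (3) `negative_gm_fraction`, the
#' fraction of GM voxels with negative CBF. The index is
#'
#' `QEI = max(0, r)^w1 * (1 / (1 + CV))^w2 * (1 - negfrac)^w3`
#'
#' (default weights 1), which is increasing in the structural correlation and
#' decreasing in both the spatial CV and the negative fraction, and is
#' invariant to global positive rescaling of the map.
#'
#' @param cbf a `cbf_map` or `vol3d` of CBF values.
#' @param tissue_labels tissue label volume on the same grid (0 background,
#'   1 CSF, 2 GM, 3 WM).
#' @param weights length-3 positive exponents for the three components.
#' @param threshold pass threshold; maps pass only with QEI strictly above
#'   it.
#' @return list of class `quality_report`: `qei`, `structural_correlation`,
#'   `spatial_cv`, `negative_gm_fraction`, `passed`, `threshold`.
#' @export
compute_qei <- function(cbf, tissue_labels, weights = c(1, 1, 1),
                        threshold = 0.4) {
  vol <- if (inherits(cbf, "cbf_map")) cbf$volume else cbf
  if (!vol_same_grid(vol, tissue_labels))
    stop("CBF map and tissue labels are on different grids")
  lab <- tissue_labels$data
  gm <- lab == 2L
  if (!any(gm)) stop("empty GM mask")
  head <- lab > 0L
  pseudo <- array(0, dim = dim(lab))
  pseudo[lab == 2L] <- 2.5
  pseudo[lab == 3L] <- 1
  x <- vol$data[head]
  ok <- is.finite(x)
  r <- suppressWarnings(stats::cor(x[ok], pseudo[head][ok]))
  if (!is.finite(r)) r <- 0
  g <- vol$data[gm]
  g <- g[is.finite(g)]
  mu <- mean(g)
  cv <- if (mu > 1e-9) stats::sd(g) / mu else Inf
  neg <- mean(g < 0)
  s_r <- max(0, r)
  s_cv <- if (is.finite(cv)) 1 / (1 + cv) else 0
  s_neg <- 1 - neg
  qei <- s_r^weights[1] * s_cv^weights[2] * s_neg^weights[3]
  structure(list(qei = qei, structural_correlation = r, spatial_cv = cv,
                 negative_gm_fraction = neg, passed = qei > threshold,
                 threshold = threshold),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("QEI %.3f (r = %.3f, CV = %.3f, neg GM = %.1f%%): %s (threshold %.2f)\n",
              x$qei, x$structural_correlation, x$spatial_cv,
              100 * x$negative_gm_fraction,
              if (x$passed) "PASS" else "FAIL", x$threshold))
  invisible(x)
}

#' Apply the QEI exclusion rule to a scored cohort
#'
#' Participants are kept only when QEI is strictly above the threshold
#' (`qei > threshold`); exclusions are logged with id and score.
#'
#' @param records list of participant records, each carrying a `qei` field
#'   (or a `quality` list with a `qei` field).
#' @param threshold exclusion threshold (default 0.4).
#' @return list: `kept`, `excluded` (record lists), `log` (character).
#' @export
filter_by_qei <- function(records, threshold = 0.4) {
  qei <- vapply(records, function(r) {
    if (!is.null(r$qei)) r$qei else r$quality$qei
  }, numeric(1))
  keep <- qei > threshold
  log <- character(0)
  for (i in which(!keep)) {
    id <- if (!is.null(records[[i]]$id)) records[[i]]$id else as.character(i)
    log <- c(log, sprintf("excluded %s: QEI %.3f <= %.2f", id, qei[i], threshold))
  }
  list(kept = records[keep], excluded = records[!keep], log = log)
}
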