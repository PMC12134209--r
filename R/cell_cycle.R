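# Cell-cycle staging.
#
# Marker scheme (EdU / Aurora-B): G1 = both negative, S = EdU positive
# (refined to Early/Mid/Late S from the spatial EdU pattern), G2 = EdU
# negative / Aurora-B positive.
#
# FUCCI scheme (hCdt1 / Geminin): EarlyG1 = hCdt1-high & Geminin-negative,
# LateG1_EarlyS = both positive, MidLateS = Geminin-positive only,
# G2 = Geminin-high & hCdt1-negative.

MARKER_STAGES <- c("G1", "EarlyS", "MidS", "LateS", "G2")
FUCCI_STAGES <- c("EarlyG1", "LateG1_EarlyS", "MidLateS", "G2")

#' Per-nucleus marker positivity
#'
#' A nucleus is positive for a marker channel when its mean in-nucleus
#' intensity exceeds the modal background outside all nuclei plus
#' `k_sd` background standard deviations. The spread is estimated robustly
#' (MAD scaled to the normal sd) so that signal blurred just outside the
#' nuclear border (e.g. peripheral late-S EdU foci) does not inflate the
#' threshold.
#'
#' @param stack an [image_stack()].
#' @param channel_role marker channel (e.g. "EDU", "AURORAB").
#' @param nucleus a [nucleus_mask()].
#' @param nuclei all nuclei in the stack (for the background region);
#'   defaults to just `nucleus`.
#' @param k_sd stringency (default 3).
#' @return logical scalar.
#' @export
marker_positive <- function(stack, channel_role, nucleus,
                            nuclei = list(nucleus), k_sd = 3) {
  x <- get_channel(stack, channel_role)
  out <- array(TRUE, dim(x))
  for (nm in nuclei) out <- out & !nm$mask
  bg <- x[out]
  bg_mode <- estimate_background(stack, channel_role, nuclei)
  # IQR-based spread: robust both to bright signal blurred past the nuclear
  # border and to the zero-clamped half of the read-noise distribution
  bg_sd <- if (length(bg) > 1L) {
    diff(quantile(bg, c(0.25, 0.75), names = FALSE)) / 1.349
  } else 0
  mean(x[nucleus$mask]) > bg_mode + k_sd * bg_sd
}

#' Stage a nucleus from EdU / Aurora-B marker logic
#'
#' Truth table: (EdU-, AurB-) is G1; (EdU+, anything) is S, refined by
#' `edu_pattern` when given; (EdU-, AurB+) is G2.
#'
#' @param edu_positive,aurorab_positive logical marker calls.
#' @param edu_pattern optional `edu_pattern` object from
#'   [classify_edu_pattern()]; refines S into EarlyS/MidS/LateS.
#' @param nucleus_id id carried into the call.
#' @return a `cell_cycle_call` (scheme "markers").
#' @export
stage_by_markers <- function(edu_positive, aurorab_positive,
                             edu_pattern = NULL, nucleus_id = 1L) {
  stopifnot(is.logical(edu_positive), is.logical(aurorab_positive))
  stage <- if (edu_positive) {
    if (!is.null(edu_pattern)) {
      switch(edu_pattern$pattern, Early = "EarlyS", Mid = "MidS",
             Late = "LateS")
    } else "MidS"  # unrefined S defaults to the modal sub-stage
  } else if (aurorab_positive) "G2" else "G1"
  structure(list(nucleus_id = as.integer(nucleus_id), scheme = "markers",
                 stage = stage, callable = TRUE,
                 evidence = list(edu_positive = edu_positive,
                                 aurorab_positive = aurorab_positive,
                                 edu_pattern = if (is.null(edu_pattern)) NA
                                               else edu_pattern$pattern)),
            class = "cell_cycle_call")
}

#' @export
print.cell_cycle_call <- function(x, ...) {
  cat(sprintf("<cell_cycle_call> nucleus %d (%s): %s\n", x$nucleus_id,
              x$scheme, if (isTRUE(x$callable)) x$stage else "uncallable"))
  invisible(x)
}

#' Classify the S-phase sub-stage from the spatial EdU pattern
#'
#' EdU-positive voxels are found by an Otsu threshold within the nucleus;
#' foci are their connected components. Rules: Mid S when more than
#' `theta_ring` of the EdU-positive voxels fall in a dilation ring around
#' the chromocenters (the ring-shaped staining of replicating
#' heterochromatin); else Late S when there are at most `theta_n` foci and
#' more than `theta_per` of the EdU-positive voxels lie in the peripheral
#' shell of the nucleus; else Early S (many small foci throughout the
#' nucleoplasm).
#'
#' @param stack an [image_stack()] with an EDU channel.
#' @param nucleus a [nucleus_mask()].
#' @param domains a [chromocenter_set()].
#' @param theta_ring,theta_n,theta_per rule thresholds (defaults 0.5, 10,
#'   0.5).
#' @param ring_um ring width around chromocenters in micrometres
#'   (default 0.5).
#' @param rim_um peripheral shell depth from the nuclear border in
#'   micrometres (default 1).
#' @return an `edu_pattern` object with `pattern` in Early/Mid/Late plus the
#'   measured evidence (`n_foci`, `median_focus_volume`,
#'   `frac_chromocenter_ring`, `frac_periphery`). A nucleus without
#'   EdU-positive voxels raises an error (it should not have been called
#'   EdU-positive).
#' @export
classify_edu_pattern <- function(stack, nucleus, domains,
                                 theta_ring = 0.5, theta_n = 10L,
                                 theta_per = 0.5, ring_um = 0.5, rim_um = 1) {
  stopifnot(inherits(nucleus, "nucleus_mask"),
            inherits(domains, "chromocenter_set"))
  x <- get_channel(stack, "EDU")
  vs <- stack$voxel_size
  vals <- x[nucleus$mask]
  thr <- otsu_threshold(vals)
  pos <- !is.na(thr) & x > thr & nucleus$mask
  n_pos <- sum(pos)
  if (n_pos == 0L) {
    chr_stop("chromofied_data_error",
             "no EdU-positive voxels in an EdU-positive nucleus")
  }
  ring_vox <- pmax(1L, round(ring_um / vs))
  ring <- dilate_mask(domains$labels > 0L, ring_vox) & nucleus$mask
  frac_ring <- sum(pos & ring) / n_pos
  rim_vox <- pmax(1L, round(rim_um / vs))
  rim <- nucleus$mask & !erode_mask(nucleus$mask, rim_vox, shape = "box")
  frac_per <- sum(pos & rim) / n_pos
  labs <- label_components(pos)
  st <- component_stats(labs, vs)
  n_foci <- nrow(st)
  pattern <- if (frac_ring > theta_ring) "Mid"
             else if (n_foci <= theta_n && frac_per > theta_per) "Late"
             else "Early"
  structure(list(nucleus_id = nucleus$nucleus_id, n_foci = n_foci,
                 median_focus_volume = if (n_foci > 0) median(st$volume)
                                       else NA_real_,
                 frac_chromocenter_ring = frac_ring,
                 frac_periphery = frac_per, pattern = pattern),
            class = "edu_pattern")
}

#' @export
print.edu_pattern <- function(x, ...) {
  cat(sprintf(
    "<edu_pattern> nucleus %d: %s S (%d foci, ring %.2f, periphery %.2f)\n",
    x$nucleus_id, x$pattern, x$n_foci, x$frac_chromocenter_ring,
    x$frac_periphery))
  invisible(x)
}

#' Stage a FUCCI nucleus from hCdt1 / Geminin intensities
#'
#' @param hcdt1,geminin non-negative normalized reporter intensities (e.g.
#'   mean in-nucleus intensity).
#' @param thresholds list with per-channel `(t_pos, t_high)`:
#'   `list(hcdt1 = c(t_pos, t_high), geminin = c(t_pos, t_high))`. See
#'   [derive_fucci_thresholds()] for data-driven thresholds.
#' @param nucleus_id id carried into the call.
#' @return a `cell_cycle_call` (scheme "fucci"). Both reporters below their
#'   positivity thresholds give an uncallable status.
#' @export
stage_fucci <- function(hcdt1, geminin,
                        thresholds = list(hcdt1 = c(60, 200),
                                          geminin = c(60, 200)),
                        nucleus_id = 1L) {
  stopifnot(hcdt1 >= 0, geminin >= 0)
  hp <- thresholds$hcdt1[1L]; hh <- thresholds$hcdt1[2L]
  gp <- thresholds$geminin[1L]; gh <- thresholds$geminin[2L]
  stage <- if (hcdt1 >= hh && geminin < gp) "EarlyG1"
           else if (hcdt1 >= hp && geminin >= gp) "LateG1_EarlyS"
           else if (hcdt1 < hp && geminin >= gp && geminin < gh) "MidLateS"
           else if (hcdt1 < hp && geminin >= gh) "G2"
           else NA_character_
  structure(list(nucleus_id = as.integer(nucleus_id), scheme = "fucci",
                 stage = stage, callable = !is.na(stage),
                 evidence = list(hcdt1 = hcdt1, geminin = geminin,
                                 thresholds = thresholds)),
            class = "cell_cycle_call")
}

#' Derive FUCCI thresholds from a population of reporter intensities
#'
#' For each reporter, the positivity threshold `t_pos` is the Otsu split of
#' the log intensities over the population and `t_high` the 75th percentile
#' of the positive cells. Both are quantile/histogram-derived, so staging is
#' invariant to a common rescaling of the channel.
#'
#' @param hcdt1,geminin numeric vectors of per-nucleus intensities.
#' @return thresholds list as accepted by [stage_fucci()].
#' @export
derive_fucci_thresholds <- function(hcdt1, geminin) {
  one <- function(v) {
    lv <- log1p(v)
    t_pos <- expm1(otsu_threshold(lv))
    pos <- v[v >= t_pos]
    t_high <- if (length(pos) > 0L) as.numeric(quantile(pos, 0.75)) else Inf
    c(t_pos, t_high)
  }
  list(hcdt1 = one(hcdt1), geminin = one(geminin))
}

#' Mean in-nucleus intensity of a channel
#'
#' Convenience measurement used as the normalized FUCCI reporter intensity.
#'
#' @param stack an [image_stack()].
#' @param channel_role channel to measure.
#' @param nucleus a [nucleus_mask()].
#' @return numeric scalar.
#' @export
nuclear_mean_intensity <- function(stack, channel_role, nucleus) {
  mean(get_channel(stack, channel_role)[nucleus$mask])
}
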