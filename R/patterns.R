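# Rule-based classification of nuclear patterns from per-domain enrichment
# ratios, Clover gating of TALE-expressing cells, and aggregation of
# condition-level proportions.
#
# A nucleus is "Enriched" when at least k_min chromocenters have signal
# above the nucleus level (per-domain ratio > 1 + delta), "Excluded" when at
# least k_min lie below (ratio < 1 - delta; the symmetric counterpart of the
# published Enriched rule), and "Even" otherwise. Enriched takes precedence.

#' Classify the nuclear pattern of one nucleus
#'
#' @param enrichment a `domain_enrichment` from [compute_enrichment()].
#' @param delta half-width of the "same as the nucleus" tolerance band
#'   around ratio 1 (default 0.2).
#' @param k_min number of chromocenters above (below) the band required to
#'   call Enriched (Excluded); default 3.
#' @return a `pattern_call` with `label`, counts `n_above` / `n_below`, and
#'   the parameters used. A nucleus with zero domains is uncallable:
#'   `label = NA` and `callable = FALSE`.
#' @export
classify_pattern <- function(enrichment, delta = 0.2, k_min = 3L) {
  stopifnot(inherits(enrichment, "domain_enrichment"), delta >= 0, k_min >= 1)
  r <- enrichment$per_domain_ratios$ratio
  if (enrichment$n_domains == 0L) {
    return(structure(list(nucleus_id = enrichment$nucleus_id,
                          label = NA_character_, callable = FALSE,
                          n_above = 0L, n_below = 0L, n_domains = 0L,
                          delta = delta, k_min = as.integer(k_min)),
                     class = "pattern_call"))
  }
  n_above <- sum(r > 1 + delta)
  n_below <- sum(r < 1 - delta)
  label <- if (n_above >= k_min) "Enriched"
           else if (n_below >= k_min) "Excluded"
           else "Even"
  structure(list(nucleus_id = enrichment$nucleus_id, label = label,
                 callable = TRUE, n_above = as.integer(n_above),
                 n_below = as.integer(n_below),
                 n_domains = enrichment$n_domains,
                 delta = delta, k_min = as.integer(k_min)),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> nucleus %d: %s (%d above / %d below of %d domains)\n",
              x$nucleus_id, if (x$callable) x$label else "uncallable",
              x$n_above, x$n_below, x$n_domains))
  invisible(x)
}

#' Gate TALE-expressing cells by Clover enrichment
#'
#' A cell expresses the TALE fusion when its whole-nucleus Clover enrichment
#' ratio is strictly above the threshold (published cut-off 1.2; a ratio of
#' exactly 1.2 is negative).
#'
#' @param clover_enrichment a `domain_enrichment` computed on the CLOVER
#'   channel.
#' @param threshold positivity cut-off (default 1.2).
#' @return a `gate_call` with `clover_ratio`, `positive` and `callable`
#'   (FALSE when the ratio is undefined).
#' @export
gate_tale <- function(clover_enrichment, threshold = 1.2) {
  stopifnot(inherits(clover_enrichment, "domain_enrichment"))
  ratio <- clover_enrichment$ratio_global
  callable <- !is.na(ratio)
  structure(list(nucleus_id = clover_enrichment$nucleus_id,
                 clover_ratio = ratio,
                 positive = if (callable) ratio > threshold else NA,
                 callable = callable, threshold = threshold),
            class = "gate_call")
}

#' Aggregate pattern calls into condition-level proportions
#'
#' Per replicate, the percentage of callable nuclei with each label; per
#' condition, mean and sample standard deviation of those percentages across
#' replicates. Replicates with zero callable nuclei are dropped with a
#' warning.
#'
#' @param calls list of `pattern_call` objects.
#' @param condition,replicate character/factor vectors, one entry per call.
#' @return list with `replicates` (condition, replicate, label, n, percent)
#'   and `conditions` (condition, label, mean_percent, sd_percent,
#'   n_replicates) data.frames. Empty input yields empty tables.
#' @export
aggregate_proportions <- function(calls,
                                  condition = rep("all", length(calls)),
                                  replicate = rep("r1", length(calls))) {
  stopifnot(length(condition) == length(calls),
            length(replicate) == length(calls))
  empty <- list(
    replicates = data.frame(condition = character(), replicate = character(),
                            label = character(), n = integer(),
                            percent = numeric()),
    conditions = data.frame(condition = character(), label = character(),
                            mean_percent = numeric(), sd_percent = numeric(),
                            n_replicates = integer()))
  if (length(calls) == 0L) return(empty)
  df <- data.frame(condition = as.character(condition),
                   replicate = as.character(replicate),
                   label = vapply(calls, function(x) {
                     if (isTRUE(x$callable)) x$label else NA_character_
                   }, character(1L)))
  rep_rows <- list()
  for (cond in unique(df$condition)) {
    for (rep_id in unique(df$replicate[df$condition == cond])) {
      sub <- df[df$condition == cond & df$replicate == rep_id, ]
      callable <- sub$label[!is.na(sub$label)]
      if (length(callable) == 0L) {
        warning(sprintf("replicate %s/%s has no callable nuclei; dropped",
                        cond, rep_id))
        next
      }
      for (lab in PATTERN_LABELS) {
        n_lab <- sum(callable == lab)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          condition = cond, replicate = rep_id, label = lab,
          n = n_lab, percent = 100 * n_lab / length(callable))
      }
    }
  }
  if (length(rep_rows) == 0L) return(empty)
  replicates <- do.call(rbind, rep_rows)
  cond_rows <- list()
  for (cond in unique(replicates$condition)) {
    for (lab in PATTERN_LABELS) {
      p <- replicates$percent[replicates$condition == cond &
                                replicates$label == lab]
      cond_rows[[length(cond_rows) + 1L]] <- data.frame(
        condition = cond, label = lab, mean_percent = mean(p),
        sd_percent = if (length(p) > 1L) stats::sd(p) else NA_real_,
        n_replicates = length(p))
    }
  }
  list(replicates = replicates, conditions = do.call(rbind, cond_rows))
}
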