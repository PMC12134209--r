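# Ground-truthed synthetic repeat-level sequencing data: a repeat
# annotation with class labels (including the 72 mouse major-satellite
# GSAT_MM entries the study summarizes), fragment sets placed within chosen
# repeats, and paired IP/input Poisson counts with a controllable
# per-repeat log2 enrichment.

#' Synthetic repeat annotation
#'
#' Repeats laid head-to-tail with gaps over a small set of chromosomes.
#' The class mix includes `GSAT_MM` (major satellite; `n_gsat` entries,
#' matching the 72 annotated blocks when left at its default), interspersed
#' classes, and the `trf`/`dust` classes the pipeline filters out.
#'
#' @param n_repeats total number of repeats.
#' @param n_gsat number of GSAT_MM entries (default 72).
#' @param seed integer seed.
#' @return a [repeat_annotation()].
#' @export
make_repeat_annotation <- function(n_repeats = 500L, n_gsat = 72L,
                                   seed = 1L) {
  stopifnot(n_repeats >= n_gsat + 4L)
  withr::with_seed(seed, {
    other <- c("L1", "B1_SINE", "ERVK", "MTA_MM", "trf", "dust")
    classes <- c(rep("GSAT_MM", n_gsat),
                 sample(other, n_repeats - n_gsat, replace = TRUE))
    classes <- sample(classes)  # shuffle positions along the genome
    lens <- ifelse(classes == "GSAT_MM",
                   round(runif(n_repeats, 1000, 8000)),   # satellite blocks
                   round(runif(n_repeats, 150, 6000)))
    chrom <- paste0("chr", sample(1:19, n_repeats, replace = TRUE))
    starts <- integer(n_repeats)
    pos <- setNames(rep(0L, 19L), paste0("chr", 1:19))
    for (i in seq_len(n_repeats)) {
      gap <- sample(200:2000, 1L)
      starts[i] <- pos[[chrom[i]]] + gap
      pos[[chrom[i]]] <- starts[i] + lens[i]
    }
    repeat_annotation(data.frame(
      chrom = chrom, start = starts, end = starts + lens,
      repeat_id = sprintf("rep_%04d", seq_len(n_repeats)),
      class_label = classes))
  })
}

#' Generate a synthetic fragment set over a repeat annotation
#'
#' Each fragment is assigned to a repeat by a multinomial draw over
#' `weights` and placed uniformly so that it overlaps that repeat
#' (fully inside when the repeat is longer than the fragment, centred over
#' it otherwise).
#'
#' @param annotation a [repeat_annotation()] (non-empty).
#' @param weights per-repeat relative abundance (>= 0, not all zero);
#'   recycled scalar allowed.
#' @param n_fragments number of fragments (>= 0).
#' @param seed integer seed.
#' @param fragment_length fragment size in bp (default 147, one nucleosome).
#' @param sample_id sample name.
#' @return a [fragment_set()].
#' @export
generate_fragments <- function(annotation, weights = 1, n_fragments,
                               seed = 1L, fragment_length = 147L,
                               sample_id = "synthetic") {
  stopifnot(inherits(annotation, "repeat_annotation"))
  if (nrow(annotation) == 0L) {
    chr_stop("chromofied_data_error", "empty repeat annotation")
  }
  weights <- rep_len(weights, nrow(annotation))
  if (any(weights < 0) || sum(weights) == 0) {
    chr_stop("chromofied_data_error",
             "weights must be >= 0 and not all zero")
  }
  if (n_fragments == 0L) {
    return(fragment_set(sample_id, data.frame(chrom = character(),
                                              start = integer(),
                                              end = integer())))
  }
  withr::with_seed(seed, {
    idx <- sample.int(nrow(annotation), n_fragments, replace = TRUE,
                      prob = weights)
    rs <- annotation$start[idx]
    re <- annotation$end[idx]
    len <- re - rs
    start <- ifelse(len >= fragment_length,
                    rs + floor(runif(n_fragments) *
                                 (len - fragment_length + 1)),
                    pmax(0L, rs - ((fragment_length - len) %/% 2L)))
    fragment_set(sample_id, data.frame(chrom = annotation$chrom[idx],
                                       start = as.integer(start),
                                       end = as.integer(start) +
                                         as.integer(fragment_length)))
  })
}

#' Generate paired IP/input repeat counts with known enrichment
#'
#' Input counts are Poisson with expectation proportional to repeat length
#' (uniform abundance); IP expectations are the input expectations scaled by
#' `2^truth_log2` and renormalized to the same depth.
#'
#' @param annotation a [repeat_annotation()].
#' @param truth_log2 per-repeat true log2 IP/input enrichment (recycled).
#' @param depth expected total fragment count per sample (>= 0).
#' @param seed integer seed.
#' @return list with named integer vectors `ip_counts` and `input_counts`
#'   plus the `truth_log2` used.
#' @export
generate_repeat_counts <- function(annotation, truth_log2 = 0, depth,
                                   seed = 1L) {
  stopifnot(inherits(annotation, "repeat_annotation"), depth >= 0)
  n <- nrow(annotation)
  truth_log2 <- rep_len(truth_log2, n)
  p <- annotation$length / sum(annotation$length)
  q <- p * 2^truth_log2
  q <- q / sum(q)
  withr::with_seed(seed, {
    input_counts <- rpois(n, depth * p)
    ip_counts <- rpois(n, depth * q)
  })
  list(ip_counts = setNames(as.integer(ip_counts), annotation$repeat_id),
       input_counts = setNames(as.integer(input_counts),
                               annotation$repeat_id),
       truth_log2 = setNames(truth_log2, annotation$repeat_id))
}
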