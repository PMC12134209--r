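# SNAP-capture-seq repeat quantification: repeat-class filtering, fragment
# to repeat overlap counting (any shared bp counts once per fragment/repeat
# pair), and the normalization chain CPM (over repeat-mapped reads) ->
# per-bp -> IP/input -> log2 -> per-IP-sample z-score across repeats.
# Coordinates are BED-style 0-based half-open throughout; strand is ignored.

#' Repeat annotation
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `repeat_id` (unique), `class_label` (non-empty).
#' @return `repeat_annotation` object (a validated data.frame with a
#'   `length` column in bp).
#' @export
repeat_annotation <- function(df) {
  need <- c("chrom", "start", "end", "repeat_id", "class_label")
  stopifnot(all(need %in% names(df)))
  df <- df[, need]
  if (any(df$end <= df$start)) {
    chr_stop("chromofied_data_error", "repeat intervals must have end > start")
  }
  if (anyDuplicated(df$repeat_id)) {
    chr_stop("chromofied_data_error", "repeat_id values must be unique")
  }
  if (any(!nzchar(df$class_label) | is.na(df$class_label))) {
    chr_stop("chromofied_data_error", "class_label must be non-empty")
  }
  df$length <- df$end - df$start
  structure(df, class = c("repeat_annotation", "data.frame"))
}

#' Deduplicated paired-fragment set for one sample
#'
#' @param sample_id sample name.
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return `fragment_set` object.
#' @export
fragment_set <- function(sample_id, df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df <- df[, c("chrom", "start", "end")]
  if (any(df$end <= df$start)) {
    chr_stop("chromofied_data_error",
             "fragment intervals must have end > start")
  }
  structure(list(sample_id = sample_id, fragments = df),
            class = "fragment_set")
}

parse_bed_intervals <- function(path, min_cols) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < min_cols) {
      chr_stop("chromofied_parse_error",
               sprintf("%s line %d: expected >= %d tab-separated fields",
                       path, i, min_cols))
    }
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || e <= s) {
      chr_stop("chromofied_parse_error",
               sprintf("%s line %d: malformed interval [%s, %s)",
                       path, i, f[2L], f[3L]))
    }
  }
  fields
}

#' Read a fragment BED (3+ columns, 0-based half-open)
#'
#' @param path BED file path.
#' @param sample_id sample name (default: file base name).
#' @return a [fragment_set()]. Malformed intervals raise a parse error
#'   naming the offending line.
#' @export
read_fragment_bed <- function(path,
                              sample_id = tools::file_path_sans_ext(basename(path))) {
  fields <- parse_bed_intervals(path, 3L)
  if (is.data.frame(fields)) return(fragment_set(sample_id, fields))
  fragment_set(sample_id, data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L))))
}

#' Read / write a repeat-annotation BED
#'
#' Dialect: chrom, start, end, name (= repeat_id), class label in column 5.
#'
#' @param path file path.
#' @param annotation a [repeat_annotation()] (for writing).
#' @return `read_repeat_bed` returns a [repeat_annotation()].
#' @export
read_repeat_bed <- function(path) {
  fields <- parse_bed_intervals(path, 5L)
  if (is.data.frame(fields)) {
    chr_stop("chromofied_data_error", paste0("empty repeat annotation: ", path))
  }
  repeat_annotation(data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    repeat_id = vapply(fields, `[`, "", 4L),
    class_label = vapply(fields, `[`, "", 5L)))
}

#' @rdname read_repeat_bed
#' @export
write_repeat_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "repeat_annotation"))
  write.table(annotation[, c("chrom", "start", "end", "repeat_id",
                             "class_label")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a fragment set as 3-column BED
#'
#' @param fragments a [fragment_set()].
#' @param path file path.
#' @export
write_fragment_bed <- function(fragments, path) {
  stopifnot(inherits(fragments, "fragment_set"))
  write.table(fragments$fragments, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove excluded repeat classes
#'
#' The published filtering drops tandem ("trf") and low-complexity ("dust")
#' repeat classes before quantification.
#'
#' @param annotation a [repeat_annotation()].
#' @param excluded_classes character vector of class labels to drop.
#' @return filtered [repeat_annotation()].
#' @export
filter_repeat_classes <- function(annotation,
                                  excluded_classes = c("trf", "dust")) {
  stopifnot(inherits(annotation, "repeat_annotation"))
  repeat_annotation(as.data.frame(
    annotation[!(annotation$class_label %in% excluded_classes), ]))
}

#' Count fragment overlaps per repeat
#'
#' A fragment increments a repeat's count iff they share at least one base
#' (half-open intersection non-empty); a fragment overlapping k repeats
#' increments all k. Backed by IRanges interval trees.
#'
#' @param fragments a [fragment_set()].
#' @param annotation a [repeat_annotation()].
#' @return named integer vector of counts, one per `repeat_id`, in
#'   annotation order.
#' @export
count_fragment_overlaps <- function(fragments, annotation) {
  stopifnot(inherits(fragments, "fragment_set"),
            inherits(annotation, "repeat_annotation"))
  counts <- setNames(integer(nrow(annotation)), annotation$repeat_id)
  fr <- fragments$fragments
  if (nrow(fr) == 0L) return(counts)
  # 0-based half-open -> 1-based closed
  gr_frag <- GenomicRanges::GRanges(
    fr$chrom, IRanges::IRanges(fr$start + 1L, fr$end))
  gr_rep <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start + 1L, annotation$end))
  hits <- GenomicRanges::countOverlaps(gr_rep, gr_frag, minoverlap = 1L)
  counts[] <- as.integer(hits)
  counts
}

#' Assemble a repeat count matrix with IP/input pairing
#'
#' @param counts named list of per-sample count vectors (all over the same
#'   repeats, e.g. from [count_fragment_overlaps()]).
#' @param roles named character vector: "IP" or "input" per sample.
#' @param pairing named character vector mapping each IP sample to its
#'   matching input sample.
#' @return `repeat_count_matrix` object.
#' @export
repeat_count_matrix <- function(counts, roles, pairing) {
  stopifnot(is.list(counts), length(counts) >= 2L, !is.null(names(counts)))
  m <- do.call(cbind, counts)
  if (any(m < 0)) chr_stop("chromofied_data_error", "counts must be >= 0")
  stopifnot(all(names(roles) %in% colnames(m)),
            all(roles %in% c("IP", "input")))
  ips <- names(roles)[roles == "IP"]
  if (!all(ips %in% names(pairing))) {
    chr_stop("chromofied_config_error",
             "every IP sample needs exactly one matching input in `pairing`")
  }
  if (!all(pairing[ips] %in% names(roles)[roles == "input"])) {
    chr_stop("chromofied_config_error",
             "pairing must map IP samples to input samples")
  }
  structure(list(counts = m, roles = roles, pairing = pairing[ips]),
            class = "repeat_count_matrix")
}

#' Normalize a repeat count matrix to z-scored log2 IP/input enrichment
#'
#' Per sample: counts are scaled to counts-per-million over all
#' repeat-mapped reads of that sample, divided by repeat length (bp), the IP
#' value divided by its matching input (repeats with zero input are masked
#' `NA` unless a pseudocount is supplied), log2-transformed, and finally
#' standardized per IP sample across the included repeats (mean 0, sd 1;
#' sample sd).
#'
#' @param counts a [repeat_count_matrix()].
#' @param annotation a [repeat_annotation()] supplying repeat lengths; its
#'   repeat_ids must match the count rows (the counts are subset and
#'   reordered to the annotation).
#' @param pseudocount optional count added to every cell before CPM (default
#'   0, i.e. masking instead of pseudocounts).
#' @return an `enrichment_matrix`: list with `stages` (matrices `cpm`,
#'   `perbp`, `ratio`, `log2`, `zscore`), `repeat_id`, `length`, `pairing`.
#'   A sample with zero total reads raises an error; an IP sample whose
#'   log2 ratios have zero spread raises a degenerate-distribution error.
#' @export
normalize_zscore <- function(counts, annotation, pseudocount = 0) {
  stopifnot(inherits(counts, "repeat_count_matrix"),
            inherits(annotation, "repeat_annotation"))
  ids <- annotation$repeat_id
  m <- counts$counts
  if (is.null(rownames(m))) {
    if (nrow(m) != length(ids)) {
      chr_stop("chromofied_data_error",
               "count rows do not match the annotation")
    }
    rownames(m) <- ids
  }
  if (!all(ids %in% rownames(m))) {
    chr_stop("chromofied_data_error", "count rows do not match the annotation")
  }
  m <- m[ids, , drop = FALSE] + pseudocount
  totals <- colSums(m)
  if (any(totals == 0)) {
    chr_stop("chromofied_data_error",
             paste0("sample(s) with zero repeat-mapped reads: ",
                    paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  cpm <- sweep(m, 2L, totals, "/") * 1e6
  perbp <- cpm / annotation$length
  ips <- names(counts$pairing)
  ratio <- matrix(NA_real_, nrow(m), length(ips),
                  dimnames = list(ids, ips))
  for (ip in ips) {
    inp <- perbp[, counts$pairing[[ip]]]
    r <- perbp[, ip] / inp
    r[inp == 0] <- NA_real_
    ratio[, ip] <- r
  }
  lg <- log2(ratio)
  z <- lg
  for (ip in ips) {
    v <- lg[, ip]
    ok <- is.finite(v)
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s < 1e-12) {
      chr_stop("chromofied_degenerate_error",
               paste0("log2 ratios of sample ", ip,
                      " have zero spread; z-scores are undefined"))
    }
    z[ok, ip] <- (v[ok] - mean(v[ok])) / s
    z[!ok, ip] <- NA_real_
  }
  structure(list(stages = list(cpm = cpm, perbp = perbp, ratio = ratio,
                               log2 = lg, zscore = z),
                 repeat_id = ids, length = annotation$length,
                 pairing = counts$pairing),
            class = "enrichment_matrix")
}

#' Summarize z-scored enrichment over one repeat class
#'
#' Boxplot-style summary per IP sample: n, median, quartiles, Tukey
#' whiskers (most extreme values within 1.5 x IQR of the quartiles), number
#' of outliers beyond the whiskers, mean, and an `above_zero` flag (mean
#' z > 0 reads as enrichment over the average repeat).
#'
#' @param enrichment an `enrichment_matrix` from [normalize_zscore()].
#' @param annotation the (filtered) [repeat_annotation()].
#' @param class_label repeat class to summarize (e.g. "GSAT_MM", the mouse
#'   major satellite).
#' @return data.frame, one row per IP sample. An absent/empty class raises
#'   an error naming the class.
#' @export
summarize_repeat_class <- function(enrichment, annotation, class_label) {
  stopifnot(inherits(enrichment, "enrichment_matrix"),
            inherits(annotation, "repeat_annotation"))
  ids <- annotation$repeat_id[annotation$class_label == class_label]
  if (length(ids) == 0L) {
    chr_stop("chromofied_data_error",
             paste0("repeat class not present in the annotation: ",
                    class_label))
  }
  z <- enrichment$stages$zscore
  rows <- lapply(colnames(z), function(ip) {
    v <- z[ids, ip]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      return(data.frame(sample = ip, class_label = class_label, n = 0L,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_,
                        n_outliers = 0L, mean = NA_real_, above_zero = NA))
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    in_lo <- v[v >= q[1L] - 1.5 * iqr]
    in_hi <- v[v <= q[3L] + 1.5 * iqr]
    data.frame(sample = ip, class_label = class_label, n = length(v),
               median = q[2L], q1 = q[1L], q3 = q[3L],
               whisker_lo = min(in_lo), whisker_hi = max(in_hi),
               n_outliers = sum(v < q[1L] - 1.5 * iqr | v > q[3L] + 1.5 * iqr),
               mean = mean(v), above_zero = mean(v) > 0)
  })
  do.call(rbind, rows)
}
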