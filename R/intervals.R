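#' Genomic interval utilities
#'
#' All coordinates in this package are GRCh37, 1-based and inclusive at both
#' ends, matching the convention in which clinical 15q11-q13 intervals are
#' printed (e.g. `chr15:22,892,936-27,892,936`). Converters at the BED
#' boundary handle 0-based half-open input.
#'
#' @param chrom Chromosome label (with or without the `chr` prefix; it is
#'   normalized to `chr`-prefixed form).
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @return `genomic_interval()` returns a one-row data frame with columns
#'   `chrom`, `start`, `end`.
#' @examples
#' iv <- genomic_interval("chr15", 25200019, 25223890)
#' interval_length_kb(iv)  # 23
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- norm_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start > end)) {
    stop("invalid interval: require start <= end and numeric coordinates")
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' @rdname genomic_interval
#' @param x For `parse_interval()`, a string like
#'   `"chr15:25,200,019-25,223,890"` (commas optional, en-dash accepted).
#' @export
parse_interval <- function(x) {
  x <- gsub(",", "", x)
  x <- gsub("–", "-", x)  # en-dash as printed in clinical reports
  m <- regmatches(x, regexec("^(chr)?([0-9XYM]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) == 0) stop("cannot parse interval string: ", x)
  genomic_interval(m[3], as.numeric(m[4]), as.numeric(m[5]))
}

#' @rdname genomic_interval
#' @param iv A genomic interval (any object with `start` and `end` fields).
#' @return `interval_length_kb()` returns the interval length in whole
#'   kilobases, truncated: `floor((end - start + 1)/1000)`.
#' @export
interval_length_kb <- function(iv) {
  as.integer(floor((iv$end - iv$start + 1) / 1000))
}

# length in megabases (not truncated); used for the >5 Mb / >=8 Mb rules
interval_length_mb <- function(start, end) {
  (end - start + 1) / 1e6
}

norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

# point-in-interval test against a set of intervals (data frame chrom/start/end)
points_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  chrom <- norm_chrom(chrom)
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                    pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  hit
}

#' Read a BED mask file
#'
#' Reads a 3+ column BED file (0-based, half-open) and converts it to the
#' package's 1-based inclusive convention (`start + 1`, `end` unchanged).
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive). A zero-row data frame is a valid (empty) mask.
#' @export
read_bed_mask <- function(path) {
  if (!file.exists(path)) stop("BED mask file not found: ", path)
  bed <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame())
      }
      stop("malformed BED mask: ", conditionMessage(e))
    })
  if (nrow(bed) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  if (ncol(bed) < 3 || !is.numeric(bed[[2]]) || !is.numeric(bed[[3]])) {
    stop("malformed BED mask: need >= 3 columns with numeric coordinates")
  }
  data.frame(chrom = norm_chrom(bed[[1]]),
             start = bed[[2]] + 1,   # 0-based half-open -> 1-based inclusive
             end = bed[[3]],
             stringsAsFactors = FALSE)
}
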