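#' Expression time-course container
#'
#' Holds a genes x samples expression matrix together with the Zeitgeber
#' time (ZT, hours since lights-on) and replicate index of every sample.
#' This is the common currency of the rhythm-screening functions: the
#' emulated design is 6 time points (ZT 4, 8, 12, 16, 20, 24) with 3
#' replicates each, but any design with at least one replicate per sampled
#' ZT is accepted.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Missing
#'   values are an error: the small single-cycle designs this package
#'   targets are too small to support imputation.
#' @param sample_zt numeric vector of ZT hours, one per column.
#' @param replicate_index integer vector, one per column; derived from
#'   column order within each ZT when omitted.
#' @param gene_ids character vector of row identifiers; taken from
#'   `rownames(values)` or generated when absent.
#' @return An object of class `timecourse`: a list with elements `values`,
#'   `sample_zt`, `replicate_index`, `gene_ids`.
#' @examples
#' m <- matrix(rnorm(12, mean = 10), nrow = 2,
#'             dimnames = list(c("g1", "g2"), NULL))
#' tc <- timecourse(m, sample_zt = rep(c(4, 12, 20), each = 2))
#' dim(tc)
#' @export
timecourse <- function(values, sample_zt, replicate_index = NULL,
                       gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("missing values are not supported; filter or re-measure before import")
  if (length(sample_zt) != ncol(values))
    stop("sample_zt must have one entry per sample (column)")
  if (any(!is.finite(sample_zt))) stop("sample_zt must be finite")
  if (is.null(replicate_index)) {
    replicate_index <- stats::ave(seq_along(sample_zt), sample_zt, FUN = seq_along)
  }
  if (length(replicate_index) != ncol(values))
    stop("replicate_index must have one entry per sample")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  rownames(values) <- gene_ids
  if (is.null(colnames(values)))
    colnames(values) <- paste0("ZT", sample_zt, "_rep", replicate_index)
  structure(list(values = values,
                 sample_zt = as.numeric(sample_zt),
                 replicate_index = as.integer(replicate_index),
                 gene_ids = as.character(gene_ids)),
            class = "timecourse")
}

#' @export
dim.timecourse <- function(x) dim(x$values)

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse> ", nrow(x$values), " genes x ", ncol(x$values), " samples\n", sep = "")
  cat("  ZT: ", paste(sort(unique(x$sample_zt)), collapse = ", "),
      " (", max(table(x$sample_zt)), " replicates)\n", sep = "")
  invisible(x)
}

#' Light/dark cycle definition
#'
#' Maps clock time to Zeitgeber time. The default reproduces the housing
#' conditions the package's analyses assume: a 14-h light / 10-h dark cycle
#' with lights-on at 05:00 (ZT0), so dark onset falls at ZT14.
#'
#' @param lights_on_clock clock hour of lights-on (ZT0), default 5.
#' @param light_hours hours of light per day, default 14.
#' @param dark_hours hours of dark per day, default 10.
#' @return An object of class `light_cycle` with fields `lights_on_clock`,
#'   `light_hours`, `dark_hours` and `dark_onset_zt` (= `light_hours`).
#' @examples
#' lc <- light_cycle()
#' lc$dark_onset_zt   # 14
#' is_dark(c(2, 15, 23.5), lc)
#' @export
light_cycle <- function(lights_on_clock = 5, light_hours = 14, dark_hours = 10) {
  if (light_hours + dark_hours != 24)
    stop("light_hours + dark_hours must equal 24")
  if (light_hours <= 0 || dark_hours <= 0)
    stop("light and dark phases must both be positive")
  structure(list(lights_on_clock = lights_on_clock,
                 light_hours = light_hours,
                 dark_hours = dark_hours,
                 dark_onset_zt = light_hours),
            class = "light_cycle")
}

#' @describeIn light_cycle TRUE for ZT hours falling in the dark phase.
#' @param zt numeric ZT hours (any real; reduced mod 24).
#' @param cycle a `light_cycle`.
#' @export
is_dark <- function(zt, cycle = light_cycle()) {
  (zt %% 24) >= cycle$dark_onset_zt
}

#' @describeIn light_cycle convert clock hours to ZT hours in [0, 24).
#' @param clock_hours numeric clock hours.
#' @export
clock_to_zt <- function(clock_hours, cycle = light_cycle()) {
  (clock_hours - cycle$lights_on_clock) %% 24
}
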