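#' Genomic regions for triplicate-region log2 re-normalization
#'
#' The background is formed by two flanking stretches of the gene on
#' either side of the triplicate region, and the triplicate (TRI) region
#' itself sits between them; coordinates are 1-based inclusive on
#' Hg19/GRCh37, chromosome 2.  Each boundary is only known to within a
#' breakpoint interval, so two interpretations are offered: `"outer"`
#' (default) takes the outermost edge of every breakpoint pair (maximal
#' background and maximal TRI span), `"inner"` the innermost.  One
#' published background breakpoint pair is printed with its coordinates
#' in descending order; both interpretations normalize it to ascending
#' order first.
#'
#' @param interpretation `"outer"` or `"inner"`.
#' @return A tibble with columns `region` (`background`/`tri`), `chrom`,
#'   `start`, `end`.
#' @export
acgh_regions <- function(interpretation = c("outer", "inner")) {
  interpretation <- match.arg(interpretation)
  if (interpretation == "outer") {
    tibble(
      region = c("background", "background", "tri"),
      chrom = "chr2",
      start = c(152340824, 152465657, 152433598),
      end = c(152433349, 152592449, 152465448)
    )
  } else {
    tibble(
      region = c("background", "background", "tri"),
      chrom = "chr2",
      start = c(152341131, 152465735, 152434494),
      end = c(152432955, 152583346, 152465223)
    )
  }
}

#' Read an aCGH probe table
#'
#' Reads per-probe log2 ratios from a BED-like 4-column tab-separated file
#' (`chrom`, `start`, `end`, `log2`; 0-based half-open coordinates,
#' converted on read) or a CSV with the same columns in 1-based inclusive
#' coordinates.
#'
#' @param path Input file.
#' @param format `"bed"` or `"csv"`; guessed from the extension when
#'   missing.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `log2`.
#' @export
read_acgh_probes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "bed"
  }
  format <- match.arg(format, c("bed", "csv"))
  if (format == "bed") {
    x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "log2"),
                         col_types = "ciid", progress = FALSE)
    x$start <- x$start + 1L  # 0-based half-open -> 1-based inclusive
  } else {
    x <- readr::read_csv(path, col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), log2 = readr::col_double()
    ), progress = FALSE)
  }
  if (any(x$start > x$end)) abort("Probe intervals must satisfy start <= end")
  if (any(!is.finite(x$log2))) abort("Probe log2 ratios must be finite")
  as_tibble(x)
}

# Midpoint-in-interval membership of probes in a set of regions.
probe_in_regions <- function(probes, regions) {
  mid <- (probes$start + probes$end) / 2
  hit <- rep(FALSE, nrow(probes))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (probes$chrom == regions$chrom[i] &
                    mid >= regions$start[i] & mid <= regions$end[i])
  }
  hit
}

#' Baseline-corrected triplicate-region log2 value
#'
#' Subtracts the mean log2 ratio of the probes in the flanking background
#' regions from the mean log2 ratio of the probes in the TRI region.
#' Probes are assigned to regions by their midpoint, which is unambiguous
#' for probes straddling a boundary.  A constant shift applied to every
#' probe cancels out.
#'
#' @param probes Probe tibble as from [read_acgh_probes()].
#' @param regions Region tibble as from [acgh_regions()].
#' @return The normalized TRI log2 value (single number).
#' @export
normalize_tri_log2 <- function(probes, regions = acgh_regions()) {
  stopifnot(all(c("chrom", "start", "end", "log2") %in% names(probes)))
  region_mean <- function(what) {
    reg <- filter(regions, .data$region == what)
    if (nrow(reg) == 0) abort(sprintf("No '%s' region configured", what))
    inside <- probe_in_regions(probes, reg)
    if (!any(inside)) {
      abort(sprintf("No probes fall inside the %s region", what))
    }
    mean(probes$log2[inside])
  }
  region_mean("tri") - region_mean("background")
}

#' Copy number from a normalized log2 ratio
#'
#' Converts a baseline-corrected log2 ratio to an estimated copy number
#' assuming the region's normal copy number: `CN = normal_cn * 2^log2`.
#'
#' @param normalized_log2 Normalized TRI log2 value(s).
#' @param normal_cn Normal copy number of the region (default 6).
#' @return Estimated copy number (vectorized).
#' @examples
#' acgh_cn(c(0, -1, log2(7 / 6)))
#' @export
acgh_cn <- function(normalized_log2, normal_cn = 6) {
  if (normal_cn <= 0) abort("normal_cn must be positive")
  normal_cn * 2^normalized_log2
}
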